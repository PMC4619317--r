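# Independent oracles, written against the raw triple table with plain
# loops - deliberately sharing no code path with the package's vectorised
# recovery and merge implementation.

RDF_TYPE_IRI <- "http://www.w3.org/1999/02/22-rdf-syntax-ns#type"
SUBCLASS_IRI <- "http://www.w3.org/2000/01/rdf-schema#subClassOf"
SAMEAS_IRI <- "http://www.w3.org/2002/07/owl#sameAs"
XSD_STRING_IRI <- "http://www.w3.org/2001/XMLSchema#string"

# tests run against the installed namespace, which does not export the
# vocabulary constants; mirror them here
RDF_TYPE <- RDF_TYPE_IRI
RDFS_SUBCLASS <- SUBCLASS_IRI
OWL_SAMEAS <- SAMEAS_IRI

oracle_ns_of <- function(iri) {
  h <- regexpr("#", iri, fixed = TRUE)
  if (h > 0) return(substr(iri, 1, h))
  parts <- gregexpr("/", iri, fixed = TRUE)[[1]]
  parts <- parts[parts > 8]
  if (length(parts) == 0 || parts[1] == -1) iri else substr(iri, 1, max(parts))
}

# Brute-force recount of unique type links, counts and multiplicities from
# raw statements.
oracle_links <- function(triples, namespaces) {
  schema <- c(RDF_TYPE_IRI, SUBCLASS_IRI, SAMEAS_IRI)
  types <- list()
  for (i in seq_len(nrow(triples))) {
    if (triples$p[i] == RDF_TYPE_IRI && !triples$o_lit[i]) {
      types[[triples$s[i]]] <- unique(c(types[[triples$s[i]]], triples$o[i]))
    }
  }
  n_inst <- table(unlist(lapply(names(types), function(s) types[[s]])))
  classify <- function(i) {
    if (triples$o_lit[i]) {
      dt <- triples$o_dt[i]
      return(list(list(type = if (is.na(dt)) XSD_STRING_IRI else dt, kind = "datatype")))
    }
    o <- triples$o[i]
    ot <- types[[o]]
    if (!is.null(ot)) return(lapply(ot, function(t) list(type = t, kind = "class")))
    internal <- startsWith(o, "urn:skolem:") ||
      any(vapply(namespaces, function(ns) startsWith(o, ns), logical(1)))
    if (internal) {
      hit <- if (startsWith(o, "urn:skolem:")) "urn:skolem:" else {
        cand <- namespaces[vapply(namespaces, function(ns) startsWith(o, ns), logical(1))]
        cand[which.max(nchar(cand))]
      }
      list(list(type = hit, kind = "invalid"))
    } else list(list(type = oracle_ns_of(o), kind = "external"))
  }
  reg <- new.env(parent = emptyenv())
  for (i in seq_len(nrow(triples))) {
    if (triples$p[i] %in% schema) next
    st <- types[[triples$s[i]]]
    if (is.null(st)) next
    okey <- if (triples$o_lit[i]) paste0("L", triples$o[i], "@", triples$o_dt[i]) else triples$o[i]
    for (subj_type in st) {
      for (oc in classify(i)) {
        key <- paste(subj_type, triples$p[i], oc$type, oc$kind, sep = "\r")
        cur <- reg[[key]]
        if (is.null(cur)) cur <- list(pairs = character(0))
        cur$pairs <- unique(c(cur$pairs, paste(triples$s[i], okey, sep = "\r")))
        reg[[key]] <- cur
      }
    }
  }
  rows <- list()
  for (key in sort(ls(reg))) {
    parts <- strsplit(key, "\r", fixed = TRUE)[[1]]
    pairs <- do.call(rbind, strsplit(reg[[key]]$pairs, "\r", fixed = TRUE))
    subj <- pairs[, 1]; obj <- pairs[, 2]
    total <- as.integer(n_inst[[parts[1]]])
    per_s <- table(subj)
    fwd <- if (length(per_s) == total && max(per_s) == 1) "1..1"
           else if (length(per_s) == total) "1..N"
           else if (max(per_s) == 1) "0..1" else "0..N"
    if (parts[4] == "class") {
      t_total <- as.integer(n_inst[[parts[3]]])
      per_o <- table(obj)
      rev <- if (length(per_o) == t_total && max(per_o) == 1) "1..1"
             else if (length(per_o) == t_total) "1..N"
             else if (max(per_o) == 1) "0..1" else "0..N"
    } else rev <- "not_determined"
    if (parts[4] == "invalid") { fwd <- "not_determined"; rev <- "not_determined" }
    rows[[length(rows) + 1L]] <- data.frame(
      subject_type = parts[1], predicate = parts[2], object_type = parts[3],
      object_kind = parts[4], count = length(reg[[key]]$pairs),
      forward = fwd, reverse = rev, stringsAsFactors = FALSE)
  }
  out <- if (length(rows)) do.call(rbind, rows) else {
    data.frame(subject_type = character(), predicate = character(),
               object_type = character(), object_kind = character(),
               count = integer(), forward = character(), reverse = character(),
               stringsAsFactors = FALSE)
  }
  rownames(out) <- NULL
  out[order(out$subject_type, out$predicate, out$object_type, out$object_kind,
            method = "radix"), , drop = FALSE]
}

links_norm <- function(l) {
  l <- l[, c("subject_type", "predicate", "object_type", "object_kind",
             "count", "forward", "reverse")]
  l <- l[order(l$subject_type, l$predicate, l$object_type, l$object_kind,
               method = "radix"), , drop = FALSE]
  rownames(l) <- NULL
  l
}

# independent reachability over the raw edge table (no igraph)
oracle_is_descendant <- function(edges, k, l) {
  if (identical(k, l)) return(TRUE)
  seen <- character(0); frontier <- k
  while (length(frontier)) {
    nxt <- unique(edges$parent[edges$child %in% frontier])
    nxt <- setdiff(nxt, seen)
    if (l %in% nxt) return(TRUE)
    seen <- c(seen, nxt); frontier <- nxt
  }
  FALSE
}

# every original link must be subsumed by a surviving link of the same
# predicate under subclass closure on both ends
oracle_coverage_ok <- function(original, simplified, edges) {
  for (i in seq_len(nrow(original))) {
    o <- original[i, ]
    surv <- simplified[simplified$predicate == o$predicate, , drop = FALSE]
    ok <- FALSE
    for (j in seq_len(nrow(surv))) {
      sv <- surv[j, ]
      src_ok <- oracle_is_descendant(edges, o$subject_type, sv$subject_type)
      tgt_ok <- if (o$object_kind == "class" && sv$object_kind == "class") {
        oracle_is_descendant(edges, o$object_type, sv$object_type)
      } else identical(o$object_type, sv$object_type) && o$object_kind == sv$object_kind
      if (src_ok && tgt_ok) { ok <- TRUE; break }
    }
    if (!ok) return(FALSE)
  }
  TRUE
}

# --- minimal ShExC grammar checker for the emitted subset -------------------
# doc := prefix* shape* ; shape := IRIREF '{' [constr (';' constr)*] '}'
# constr := '(' triple ('|' triple)+ ')' card? | triple
# triple := IRIREF (('@' IRIREF) | 'IRI' | pname) card? ; card := '?'|'+'|'*'
shexc_parse_ok <- function(lines) {
  txt <- paste(sub("\\s#\\s.*$", "", lines), collapse = " ")
  toks <- regmatches(txt, gregexpr(
    "<[^>]*>|@<[^>]*>|PREFIX|IRI|[A-Za-z][A-Za-z0-9_]*:[A-Za-z0-9_]*|[{}();|?*+]",
    txt))[[1]]
  pos <- 1L
  peek <- function() if (pos <= length(toks)) toks[pos] else NA_character_
  adv <- function() { t <- peek(); pos <<- pos + 1L; t }
  is_iriref <- function(t) !is.na(t) && startsWith(t, "<")
  is_pname <- function(t) !is.na(t) && grepl("^[A-Za-z][A-Za-z0-9_]*:", t)
  parse_triple <- function() {
    if (!is_iriref(peek())) return(FALSE)
    adv()
    v <- peek()
    if (is.na(v)) return(FALSE)
    if (startsWith(v, "@<") || v == "IRI" || is_pname(v)) adv() else return(FALSE)
    if (peek() %in% c("?", "+", "*")) adv()
    TRUE
  }
  parse_constr <- function() {
    if (identical(peek(), "(")) {
      adv()
      if (!parse_triple()) return(FALSE)
      reps <- 0L
      while (identical(peek(), "|")) { adv(); if (!parse_triple()) return(FALSE); reps <- reps + 1L }
      if (reps < 1L) return(FALSE)
      if (!identical(adv(), ")")) return(FALSE)
      if (peek() %in% c("?", "+", "*")) adv()
      return(TRUE)
    }
    parse_triple()
  }
  while (identical(peek(), "PREFIX")) {
    adv()
    if (!is_pname(peek())) return(FALSE)
    adv()
    if (!is_iriref(peek())) return(FALSE)
    adv()
  }
  while (!is.na(peek())) {
    if (!is_iriref(adv())) return(FALSE)
    if (!identical(adv(), "{")) return(FALSE)
    if (!identical(peek(), "}")) {
      if (!parse_constr()) return(FALSE)
      while (identical(peek(), ";")) { adv(); if (!parse_constr()) return(FALSE) }
    }
    if (!identical(adv(), "}")) return(FALSE)
  }
  TRUE
}

# shared fixture shorthand
mem_example <- function(name) {
  ex <- example_graphs()[[name]]
  memory_graph(ex$triples, ex$namespaces)
}
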
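# Parsers and writers for the concrete RDF syntaxes the tool accepts.
#
# The environment offers no RDF library, so a Turtle subset sufficient for
# instance data and for this package's own exports is implemented here:
# @prefix/@base (and SPARQL-style PREFIX/BASE), prefixed names, IRIs,
# string/numeric/boolean literals with ^^datatype and @lang tags, 'a',
# ';' and ',' continuation, labelled and anonymous blank nodes with
# property lists. RDF collections "(...)" and triple-quoted strings are
# rejected with a parse error. N-Triples is parsed as the Turtle subset it
# is. RDF/XML is read through xml2.

TURTLE_TOKEN_RE <- paste0(
  "<[^>]*>",                                            # IRIREF
  '|"(?:[^"\\\\]|\\\\.)*"',                             # STRING
  "|\\^\\^",                                            # datatype marker
  "|@[A-Za-z]+(?:-[A-Za-z0-9]+)*",                      # langtag / @prefix / @base
  "|_:[A-Za-z0-9_.-]+",                                 # blank node label
  "|(?:[A-Za-z][A-Za-z0-9_.-]*)?:",                     # PNAME_NS (maybe followed by local)
  "(?:%[0-9A-Fa-f]{2}|[A-Za-z0-9_~-]|\\.(?=[A-Za-z0-9_~%-]))*",
  "|[A-Za-z][A-Za-z0-9_]*",                             # bare keyword (a, true, false, PREFIX, BASE)
  "|[+-]?(?:\\d+\\.\\d+(?:[eE][+-]?\\d+)?|\\d+[eE][+-]?\\d+|\\.\\d+(?:[eE][+-]?\\d+)?|\\d+)",
  "|[;,.\\[\\]()]",
  "|#.*$"
)

tokenize_turtle <- function(lines, file = "<text>") {
  toks <- vector("list", length(lines))
  for (i in seq_along(lines)) {
    line <- lines[[i]]
    if (!nzchar(trimws(line))) next
    if (grepl('"""', line, fixed = TRUE) || grepl("'''", line, fixed = TRUE)) {
      # a legal single-quoted string would escape its quotes
      stop(sprintf("parse error in %s at line %d: triple-quoted strings are not supported",
                   file, i), call. = FALSE)
    }
    m <- gregexpr(TURTLE_TOKEN_RE, line, perl = TRUE)[[1]]
    if (m[1] == -1) {
      stop(sprintf("parse error in %s at line %d: unrecognised content", file, i), call. = FALSE)
    }
    starts <- as.integer(m)
    lens <- attr(m, "match.length")
    # everything between tokens must be whitespace
    covered <- rep(FALSE, nchar(line))
    for (k in seq_along(starts)) covered[seq(starts[k], length.out = lens[k])] <- TRUE
    gap <- which(!covered & !grepl("^\\s$", strsplit(line, "")[[1]]))
    if (length(gap)) {
      stop(sprintf("parse error in %s at line %d, column %d: unexpected character '%s'",
                   file, i, gap[1], substr(line, gap[1], gap[1])), call. = FALSE)
    }
    vals <- substring(line, starts, starts + lens - 1L)
    vals <- vals[!startsWith(vals, "#")]
    if (length(vals)) toks[[i]] <- data.frame(tok = vals, line = i, stringsAsFactors = FALSE)
  }
  out <- do.call(rbind, toks[!vapply(toks, is.null, logical(1))])
  if (is.null(out)) data.frame(tok = character(), line = integer()) else out
}

#' Parse Turtle text into a triple table
#'
#' @param text a character scalar (entire document) or vector of lines.
#' @param file label used in error messages.
#' @return a triple table (see [rdf_triples()]).
#' @export
parse_turtle <- function(text, file = "<text>") {
  lines <- if (length(text) == 1L) strsplit(text, "\n", fixed = TRUE)[[1]] else text
  tokens <- tokenize_turtle(lines, file)
  st <- new.env(parent = emptyenv())
  st$toks <- tokens$tok; st$lines <- tokens$line; st$pos <- 1L
  st$prefixes <- character(0); st$base <- NA_character_; st$bnode_n <- 0L; st$file <- file
  st$s <- character(); st$p <- character(); st$o <- character()
  st$o_lit <- logical(); st$o_dt <- character()

  while (st$pos <= length(st$toks)) parse_statement(st)
  rdf_triples(st$s, st$p, st$o, st$o_lit, st$o_dt)
}

tt_peek <- function(st) if (st$pos <= length(st$toks)) st$toks[st$pos] else NA_character_
tt_next <- function(st) { t <- tt_peek(st); st$pos <- st$pos + 1L; t }
tt_err <- function(st, msg) {
  ln <- if (st$pos <= length(st$lines)) st$lines[st$pos] else st$lines[length(st$lines)]
  stop(sprintf("parse error in %s at line %d: %s", st$file, if (length(ln)) ln else 0L, msg),
       call. = FALSE)
}
tt_expect <- function(st, tok) {
  t <- tt_next(st)
  if (is.na(t) || t != tok) tt_err(st, sprintf("expected '%s', got '%s'", tok, t))
  t
}

parse_statement <- function(st) {
  t <- tt_peek(st)
  tl <- tolower(t)
  if (t == "@prefix" || tl == "prefix") {
    tt_next(st)
    ns <- tt_next(st)
    if (is.na(ns) || !grepl(":$", ns)) tt_err(st, "expected prefix name ending in ':'")
    iri <- tt_next(st)
    if (is.na(iri) || !startsWith(iri, "<")) tt_err(st, "expected IRI in prefix declaration")
    st$prefixes[sub(":$", "", ns)] <- resolve_iri(st, iri)
    if (t == "@prefix") tt_expect(st, ".")
    return(invisible())
  }
  if (t == "@base" || tl == "base") {
    tt_next(st)
    iri <- tt_next(st)
    if (is.na(iri) || !startsWith(iri, "<")) tt_err(st, "expected IRI in base declaration")
    st$base <- substr(iri, 2L, nchar(iri) - 1L)
    if (t == "@base") tt_expect(st, ".")
    return(invisible())
  }
  subj <- parse_node(st, allow_literal = FALSE)
  parse_predicate_object_list(st, subj)
  tt_expect(st, ".")
}

parse_predicate_object_list <- function(st, subj) {
  repeat {
    verb <- tt_next(st)
    pred <- if (identical(verb, "a")) RDF_TYPE else resolve_term_iri(st, verb)
    repeat {
      obj <- parse_object(st)
      emit_triple(st, subj, pred, obj)
      if (identical(tt_peek(st), ",")) { tt_next(st); next }
      break
    }
    had_semi <- FALSE
    while (identical(tt_peek(st), ";")) { tt_next(st); had_semi <- TRUE }
    if (!had_semi) break
    nxt <- tt_peek(st)
    if (is.na(nxt) || nxt %in% c(".", "]")) break
  }
}

emit_triple <- function(st, subj, pred, obj) {
  st$s <- c(st$s, subj)
  st$p <- c(st$p, pred)
  st$o <- c(st$o, obj$value)
  st$o_lit <- c(st$o_lit, obj$lit)
  st$o_dt <- c(st$o_dt, obj$dt)
}

new_bnode <- function(st) {
  st$bnode_n <- st$bnode_n + 1L
  paste0(SKOLEM_PREFIX, "genid", st$bnode_n)
}

parse_node <- function(st, allow_literal = TRUE) {
  t <- tt_peek(st)
  if (is.na(t)) tt_err(st, "unexpected end of input")
  if (t == "[") {
    tt_next(st)
    node <- new_bnode(st)
    if (identical(tt_peek(st), "]")) { tt_next(st); return(node) }
    parse_predicate_object_list(st, node)
    tt_expect(st, "]")
    return(node)
  }
  if (t == "(") tt_err(st, "RDF collections '(...)' are not supported")
  if (startsWith(t, "_:")) { tt_next(st); return(paste0(SKOLEM_PREFIX, substr(t, 3L, nchar(t)))) }
  if (startsWith(t, "<") || grepl(":", t, fixed = TRUE)) {
    return(resolve_term_iri(st, tt_next(st)))
  }
  tt_err(st, sprintf("expected subject, got '%s'", t))
}

parse_object <- function(st) {
  t <- tt_peek(st)
  if (is.na(t)) tt_err(st, "unexpected end of input in object position")
  if (startsWith(t, '"')) {
    tt_next(st)
    lex <- unescape_ntriples(substr(t, 2L, nchar(t) - 1L))
    nxt <- tt_peek(st)
    if (identical(nxt, "^^")) {
      tt_next(st)
      dt <- resolve_term_iri(st, tt_next(st))
      return(list(value = lex, lit = TRUE, dt = dt))
    }
    if (!is.na(nxt) && startsWith(nxt, "@") && !nxt %in% c("@prefix", "@base")) {
      tt_next(st)  # language tags collapse onto xsd:string (no stratification)
      return(list(value = lex, lit = TRUE, dt = XSD_STRING))
    }
    return(list(value = lex, lit = TRUE, dt = XSD_STRING))
  }
  if (t %in% c("true", "false")) {
    tt_next(st)
    return(list(value = t, lit = TRUE, dt = paste0(XSD_NS, "boolean")))
  }
  if (grepl("^[+-]?(\\d|\\.\\d)", t)) {
    tt_next(st)
    dt <- if (grepl("[eE]", t)) "double" else if (grepl(".", t, fixed = TRUE)) "decimal" else "integer"
    return(list(value = t, lit = TRUE, dt = paste0(XSD_NS, dt)))
  }
  if (t == "[" || t == "(" || startsWith(t, "_:") || startsWith(t, "<") ||
      grepl(":", t, fixed = TRUE)) {
    return(list(value = parse_node(st, allow_literal = FALSE), lit = FALSE, dt = NA_character_))
  }
  tt_err(st, sprintf("expected object, got '%s'", t))
}

resolve_iri <- function(st, iriref) {
  iri <- substr(iriref, 2L, nchar(iriref) - 1L)
  if (!is.na(st$base) && !grepl("^[A-Za-z][A-Za-z0-9+.-]*:", iri)) iri <- paste0(st$base, iri)
  iri
}

resolve_term_iri <- function(st, t) {
  if (is.na(t)) tt_err(st, "unexpected end of input")
  if (startsWith(t, "<")) return(resolve_iri(st, t))
  colon <- regexpr(":", t, fixed = TRUE)
  if (colon < 1) tt_err(st, sprintf("expected IRI or prefixed name, got '%s'", t))
  prefix <- substr(t, 1L, colon - 1L)
  local <- substr(t, colon + 1L, nchar(t))
  ns <- if (prefix %in% names(st$prefixes)) st$prefixes[[prefix]] else NA_character_
  if (is.na(ns)) tt_err(st, sprintf("undeclared prefix '%s:'", prefix))
  paste0(unname(ns), gsub("%([0-9A-Fa-f]{2})", "%\\1", local))
}

#' Parse N-Triples text into a triple table
#'
#' N-Triples is accepted through the Turtle reader (it is a syntactic
#' subset of the supported Turtle dialect).
#'
#' @inheritParams parse_turtle
#' @return a triple table.
#' @export
parse_ntriples <- function(text, file = "<text>") parse_turtle(text, file)

#' Parse an RDF/XML document into a triple table
#'
#' Supports the common RDF/XML patterns: `rdf:Description` and typed node
#' elements with `rdf:about`/`rdf:nodeID`, property elements carrying
#' `rdf:resource`, `rdf:nodeID`, `rdf:datatype`, text literals and nested
#' node elements (including `rdf:parseType="Resource"`).
#'
#' @param x path to a file or a character scalar of XML text.
#' @return a triple table.
#' @export
parse_rdfxml <- function(x) {
  doc <- if (length(x) == 1L && !grepl("<", x, fixed = TRUE) && file.exists(x)) {
    xml2::read_xml(x)
  } else xml2::read_xml(paste(x, collapse = "\n"))
  st <- new.env(parent = emptyenv())
  st$s <- character(); st$p <- character(); st$o <- character()
  st$o_lit <- logical(); st$o_dt <- character(); st$bnode_n <- 0L
  rdf_ns <- "http://www.w3.org/1999/02/22-rdf-syntax-ns#"
  root <- xml2::xml_root(doc)
  nodes <- if (identical(xml2::xml_name(root), "RDF")) {
    xml2::xml_children(root)
  } else list(root)
  for (n in nodes) rdfxml_node(st, n, rdf_ns)
  rdf_triples(st$s, st$p, st$o, st$o_lit, st$o_dt)
}

# namespaced attribute lookup that tolerates xml2's prefix handling
rdf_attr <- function(node, name, rdf_ns) {
  v <- xml2::xml_attr(node, paste0("rdf:", name), ns = c(rdf = rdf_ns))
  if (is.na(v)) v <- xml2::xml_attr(node, name)
  v
}

rdfxml_expand <- function(node) {
  # expand the element's qualified name to a full IRI using its namespace
  ns_href <- xml2::xml_ns(xml2::xml_root(node))
  qn <- xml2::xml_name(node, ns = ns_href)
  colon <- regexpr(":", qn, fixed = TRUE)
  if (colon > 0) {
    prefix <- substr(qn, 1L, colon - 1L)
    local <- substr(qn, colon + 1L, nchar(qn))
    href <- unname(ns_href[prefix])
    if (!is.na(href)) return(paste0(href, local))
  }
  qn
}

rdfxml_node <- function(st, node, rdf_ns) {
  if (inherits(node, "xml_node") && xml2::xml_type(node) != "element") return(invisible(NULL))
  about <- rdf_attr(node, "about", rdf_ns)
  node_id <- rdf_attr(node, "nodeID", rdf_ns)
  subj <- if (!is.na(about)) about else if (!is.na(node_id)) {
    paste0(SKOLEM_PREFIX, node_id)
  } else {
    st$bnode_n <- st$bnode_n + 1L
    paste0(SKOLEM_PREFIX, "genid", st$bnode_n)
  }
  iri <- rdfxml_expand(node)
  if (!identical(iri, paste0(rdf_ns, "Description"))) {
    st$s <- c(st$s, subj); st$p <- c(st$p, RDF_TYPE); st$o <- c(st$o, iri)
    st$o_lit <- c(st$o_lit, FALSE); st$o_dt <- c(st$o_dt, NA_character_)
  }
  for (prop in xml2::xml_children(node)) {
    if (xml2::xml_type(prop) != "element") next
    pred <- rdfxml_expand(prop)
    res <- rdf_attr(prop, "resource", rdf_ns)
    pnid <- rdf_attr(prop, "nodeID", rdf_ns)
    dt <- rdf_attr(prop, "datatype", rdf_ns)
    ptype <- rdf_attr(prop, "parseType", rdf_ns)
    kids <- Filter(function(k) xml2::xml_type(k) == "element", xml2::xml_children(prop))
    if (!is.na(res)) {
      obj <- res; lit <- FALSE; odt <- NA_character_
    } else if (!is.na(pnid)) {
      obj <- paste0(SKOLEM_PREFIX, pnid); lit <- FALSE; odt <- NA_character_
    } else if (identical(ptype, "Resource")) {
      st$bnode_n <- st$bnode_n + 1L
      obj <- paste0(SKOLEM_PREFIX, "genid", st$bnode_n); lit <- FALSE; odt <- NA_character_
      for (k in kids) rdfxml_property_into(st, obj, k, rdf_ns)
      st$s <- c(st$s, subj); st$p <- c(st$p, pred); st$o <- c(st$o, obj)
      st$o_lit <- c(st$o_lit, FALSE); st$o_dt <- c(st$o_dt, NA_character_)
      next
    } else if (length(kids) == 1L) {
      obj <- rdfxml_node(st, kids[[1]], rdf_ns); lit <- FALSE; odt <- NA_character_
    } else {
      obj <- xml2::xml_text(prop); lit <- TRUE
      odt <- if (!is.na(dt)) dt else XSD_STRING
    }
    st$s <- c(st$s, subj); st$p <- c(st$p, pred); st$o <- c(st$o, obj)
    st$o_lit <- c(st$o_lit, lit); st$o_dt <- c(st$o_dt, odt)
  }
  subj
}

rdfxml_property_into <- function(st, subj, prop, rdf_ns) {
  pred <- rdfxml_expand(prop)
  res <- rdf_attr(prop, "resource", rdf_ns)
  dt <- rdf_attr(prop, "datatype", rdf_ns)
  kids <- Filter(function(k) xml2::xml_type(k) == "element", xml2::xml_children(prop))
  if (!is.na(res)) {
    st$s <- c(st$s, subj); st$p <- c(st$p, pred); st$o <- c(st$o, res)
    st$o_lit <- c(st$o_lit, FALSE); st$o_dt <- c(st$o_dt, NA_character_)
  } else if (length(kids) == 1L) {
    obj <- rdfxml_node(st, kids[[1]], rdf_ns)
    st$s <- c(st$s, subj); st$p <- c(st$p, pred); st$o <- c(st$o, obj)
    st$o_lit <- c(st$o_lit, FALSE); st$o_dt <- c(st$o_dt, NA_character_)
  } else {
    st$s <- c(st$s, subj); st$p <- c(st$p, pred); st$o <- c(st$o, xml2::xml_text(prop))
    st$o_lit <- c(st$o_lit, TRUE)
    st$o_dt <- c(st$o_dt, if (!is.na(dt)) dt else XSD_STRING)
  }
}

#' Parse an RDF file, dispatching on extension
#'
#' `.ttl` is read as Turtle, `.nt` as N-Triples, `.rdf`/`.owl`/`.xml` as
#' RDF/XML.
#'
#' @param path file path.
#' @return a triple table.
#' @export
parse_rdf_file <- function(path) {
  if (!file.exists(path)) stop(sprintf("file not found: %s", path), call. = FALSE)
  ext <- tolower(tools::file_ext(path))
  switch(ext,
    ttl = parse_turtle(readLines(path, warn = FALSE), file = path),
    nt = parse_ntriples(readLines(path, warn = FALSE), file = path),
    rdf = , owl = , xml = parse_rdfxml(path),
    stop(sprintf("unsupported RDF file extension '.%s' for %s (use .ttl, .nt, .rdf, .owl)",
                 ext, path), call. = FALSE)
  )
}

#' Serialize a triple table as Turtle
#'
#' Output is deterministic: subjects, predicates and objects appear in byte
#' order, grouped with `;`/`,` continuation.
#'
#' @param triples a triple table.
#' @param path optional file path; when `NULL` the text is returned.
#' @param prefixes named character vector mapping prefix labels to namespace
#'   IRIs; matching IRIs are abbreviated.
#' @return invisibly, the Turtle text as a character vector of lines.
#' @export
write_turtle <- function(triples, path = NULL, prefixes = c()) {
  fmt_iri <- function(iri) {
    for (px in names(prefixes)) {
      ns <- prefixes[[px]]
      if (startsWith(iri, ns)) {
        local <- substr(iri, nchar(ns) + 1L, nchar(iri))
        if (grepl("^[A-Za-z0-9_][A-Za-z0-9_-]*$", local) || local == "")
          return(paste0(px, ":", local))
      }
    }
    paste0("<", iri, ">")
  }
  fmt_obj <- function(o, lit, dt) {
    if (!lit) return(fmt_iri(o))
    lex <- paste0('"', escape_ntriples(o), '"')
    if (identical(dt, XSD_STRING)) lex else paste0(lex, "^^", fmt_iri(dt))
  }
  out <- character()
  for (px in names(prefixes)) out <- c(out, sprintf("@prefix %s: <%s> .", px, prefixes[[px]]))
  if (length(out)) out <- c(out, "")
  tr <- sort_triples(triples)
  for (s in unique(tr$s)) {
    rows <- tr[tr$s == s, , drop = FALSE]
    plines <- character()
    for (p in unique(rows$p)) {
      prow <- rows[rows$p == p, , drop = FALSE]
      objs <- mapply(fmt_obj, prow$o, prow$o_lit, prow$o_dt, USE.NAMES = FALSE)
      pname <- if (p == RDF_TYPE) "a" else fmt_iri(p)
      plines <- c(plines, paste0("    ", pname, " ", paste(objs, collapse = ", ")))
    }
    out <- c(out, paste0(fmt_iri(s)), paste0(plines, c(rep(" ;", length(plines) - 1L), " .")), "")
  }
  if (!is.null(path)) writeLines(out, path, useBytes = TRUE)
  invisible(out)
}
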
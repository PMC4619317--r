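# structure-RDF: the package's own vocabulary for persisting a recovered
# structure, and its reader. The encoding budget is fixed: exactly 2
# triples per class, 1 per subclass edge, 2 per class property and 6 per
# unique type link (so at most 8 link-attributable triples per link).

VOCAB <- "http://rdfstruct.org/ns#"
RDFS_NS <- "http://www.w3.org/2000/01/rdf-schema#"
OWL_NS <- "http://www.w3.org/2002/07/owl#"
XSD_INT <- "http://www.w3.org/2001/XMLSchema#integer"

vs <- function(x) paste0(VOCAB, x)

KIND_TO_TYPE <- c(class = "ClassLink", datatype = "DatatypeLink",
                  external = "ExternalLink", invalid = "InvalidLink")
MULT_TO_IND <- c("1..1" = "M1_1", "1..N" = "M1_N", "0..1" = "M0_1",
                 "0..N" = "M0_N", "not_determined" = "Mnd")

# stable, collision-free node IRIs from content hashes
hash_ids <- function(values, prefix) {
  if (length(values) == 0) return(character(0))
  h <- fnv1a32(values)
  dup <- duplicated(h) | duplicated(h, fromLast = TRUE)
  if (any(dup)) h[dup] <- paste0(h[dup], "x", ave(seq_along(h), h, FUN = seq_along)[dup])
  paste0(VOCAB, prefix, h)
}

#' Export a structure graph as structure-RDF (Turtle)
#'
#' @param s a `structure_graph`.
#' @param path output file; when `NULL` the Turtle lines are returned.
#' @return invisibly, the Turtle text.
#' @export
export_structure_rdf <- function(s, path = NULL) {
  stopifnot(inherits(s, "structure_graph"))
  nodes <- s$class_tree$nodes
  edges <- s$class_tree$edges
  links <- s$links
  S <- P <- O <- character(0); L <- logical(0); D <- character(0)
  add <- function(s_, p_, o_, lit = FALSE, dt = NA_character_) {
    S <<- c(S, s_); P <<- c(P, p_); O <<- c(O, o_); L <<- c(L, lit); D <<- c(D, dt)
  }
  for (i in seq_len(nrow(nodes))) {
    add(nodes$class[i], RDF_TYPE, vs("Class"))
    add(nodes$class[i], vs("instances"), as.character(nodes$instances[i]), TRUE, XSD_INT)
  }
  for (i in seq_len(nrow(edges))) add(edges$child[i], RDFS_SUBCLASS, edges$parent[i])
  if (nrow(links)) {
    cp_key <- paste(links$subject_type, links$predicate, sep = "\r")
    cps <- unique(data.frame(owner = links$subject_type, predicate = links$predicate,
                             key = cp_key, stringsAsFactors = FALSE))
    cps$iri <- hash_ids(cps$key, "cp-")
    for (i in seq_len(nrow(cps))) {
      add(cps$owner[i], vs("classProperty"), cps$iri[i])
      add(cps$iri[i], vs("predicate"), cps$predicate[i])
    }
    link_iri <- hash_ids(paste(cp_key, links$object_type, links$object_kind, sep = "\r"),
                         "link-")
    cp_of <- cps$iri[match(cp_key, cps$key)]
    for (i in seq_len(nrow(links))) {
      add(cp_of[i], vs("link"), link_iri[i])
      add(link_iri[i], RDF_TYPE, vs(KIND_TO_TYPE[[links$object_kind[i]]]))
      add(link_iri[i], vs("target"), links$object_type[i])
      add(link_iri[i], vs("count"), as.character(links$count[i]), TRUE, XSD_INT)
      add(link_iri[i], vs("forward"), vs(MULT_TO_IND[[links$forward[i]]]))
      add(link_iri[i], vs("reverse"), vs(MULT_TO_IND[[links$reverse[i]]]))
    }
  }
  tr <- rdf_triples(S, P, O, L, D)
  txt <- write_turtle(tr, path = path,
                      prefixes = c(vs = VOCAB,
                                   rdf = "http://www.w3.org/1999/02/22-rdf-syntax-ns#",
                                   rdfs = RDFS_NS,
                                   xsd = XSD_NS))
  invisible(txt)
}

#' Read a structure-RDF file back into a structure graph
#'
#' Inverse of [export_structure_rdf()] up to the integrity findings (which
#' are re-derivable from the source resource, not serialized) and
#' truncation flags. Files missing reverse multiplicities get
#' `not_determined`.
#'
#' @param path a Turtle file produced by [export_structure_rdf()].
#' @return a `structure_graph`.
#' @export
import_structure_rdf <- function(path) {
  tr <- parse_rdf_file(path)
  type_of <- function(ss) tr$o[tr$p == RDF_TYPE & tr$s %in% ss]
  cls <- sort(tr$s[tr$p == RDF_TYPE & tr$o == vs("Class")], method = "radix")
  inst <- rep(0L, length(cls))
  iv <- tr[tr$p == vs("instances"), , drop = FALSE]
  m <- match(cls, iv$s)
  inst[!is.na(m)] <- as.integer(iv$o[m[!is.na(m)]])
  classes <- data.frame(class = cls, instances = inst, stringsAsFactors = FALSE)
  sub <- tr[tr$p == RDFS_SUBCLASS, c("s", "o"), drop = FALSE]
  tree <- detect_concept_classes(build_class_tree(
    classes, data.frame(child = sub$s, parent = sub$o, stringsAsFactors = FALSE)))
  ind_to_mult <- stats::setNames(names(MULT_TO_IND), vs(MULT_TO_IND))
  type_to_kind <- stats::setNames(names(KIND_TO_TYPE), vs(KIND_TO_TYPE))
  cp_rows <- tr[tr$p == vs("classProperty"), c("s", "o"), drop = FALSE]
  cp_owner <- stats::setNames(cp_rows$s, cp_rows$o)
  cp_pred_rows <- tr[tr$p == vs("predicate"), c("s", "o"), drop = FALSE]
  cp_pred <- stats::setNames(cp_pred_rows$o, cp_pred_rows$s)
  link_rows <- tr[tr$p == vs("link"), c("s", "o"), drop = FALSE]
  out <- list()
  for (i in seq_len(nrow(link_rows))) {
    cp <- link_rows$s[i]; ln <- link_rows$o[i]
    if (is.na(cp_owner[cp]) || is.na(cp_pred[cp])) {
      stop(sprintf("structure-RDF schema error: class property <%s> lacks owner or predicate", cp),
           call. = FALSE)
    }
    get1 <- function(p_) tr$o[tr$s == ln & tr$p == p_]
    target <- get1(vs("target"))
    cnt <- get1(vs("count"))
    ty <- type_of(ln)
    kind <- type_to_kind[ty[ty %in% names(type_to_kind)]]
    if (length(target) != 1 || length(cnt) != 1 || length(kind) != 1) {
      stop(sprintf("structure-RDF schema error: link node <%s> is missing target, count or kind",
                   ln), call. = FALSE)
    }
    fwd <- get1(vs("forward")); rev <- get1(vs("reverse"))
    out[[length(out) + 1L]] <- data.frame(
      subject_type = unname(cp_owner[cp]), predicate = unname(cp_pred[cp]),
      object_type = target, object_kind = unname(kind),
      count = as.integer(cnt),
      forward = if (length(fwd) == 1) unname(ind_to_mult[fwd]) else "not_determined",
      reverse = if (length(rev) == 1) unname(ind_to_mult[rev]) else "not_determined",
      stringsAsFactors = FALSE)
  }
  links <- if (length(out)) do.call(rbind, out) else {
    data.frame(subject_type = character(), predicate = character(),
               object_type = character(), object_kind = character(),
               count = integer(), forward = character(), reverse = character(),
               stringsAsFactors = FALSE)
  }
  if (anyNA(links$forward) || anyNA(links$reverse)) {
    stop("structure-RDF schema error: unknown multiplicity individual", call. = FALSE)
  }
  links <- reset_rownames(links[order(links$subject_type, links$predicate,
                                      links$object_type, links$object_kind,
                                      method = "radix"), , drop = FALSE])
  structure_graph(tree, links, namespaces = character())
}

#' Structural equality of two structure graphs
#'
#' Compares classes (IRIs, instance counts, concept flags), subclass edges
#' and unique type links with counts and multiplicities. Findings,
#' truncation flags and provenance metadata are ignored (they are not part
#' of the serialized contract).
#'
#' @param a,b `structure_graph` objects.
#' @return logical.
#' @export
structure_equal <- function(a, b) {
  norm_nodes <- function(s) {
    n <- s$class_tree$nodes[, c("class", "instances", "concept")]
    reset_rownames(n[order(n$class, method = "radix"), ])
  }
  norm_edges <- function(s) {
    e <- s$class_tree$edges
    reset_rownames(e[order(e$child, e$parent, method = "radix"), ])
  }
  norm_links <- function(s) {
    l <- s$links[, c("subject_type", "predicate", "object_type", "object_kind",
                     "count", "forward", "reverse")]
    reset_rownames(l[order(l$subject_type, l$predicate, l$object_type,
                           l$object_kind, method = "radix"), ])
  }
  isTRUE(all.equal(norm_nodes(a), norm_nodes(b))) &&
    isTRUE(all.equal(norm_edges(a), norm_edges(b))) &&
    isTRUE(all.equal(norm_links(a), norm_links(b)))
}
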
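# XGMML network export (Cytoscape 3.x dialect).

XGMML_NS <- "http://www.cs.rpi.edu/XGMML"

#' Export a structure graph as XGMML
#'
#' One node per type: every class in the tree (concept classes optionally
#' hidden), plus the datatype (optionally hidden), external and invalid
#' target types of the surviving links. One edge per unique type link and
#' per direct subClassOf pair; edges touching hidden nodes are dropped.
#'
#' @param s a `structure_graph`.
#' @param path output file; `NULL` returns the xml2 document.
#' @param hide_concepts drop concept-class nodes (GO-style vocabularies).
#' @param hide_datatypes drop datatype nodes, as in typical published
#'   network views.
#' @return invisibly, the `xml_document`.
#' @export
export_xgmml <- function(s, path = NULL, hide_concepts = FALSE, hide_datatypes = FALSE) {
  stopifnot(inherits(s, "structure_graph"))
  nodes <- s$class_tree$nodes
  keep_cls <- nodes$class
  if (hide_concepts) keep_cls <- nodes$class[!(nodes$concept %in% TRUE)]
  links <- s$links
  extra <- unique(links[links$object_kind != "class",
                        c("object_type", "object_kind"), drop = FALSE])
  if (hide_datatypes) extra <- extra[extra$object_kind != "datatype", , drop = FALSE]
  node_df <- rbind(
    data.frame(iri = keep_cls, kind = rep("class", length(keep_cls)),
               instances = nodes$instances[match(keep_cls, nodes$class)],
               concept = nodes$concept[match(keep_cls, nodes$class)] %in% TRUE,
               stringsAsFactors = FALSE),
    if (nrow(extra)) data.frame(iri = extra$object_type, kind = extra$object_kind,
                                instances = NA_integer_, concept = FALSE,
                                stringsAsFactors = FALSE))
  node_df <- unique(node_df)
  # a type can be both a class and, say, an external marker under the same
  # IRI only artificially; keep first (class) classification
  node_df <- node_df[!duplicated(node_df$iri), , drop = FALSE]
  node_df <- reset_rownames(node_df[order(node_df$iri, method = "radix"), , drop = FALSE])
  node_df$id <- hash_ids(node_df$iri, "n")
  node_df$id <- sub(VOCAB, "", node_df$id, fixed = TRUE)

  doc <- xml2::xml_new_root("graph", label = "recovered RDF structure",
                            directed = "1", xmlns = XGMML_NS)
  att <- function(parent, name, value, type = "string") {
    xml2::xml_add_child(parent, "att", name = name, value = as.character(value),
                        type = type)
  }
  for (i in seq_len(nrow(node_df))) {
    nd <- xml2::xml_add_child(doc, "node", id = node_df$id[i],
                              label = local_name(node_df$iri[i]))
    att(nd, "iri", node_df$iri[i])
    att(nd, "kind", node_df$kind[i])
    if (!is.na(node_df$instances[i])) att(nd, "instanceCount", node_df$instances[i], "integer")
    att(nd, "concept", tolower(as.character(node_df$concept[i])), "boolean")
  }
  id_of <- stats::setNames(node_df$id, node_df$iri)
  edge_n <- 0L
  for (i in seq_len(nrow(links))) {
    src <- id_of[links$subject_type[i]]; dst <- id_of[links$object_type[i]]
    if (is.na(src) || is.na(dst)) next  # touches a hidden node
    edge_n <- edge_n + 1L
    ed <- xml2::xml_add_child(doc, "edge", source = unname(src), target = unname(dst),
                              label = local_name(links$predicate[i]))
    att(ed, "kind", "typelink")
    att(ed, "predicate", links$predicate[i])
    att(ed, "count", links$count[i], "integer")
    att(ed, "forward", links$forward[i])
    att(ed, "reverse", links$reverse[i])
  }
  edges <- s$class_tree$edges
  for (i in seq_len(nrow(edges))) {
    src <- id_of[edges$child[i]]; dst <- id_of[edges$parent[i]]
    if (is.na(src) || is.na(dst)) next
    ed <- xml2::xml_add_child(doc, "edge", source = unname(src), target = unname(dst),
                              label = "subClassOf")
    att(ed, "kind", "subClassOf")
  }
  if (!is.null(path)) xml2::write_xml(doc, path)
  invisible(doc)
}
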
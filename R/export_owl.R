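# OWL 2 export in RDF/XML: property declarations with domain/range,
# per-class allValuesFrom restrictions with qualified cardinalities derived
# from the forward multiplicities, optional inverse restrictions from the
# reverse multiplicities, and the subClassOf axioms of the class tree.

#' Export a structure graph as an OWL 2 ontology (RDF/XML)
#'
#' Multiplicity mapping: `1..1` adds `owl:qualifiedCardinality 1`, `1..N`
#' adds `owl:minQualifiedCardinality 1`, `0..1` adds
#' `owl:maxQualifiedCardinality 1`, `0..N` and `not_determined` add no
#' cardinality axiom. Links with invalid targets have no OWL counterpart
#' and are skipped (reported through the integrity findings instead).
#'
#' @param s a `structure_graph`.
#' @param path output file; `NULL` returns the xml2 document.
#' @param include_inverse also emit restrictions on the target classes via
#'   `owl:inverseOf` expressing the reverse multiplicities.
#' @return invisibly, the `xml_document`.
#' @export
export_owl <- function(s, path = NULL, include_inverse = FALSE) {
  stopifnot(inherits(s, "structure_graph"))
  links <- s$links[s$links$object_kind != "invalid", , drop = FALSE]
  rdf_ns <- "http://www.w3.org/1999/02/22-rdf-syntax-ns#"
  doc <- xml2::xml_new_root("rdf:RDF",
                            "xmlns:rdf" = rdf_ns,
                            "xmlns:rdfs" = RDFS_NS,
                            "xmlns:owl" = OWL_NS,
                            "xmlns:xsd" = XSD_NS)
  xml2::xml_add_child(doc, "owl:Ontology", "rdf:about" = paste0(VOCAB, "exported"))

  res_attr <- function(node, name, iri) {
    xml2::xml_add_child(node, name, "rdf:resource" = iri)
  }
  union_class <- function(parent, name, iris) {
    if (length(iris) == 1) return(res_attr(parent, name, iris))
    el <- xml2::xml_add_child(parent, name)
    cl <- xml2::xml_add_child(el, "owl:Class")
    un <- xml2::xml_add_child(cl, "owl:unionOf", "rdf:parseType" = "Collection")
    for (i in iris) xml2::xml_add_child(un, "owl:Class", "rdf:about" = i)
    el
  }

  # property declarations with domain and range unions
  for (p in sort(unique(links$predicate), method = "radix")) {
    lp <- links[links$predicate == p, , drop = FALSE]
    dtype <- lp$object_kind == "datatype"
    if (any(!dtype)) {
      prop <- xml2::xml_add_child(doc, "owl:ObjectProperty", "rdf:about" = p)
      union_class(prop, "rdfs:domain", sort(unique(lp$subject_type[!dtype]), method = "radix"))
      union_class(prop, "rdfs:range", sort(unique(lp$object_type[!dtype]), method = "radix"))
    }
    if (any(dtype)) {
      prop <- xml2::xml_add_child(doc, "owl:DatatypeProperty", "rdf:about" = p)
      union_class(prop, "rdfs:domain", sort(unique(lp$subject_type[dtype]), method = "radix"))
      for (r in sort(unique(lp$object_type[dtype]), method = "radix")) {
        res_attr(prop, "rdfs:range", r)
      }
    }
  }

  card_restriction <- function(parent, pred, link, inverse = FALSE) {
    mult <- if (inverse) link$reverse else link$forward
    spec <- switch(mult,
                   "1..1" = c("owl:qualifiedCardinality", "1"),
                   "1..N" = c("owl:minQualifiedCardinality", "1"),
                   "0..1" = c("owl:maxQualifiedCardinality", "1"),
                   NULL)
    if (is.null(spec)) return(invisible(NULL))
    sub <- xml2::xml_add_child(parent, "rdfs:subClassOf")
    restr <- xml2::xml_add_child(sub, "owl:Restriction")
    if (inverse) {
      onp <- xml2::xml_add_child(restr, "owl:onProperty")
      pdesc <- xml2::xml_add_child(onp, "rdf:Description")
      res_attr(pdesc, "owl:inverseOf", pred)
    } else {
      res_attr(restr, "owl:onProperty", pred)
    }
    card <- xml2::xml_add_child(restr, spec[1], spec[2])
    xml2::xml_set_attr(card, "rdf:datatype", paste0(XSD_NS, "nonNegativeInteger"))
    onx <- if (!inverse && link$object_kind == "datatype") "owl:onDataRange" else "owl:onClass"
    res_attr(restr, onx, if (inverse) link$subject_type else link$object_type)
    invisible(restr)
  }

  classes <- s$class_tree$nodes$class
  edges <- s$class_tree$edges
  for (cl in classes) {
    el <- xml2::xml_add_child(doc, "owl:Class", "rdf:about" = cl)
    for (pa in sort(edges$parent[edges$child == cl], method = "radix")) {
      res_attr(el, "rdfs:subClassOf", pa)
    }
    lc <- links[links$subject_type == cl, , drop = FALSE]
    for (p in sort(unique(lc$predicate), method = "radix")) {
      lp <- lc[lc$predicate == p, , drop = FALSE]
      # allValuesFrom over the class property's targets (an or-union when
      # the class property groups several links)
      sub <- xml2::xml_add_child(el, "rdfs:subClassOf")
      restr <- xml2::xml_add_child(sub, "owl:Restriction")
      res_attr(restr, "owl:onProperty", p)
      union_class(restr, "owl:allValuesFrom",
                  sort(unique(lp$object_type), method = "radix"))
      for (i in seq_len(nrow(lp))) card_restriction(el, p, lp[i, ])
    }
    if (include_inverse) {
      lt <- links[links$object_type == cl & links$object_kind == "class", , drop = FALSE]
      for (i in seq_len(nrow(lt))) card_restriction(el, lt$predicate[i], lt[i, ], inverse = TRUE)
    }
  }
  n_invalid <- sum(s$links$object_kind == "invalid")
  if (n_invalid) {
    message(sprintf("export_owl: skipped %d link(s) with invalid targets (no OWL counterpart)",
                    n_invalid))
  }
  if (!is.null(path)) xml2::write_xml(doc, path)
  invisible(doc)
}
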
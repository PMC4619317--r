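# structure-RDF round trip with its encoding budget, XGMML, OWL, ShEx and
# the integrity report.

ex <- "http://example.org/"

full_structure <- function(seed = 21) {
  fx <- generate_fixture(fixture_spec(
    tree_depth = 2, branching = 2, instances_per_class = c(0, 5),
    predicates = list(list(name = "p1", target = "class", forward = "1..1"),
                      list(name = "p2", target = "datatype", forward = "0..N"),
                      list(name = "p3", target = "external", forward = "0..1")),
    fraction_untyped = 0.4, seed = seed))
  simplify_structure(recover_structure(fx$graph))
}

test_that("structure-RDF round trip is lossless within its triple budget", {
  s <- full_structure()
  f <- withr::local_tempfile(fileext = ".ttl")
  export_structure_rdf(s, f)
  s2 <- import_structure_rdf(f)
  expect_true(structure_equal(s, s2))
  # budget: exactly 2 per class, 1 per subclass edge, <= 8 per link
  tr <- parse_rdf_file(f)
  C <- nrow(s$class_tree$nodes); E <- nrow(s$class_tree$edges); L <- nrow(s$links)
  CP <- nrow(class_properties(s))
  expect_equal(nrow(tr), 2 * C + E + 2 * CP + 6 * L)
  expect_lte(2 * CP + 6 * L, 8 * L)
})

test_that("an empty structure exports to a prologue-only file", {
  s <- structure_graph(build_class_tree(data.frame(class = character(),
                                                   instances = integer()),
                                        data.frame(child = character(),
                                                   parent = character())),
                       recover_structure(memory_graph(rdf_triples(), ex))$links)
  f <- withr::local_tempfile(fileext = ".ttl")
  export_structure_rdf(s, f)
  expect_equal(nrow(parse_rdf_file(f)), 0)
})

test_that("a truncated structure-RDF file raises a schema error naming the node", {
  s <- full_structure()
  f <- withr::local_tempfile(fileext = ".ttl")
  export_structure_rdf(s, f)
  lines <- readLines(f)
  drop <- grep("vs:target", lines)[1]
  writeLines(lines[-drop], f)
  expect_error(import_structure_rdf(f), "schema error.*link node")
})

test_that("files without reverse multiplicities default to not_determined", {
  s <- full_structure()
  f <- withr::local_tempfile(fileext = ".ttl")
  export_structure_rdf(s, f)
  lines <- readLines(f)
  writeLines(lines[!grepl("vs:reverse", lines)], f)
  s2 <- import_structure_rdf(f)
  expect_true(all(s2$links$reverse == "not_determined"))
  expect_equal(s2$links$forward, s$links$forward)
})

test_that("XGMML is well-formed with complete node and edge attributes", {
  s <- full_structure()
  f <- withr::local_tempfile(fileext = ".xgmml")
  export_xgmml(s, f)
  doc <- xml2::read_xml(f)
  ns <- xml2::xml_ns_rename(xml2::xml_ns(doc), d1 = "x")
  nodes <- xml2::xml_find_all(doc, ".//x:node", ns)
  n_types <- nrow(s$class_tree$nodes) +
    length(unique(s$links$object_type[s$links$object_kind != "class"]))
  expect_equal(length(nodes), n_types)
  ids <- xml2::xml_attr(nodes, "id")
  expect_false(any(duplicated(ids)))
  edges <- xml2::xml_find_all(doc, ".//x:edge", ns)
  expect_equal(length(edges), nrow(s$links) + nrow(s$class_tree$edges))
  expect_true(all(xml2::xml_attr(edges, "source") %in% ids))
  expect_true(all(xml2::xml_attr(edges, "target") %in% ids))
  tl <- edges[vapply(edges, function(e) {
    any(xml2::xml_attr(xml2::xml_find_all(e, ".//x:att", ns), "name") == "forward")
  }, logical(1))]
  expect_equal(length(tl), nrow(s$links))
})

read_xgmml <- function(s, ...) {
  f <- tempfile(fileext = ".xgmml")
  on.exit(unlink(f))
  export_xgmml(s, f, ...)
  xml2::read_xml(f)
}

test_that("XGMML hide flags drop the nodes and their edges", {
  s <- full_structure()
  stopifnot(any(s$links$object_kind == "datatype"))
  doc <- read_xgmml(s, hide_datatypes = TRUE, hide_concepts = TRUE)
  ns <- xml2::xml_ns_rename(xml2::xml_ns(doc), d1 = "x")
  kinds <- xml2::xml_attr(xml2::xml_find_all(
    doc, ".//x:node/x:att[@name='kind']", ns), "value")
  expect_false("datatype" %in% kinds)
  concepts <- xml2::xml_attr(xml2::xml_find_all(
    doc, ".//x:node/x:att[@name='concept']", ns), "value")
  expect_false("true" %in% concepts)
  # worked example: two class nodes, one 1..1/1..N edge
  gs <- simplify_structure(recover_structure(mem_example("gene_chromosome")))
  gd <- read_xgmml(gs)
  gns <- xml2::xml_ns_rename(xml2::xml_ns(gd), d1 = "x")
  expect_equal(length(xml2::xml_find_all(gd, ".//x:node", gns)), 2)
  fwd <- xml2::xml_attr(xml2::xml_find_all(gd, ".//x:edge/x:att[@name='forward']", gns), "value")
  rev <- xml2::xml_attr(xml2::xml_find_all(gd, ".//x:edge/x:att[@name='reverse']", gns), "value")
  expect_equal(fwd, "1..1")
  expect_equal(rev, "1..N")
  empty <- structure_graph(build_class_tree(data.frame(class = character(),
                                                       instances = integer()),
                                            data.frame(child = character(),
                                                       parent = character())),
                           gs$links[0, ])
  ed <- read_xgmml(empty)
  ens <- xml2::xml_ns(ed)
  expect_equal(length(xml2::xml_find_all(ed, ".//d1:node", ens)), 0)
})

test_that("OWL export carries restriction axioms per the multiplicity mapping", {
  s <- full_structure()
  f <- withr::local_tempfile(fileext = ".owl")
  suppressMessages(export_owl(s, f, include_inverse = TRUE))
  doc <- xml2::read_xml(f)
  # well-formed XML that re-serializes stably
  f2 <- withr::local_tempfile(fileext = ".owl")
  xml2::write_xml(doc, f2)
  expect_identical(readLines(f), readLines(f2))
  # and our independent RDF/XML reader accepts it
  expect_silent(tr <- parse_rdfxml(f))
  owl <- "http://www.w3.org/2002/07/owl#"
  restr <- tr[tr$p == paste0(owl, "onProperty"), ]
  expect_gt(nrow(restr), 0)
  # per-link cardinality tokens
  for (i in seq_len(nrow(s$links))) {
    lk <- s$links[i, ]
    if (lk$object_kind == "invalid") next
    expected <- switch(lk$forward,
                       "1..1" = "qualifiedCardinality",
                       "1..N" = "minQualifiedCardinality",
                       "0..1" = "maxQualifiedCardinality", NULL)
    if (is.null(expected)) next
    hit <- tr$s[tr$p == paste0(owl, expected)]
    on_cls <- tr[tr$p %in% paste0(owl, c("onClass", "onDataRange")), ]
    expect_true(any(on_cls$s %in% hit & on_cls$o == lk$object_type),
                info = paste(lk$predicate, lk$forward))
  }
  # invalid links are skipped with a message
  expect_message(export_owl(s), "skipped")
})

test_that("OWL export of a link-free structure has only class axioms", {
  g <- memory_graph(rdf_triples(s = paste0(ex, "A"), p = RDFS_SUBCLASS,
                                o = paste0(ex, "B")), ex)
  f <- withr::local_tempfile(fileext = ".owl")
  export_owl(recover_structure(g), f)
  doc <- xml2::read_xml(f)
  expect_equal(length(xml2::xml_find_all(doc, "//owl:Restriction")), 0)
  expect_equal(length(xml2::xml_find_all(doc, "//owl:Class[@rdf:about]")), 2)
})

test_that("ShExC output parses and maps multiplicities to cardinalities", {
  s <- full_structure()
  lines <- export_shex(s)
  expect_true(shexc_parse_ok(lines))
  # every shape label is a class with instances
  shapes <- sub(" \\{$", "", grep("\\{$", lines, value = TRUE))
  shapes <- gsub("[<>]", "", shapes)
  with_inst <- s$class_tree$nodes$class[s$class_tree$nodes$instances > 0]
  expect_true(all(shapes %in% with_inst))
  # gene fixture: 1..1 gives a bare constraint
  gl <- export_shex(simplify_structure(recover_structure(mem_example("gene_chromosome"))))
  expect_true(shexc_parse_ok(gl))
  con <- grep("locatedOn", gl, value = TRUE)
  expect_match(con, "@<http://example.org/Chromosome>$")
  # or-group for a class property with several links
  tr <- rdf_triples(
    s = c(paste0(ex, c("i1", "t1", "t2")), paste0(ex, c("i1", "i1"))),
    p = c(rep(RDF_TYPE, 3), rep(paste0(ex, "p"), 2)),
    o = c(paste0(ex, c("X", "Y1", "Y2")), paste0(ex, c("t1", "t2"))))
  sl <- export_shex(recover_structure(memory_graph(tr, ex)))
  expect_true(shexc_parse_ok(sl))
  expect_match(paste(sl, collapse = "\n"), "\\( <http://example.org/p> .* \\| <http://example.org/p> .* \\)")
  # 0..N literal link renders as xsd:string *
  fx <- generate_fixture(fixture_spec(
    predicates = list(list(name = "pl", target = "datatype", forward = "0..N")),
    instances_per_class = 4, seed = 3))
  dl <- export_shex(recover_structure(fx$graph))
  expect_match(grep("org/pl>", dl, value = TRUE), "xsd:string \\*")
})

test_that("integrity report counts the seeded defects exactly", {
  fx <- generate_fixture(fixture_spec(instances_per_class = 10,
                                      fraction_untyped = 0.3, seed = 4))
  s <- recover_structure(fx$graph)
  rep <- integrity_report(s)
  expect_equal(sum(rep$kind == "untyped_subject_with_properties"), 3)
  expect_equal(sum(rep$kind == "undetermined_multiplicity"), 1)
  f <- withr::local_tempfile(fileext = ".txt")
  integrity_report(s, f)
  expect_match(readLines(f)[1], "^4 issues")

  cds <- mem_example("cds_collision")
  rc <- integrity_report(recover_structure(cds))
  expect_equal(sum(rc$kind == "predicate_also_class"), 1)
  expect_match(rc$subject[rc$kind == "predicate_also_class"], "CDS")

  clean <- integrity_report(recover_structure(mem_example("gene_chromosome")))
  expect_equal(nrow(clean), 0)
  expect_equal(attr(clean, "report"), "0 issues")
})
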
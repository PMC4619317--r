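# Object classification, type-link extraction, multiplicity rules,
# concept classes.

ex <- "http://example.org/"
xsd_int <- "http://www.w3.org/2001/XMLSchema#integer"

test_that("classify_object covers the four object kinds", {
  g <- mem_example("gene_chromosome")
  lit <- classify_object("17", o_lit = TRUE, o_dt = xsd_int, g = g, namespaces = ex)
  expect_equal(lit, data.frame(object_type = xsd_int, object_kind = "datatype",
                               stringsAsFactors = FALSE))
  cls <- classify_object(paste0(ex, "chr1"), g = g, namespaces = ex)
  expect_equal(cls$object_kind, "class")
  expect_equal(cls$object_type, paste0(ex, "Chromosome"))
  extn <- classify_object("http://other.org/id/42", g = g, namespaces = ex)
  expect_equal(extn, data.frame(object_type = "http://other.org/id/",
                                object_kind = "external", stringsAsFactors = FALSE))
  inv <- classify_object(paste0(ex, "orphan"), g = g, namespaces = ex)
  expect_equal(inv, data.frame(object_type = ex, object_kind = "invalid",
                               stringsAsFactors = FALSE))
})

test_that("a multi-typed object yields one classification per type", {
  tr <- rdf_triples(
    s = c(paste0(ex, "o"), paste0(ex, "o"), paste0(ex, "s"), paste0(ex, "s")),
    p = c(RDF_TYPE, RDF_TYPE, RDF_TYPE, paste0(ex, "p")),
    o = c(paste0(ex, "A"), paste0(ex, "B"), paste0(ex, "C"), paste0(ex, "o")))
  g <- memory_graph(tr, ex)
  cls <- classify_object(paste0(ex, "o"), g = g, namespaces = ex)
  expect_equal(cls$object_type, paste0(ex, c("A", "B")))
})

test_that("extract_type_links crosses subject types with object classifications", {
  # a subject with two declared types produces two type links
  tr <- rdf_triples(
    s = c(paste0(ex, "s"), paste0(ex, "s"), paste0(ex, "o"), paste0(ex, "s")),
    p = c(RDF_TYPE, RDF_TYPE, RDF_TYPE, paste0(ex, "p")),
    o = c(paste0(ex, "A"), paste0(ex, "B"), paste0(ex, "C"), paste0(ex, "o")))
  g <- memory_graph(tr, ex)
  exl <- extract_type_links(g)
  expect_equal(exl$links$subject_type, paste0(ex, c("A", "B")))
  expect_equal(exl$links$object_type, rep(paste0(ex, "C"), 2))
  expect_equal(exl$links$count, c(1L, 1L))
  # worked example: one statement, one link
  gg <- mem_example("gene_chromosome")
  el <- extract_type_links(gg)
  expect_equal(nrow(el$links), 1)
  expect_equal(el$links$subject_type, paste0(ex, "Gene"))
  expect_equal(el$links$object_kind, "class")
})

test_that("classify_forward implements the four-way rule and its contract", {
  expect_equal(classify_forward(3, c(1, 1, 1)), "1..1")
  expect_equal(classify_forward(2, c(5, 1)), "1..N")
  expect_equal(classify_forward(3, c(1, 1)), "0..1")
  expect_equal(classify_forward(5, c(2)), "0..N")
  expect_error(classify_forward(3, integer(0)), "zero participating")
  expect_error(classify_forward(1, c(0)), ">= 1")
})

test_that("classify_reverse inverts roles and refuses non-class targets", {
  expect_equal(classify_reverse("class", 2, c(6, 4)), "1..N")
  expect_equal(classify_reverse("datatype", 0, integer(0)), "not_determined")
  expect_equal(classify_reverse("invalid", 0, integer(0)), "not_determined")
})

test_that("truncated predicates force not_determined multiplicities", {
  fx <- generate_fixture(fixture_spec(instances_per_class = 6, seed = 11))
  g <- fx$graph
  g$handle$limit_per_predicate <- 2L
  s <- recover_structure(g)
  trunc <- s$links[s$links$truncated, ]
  expect_gt(nrow(trunc), 0)
  expect_true(all(trunc$forward == "not_determined"))
  expect_true(all(trunc$reverse == "not_determined"))
})

test_that("concept classes require zero instances through the whole subtree", {
  mk_tree <- function(inst) {
    build_class_tree(
      data.frame(class = paste0(ex, c("top", "mid", "leaf")), instances = inst),
      data.frame(child = paste0(ex, c("mid", "leaf")),
                 parent = paste0(ex, c("top", "mid"))))
  }
  t1 <- detect_concept_classes(mk_tree(c(0L, 0L, 0L)))
  expect_true(all(t1$nodes$concept))
  t2 <- detect_concept_classes(mk_tree(c(0L, 0L, 3L)))
  expect_equal(t2$nodes$concept[t2$nodes$class == paste0(ex, "top")], FALSE)
  expect_equal(t2$nodes$concept[t2$nodes$class == paste0(ex, "leaf")], FALSE)
  t3 <- detect_concept_classes(mk_tree(c(5L, 0L, 0L)))
  flag <- function(t, n) t$nodes$concept[t$nodes$class == paste0(ex, n)]
  expect_false(flag(t3, "top"))
  expect_true(flag(t3, "mid"))
  expect_true(flag(t3, "leaf"))
})

test_that("multiplicity is monotone under statement deletion", {
  rank_low <- function(m) ifelse(startsWith(m, "1"), 1L, 0L)
  rank_up <- function(m) ifelse(endsWith(m, "N"), 2L, 1L)
  fx <- generate_fixture(fixture_spec(
    instances_per_class = 6,
    predicates = list(list(name = "p1", target = "class", forward = "1..N")),
    seed = 5))
  tr <- fx$triples
  pred_rows <- which(tr$p == paste0(ex, "p1"))
  s0 <- recover_structure(fx$graph)$links
  for (drop in pred_rows[seq_len(min(4, length(pred_rows)))]) {
    g2 <- memory_graph(tr[-drop, ], ex)
    s1 <- recover_structure(g2)$links
    m <- merge(s0, s1, by = c("subject_type", "predicate", "object_type", "object_kind"))
    expect_true(all(rank_low(m$forward.y) <= rank_low(m$forward.x)))
    expect_true(all(rank_up(m$forward.y) <= rank_up(m$forward.x)))
  }
})

test_that("link count sums reconcile with raw statement combinations", {
  for (seed in c(2, 9)) {
    fx <- generate_fixture(random_fixture_spec(seed))
    s <- recover_structure(fx$graph)
    orl <- oracle_links(fx$triples, fx$namespaces)
    by_pred <- function(l) tapply(l$count, l$predicate, sum)
    expect_equal(by_pred(s$links), by_pred(orl))
  }
})
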
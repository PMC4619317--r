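# The queryable-graph contract: enumeration operations, deterministic
# ordering, limits.

ex <- "http://example.org/"

test_that("resource_handle validates its invariants", {
  expect_error(resource_handle(namespaces = ex), "exactly one of")
  expect_error(resource_handle(input = "a.ttl", endpoint = "http://x/", namespaces = ex),
               "exactly one of")
  expect_error(resource_handle(input = "a.ttl", namespaces = character(0)),
               "at least one")
  expect_error(resource_handle(input = "a.ttl", namespaces = ex, limit_per_predicate = 0),
               "positive integer")
  h <- resource_handle(input = "a.ttl", namespaces = ex, limit_per_predicate = 5)
  expect_s3_class(h, "resource_handle")
})

test_that("enumerate_classes lists typed and subclass-only classes with counts", {
  g <- memory_graph(rdf_triples(
    s = c(paste0(ex, "BRCA1"), paste0(ex, "chr17")),
    p = c(RDF_TYPE, RDF_TYPE),
    o = c(paste0(ex, "Gene"), paste0(ex, "Chromosome"))), ex)
  cl <- enumerate_classes(g)
  expect_equal(cl$class, paste0(ex, c("Chromosome", "Gene")))
  expect_equal(cl$instances, c(1L, 1L))

  g2 <- memory_graph(rdf_triples(s = paste0(ex, "X"), p = RDFS_SUBCLASS,
                                 o = paste0(ex, "Y")), ex)
  cl2 <- enumerate_classes(g2)
  expect_equal(cl2$class, paste0(ex, c("X", "Y")))
  expect_equal(cl2$instances, c(0L, 0L))

  gene_g <- mem_example("gene_chromosome")
  cl3 <- enumerate_classes(gene_g)
  expect_equal(cl3$instances[cl3$class == paste0(ex, "Gene")], 10L)
  expect_equal(cl3$instances[cl3$class == paste0(ex, "Chromosome")], 2L)
})

test_that("sameAs between classes is emitted in both directions", {
  g <- memory_graph(rdf_triples(
    s = c(paste0(ex, "i1"), paste0(ex, "i2"), paste0(ex, "A")),
    p = c(RDF_TYPE, RDF_TYPE, OWL_SAMEAS),
    o = c(paste0(ex, "A"), paste0(ex, "B"), paste0(ex, "B"))), ex)
  sl <- enumerate_subclass_links(g)
  expect_equal(nrow(sl), 2)
  expect_setequal(paste(sl$child, sl$parent),
                  c(paste(paste0(ex, "A"), paste0(ex, "B")),
                    paste(paste0(ex, "B"), paste0(ex, "A"))))
  empty <- memory_graph(rdf_triples(), ex)
  expect_equal(nrow(enumerate_subclass_links(empty)), 0)
})

test_that("enumerate_predicates excludes schema predicates and sorts", {
  expect_equal(enumerate_predicates(mem_example("gene_chromosome")),
               paste0(ex, "locatedOn"))
  only_types <- memory_graph(rdf_triples(s = paste0(ex, "x"), p = RDF_TYPE,
                                         o = paste0(ex, "T")), ex)
  expect_equal(enumerate_predicates(only_types), character(0))
  many <- memory_graph(rdf_triples(
    s = rep(paste0(ex, "x"), 5), p = paste0(ex, "p", 5:1),
    o = paste0(ex, "y", 1:5)), ex)
  expect_equal(enumerate_predicates(many), paste0(ex, "p", 1:5))
})

test_that("fetch_statements honors limits with sorted-prefix semantics", {
  g <- mem_example("gene_chromosome")
  full <- fetch_statements(g, paste0(ex, "locatedOn"))
  expect_equal(nrow(full$statements), 10)
  expect_false(full$truncated)
  lim <- fetch_statements(g, paste0(ex, "locatedOn"), limit = 3)
  expect_equal(nrow(lim$statements), 3)
  expect_true(lim$truncated)
  expect_equal(lim$statements, full$statements[1:3, ])
  absent <- fetch_statements(g, paste0(ex, "nosuch"))
  expect_equal(nrow(absent$statements), 0)
  expect_false(absent$truncated)
})

test_that("limit=k always returns a prefix of the unlimited result", {
  for (seed in 1:5) {
    fx <- generate_fixture(random_fixture_spec(seed))
    g <- fx$graph
    for (p in enumerate_predicates(g)) {
      full <- fetch_statements(g, p)$statements
      for (k in unique(c(1, 2, nrow(full)))) {
        pre <- fetch_statements(g, p, limit = k)
        expect_equal(pre$statements, full[seq_len(min(k, nrow(full))), , drop = FALSE])
        expect_equal(pre$truncated, k < nrow(full))
      }
    }
  }
})
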
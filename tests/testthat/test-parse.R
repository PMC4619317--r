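# Turtle / N-Triples / RDF-XML readers and the Turtle writer.

test_that("turtle parsing handles prefixes, 'a', lists, literals and bnodes", {
  ttl <- c(
    "@prefix ex: <http://ex.org/> .",
    "@prefix xsd: <http://www.w3.org/2001/XMLSchema#> .",
    "ex:BRCA1 a ex:Gene ; ex:locatedOn ex:chr17 ; ex:symbol \"BRCA1\" .",
    "ex:chr17 a ex:Chromosome ; ex:length \"83257441\"^^xsd:integer, 83 .",
    "ex:note ex:text \"multi, part; still one\"@en .",
    "_:b1 ex:linksTo ex:BRCA1 .",
    "[] ex:comment \"anon\" .")
  tr <- parse_turtle(ttl)
  expect_equal(nrow(tr), 9)
  expect_true(all(tr$p != ""))
  expect_equal(sum(tr$o_lit), 5)
  ints <- tr[tr$o_lit & grepl("integer$", tr$o_dt), ]
  expect_setequal(ints$o, c("83257441", "83"))
  # language tags collapse onto xsd:string
  expect_equal(tr$o_dt[tr$o == "multi, part; still one"],
               "http://www.w3.org/2001/XMLSchema#string")
  # blank nodes are skolemised deterministically
  expect_true(any(startsWith(tr$s, "urn:skolem:b1")))
  expect_true(any(startsWith(tr$s, "urn:skolem:genid")))
})

test_that("parse errors carry file and line", {
  expect_error(parse_turtle(c("@prefix ex: <http://e/> .", "ex:a ex:b ???" ), file = "x.ttl"),
               "x\\.ttl at line 2")
  expect_error(parse_turtle("ex:a ex:b ex:c ."), "undeclared prefix")
  expect_error(parse_turtle('<a> <b> """long""" .'), "triple-quoted")
  expect_error(parse_turtle("<a> <b> (1 2) ."), "collections")
})

test_that("three-triple and empty files report their statement counts", {
  f <- withr::local_tempfile(fileext = ".ttl")
  writeLines(c("@prefix ex: <http://e.org/> .",
               "ex:g a ex:Gene .", "ex:c a ex:Chr .", "ex:g ex:on ex:c ."), f)
  h <- resource_handle(input = f, namespaces = "http://e.org/")
  expect_equal(graph_size(rdf_load(h)), 3)
  writeLines(character(0), f)
  expect_equal(graph_size(rdf_load(h)), 0)
})

test_that("ntriples round-trips through the turtle writer", {
  tr <- rdf_triples(
    s = c("http://e.org/a", "http://e.org/a"),
    p = c("http://e.org/p", "http://e.org/q"),
    o = c("http://e.org/b", "tricky \"quoted\"\nline"),
    o_lit = c(FALSE, TRUE))
  txt <- write_turtle(tr)
  back <- parse_turtle(txt)
  expect_equal(back, tr)
})

test_that("rdfxml reader covers typed nodes, nested nodes and datatypes", {
  xml <- '<?xml version="1.0"?>
<rdf:RDF xmlns:rdf="http://www.w3.org/1999/02/22-rdf-syntax-ns#"
         xmlns:ex="http://e.org/">
  <ex:Gene rdf:about="http://e.org/BRCA1">
    <ex:locatedOn rdf:resource="http://e.org/chr17"/>
    <ex:length rdf:datatype="http://www.w3.org/2001/XMLSchema#integer">81</ex:length>
    <ex:partner>
      <ex:Gene rdf:about="http://e.org/BRCA2"/>
    </ex:partner>
  </ex:Gene>
</rdf:RDF>'
  tr <- parse_rdfxml(xml)
  expect_equal(nrow(tr), 5)
  expect_true(any(tr$p == "http://e.org/locatedOn" & tr$o == "http://e.org/chr17"))
  expect_true(any(tr$o == "81" & grepl("integer$", tr$o_dt)))
  type_t <- tr[grepl("type$", tr$p), ]
  expect_setequal(type_t$s, c("http://e.org/BRCA1", "http://e.org/BRCA2"))
})

test_that("unsupported extensions and missing files error clearly", {
  expect_error(parse_rdf_file("nope.ttl"), "not found")
  f <- withr::local_tempfile(fileext = ".json")
  writeLines("{}", f)
  expect_error(parse_rdf_file(f), "unsupported RDF file extension")
})
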
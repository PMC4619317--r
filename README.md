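# rdfstruct

Recover, simplify and export the class-level structure of an RDF resource.

Biological knowledge bases increasingly publish their content as RDF
(Reactome, UniProt, ChEBI, genome-annotation stores). Writing SPARQL
queries against such a resource — or validating a resource you generate —
requires knowing its *structure*: which classes exist, which predicates
link them, and with what cardinality. Published ontologies often describe
the *intended* content rather than the actual triples, and many resources
ship no usable schema at all. `rdfstruct` derives the schema from the
instance data itself and reports where the data is structurally broken.

## What it computes

For every statement `(s, p, o)` the **type link** `(type(s), p, type(o))`
is formed; deduplicated tuples are **unique type links**, each carrying an
occurrence count and two multiplicities:

* **forward** — over the instances of the subject class: `1..1` (every
  instance has exactly one reference), `1..N` (every instance has at least
  one), `0..1`, `0..N`;
* **reverse** — the same classification with the roles of source and
  target inverted (only defined for links between classes).

Object types are one of: a **class** (the object's `rdf:type`), a
**datatype** (e.g. `xsd:integer`), **external** (an untyped IRI outside
the resource's namespaces) or **invalid** (an untyped IRI *inside* the
resource — a structural defect; such links get multiplicity
`not_determined` and an integrity finding).

A second stage merges links over the class hierarchy (`rdfs:subClassOf`,
with `owl:sameAs` folded in): links from or to sibling subclasses are
lifted to their nearest common ancestor in a five-step per-predicate
procedure, shrinking hairball networks while preserving coverage — every
original link remains subsumed by a surviving link, and per-predicate
counts are conserved exactly.

The result exports as:

| format | content |
|---|---|
| structure-RDF (Turtle) | classes, class properties, links, counts, multiplicities; re-importable |
| XGMML | Cytoscape 3.x network: one node per type, one edge per link / subclass pair |
| OWL 2 (RDF/XML) | properties with domain/range, `allValuesFrom` + qualified-cardinality restrictions |
| ShExC | one shape per instantiated class; `1..1` → no modifier, `0..1` → `?`, `1..N` → `+`, `0..N` → `*` |
| report | untyped subjects with properties, undetermined multiplicities, IRIs used as class *and* predicate |

## Worked example

Ten genes, each located on exactly one of two chromosomes:

```r
library(rdfstruct)
ex <- example_graphs()
f <- tempfile(fileext = ".ttl")
writeLines(write_turtle(ex$gene_chromosome$triples,
                        prefixes = c(ex = "http://example.org/")), f)
h <- resource_handle(input = f, namespaces = "http://example.org/")
s <- simplify_structure(recover_structure(rdf_load(h)))
s$links[, c("subject_type", "predicate", "object_type", "count", "forward", "reverse")]
#>              subject_type                    predicate
#> 1 http://example.org/Gene http://example.org/locatedOn
#>                     object_type count forward reverse
#> 1 http://example.org/Chromosome    10    1..1    1..N
summary(s)
#> classes with instances:     2
#> classes without instances:  0
#> unique type links before simplification: 1
#> unique type links after simplification:  1
#> forward multiplicity histogram:
#>   1..1           1
#>   1..N           0
#>   0..1           0
#>   0..N           0
#>   not_determined 0
#> integrity findings: 0
```

Forward `1..1`: every gene sits on exactly one chromosome. Reverse
`1..N`: every chromosome carries at least one gene, some carry several.
`export_xgmml(s, "genes.xgmml")`, `export_owl(s, "genes.owl")` and
`export_shex(s, "genes.shex")` write the other views;
`integrity_report(s)` lists defects (none here).

## Command line

```sh
inst/scripts/rdfstruct recover --input data.ttl \
    --namespace http://example.org/ \
    --xgmml out.xgmml --shex out.shex --report report.txt
```

Subcommands: `recover` (full pipeline; `--endpoint URL` analyses a live
SPARQL 1.1 endpoint, `--limit N` caps statements per predicate, capped
predicates report `not_determined` multiplicities), `export` (re-export a
saved structure-RDF file), `fixture` (write a seeded synthetic graph),
`report`. A JSON config file (`--config`) takes the same keys; flags
override it. `start_fixture_endpoint()` serves any local RDF file as a
loopback SPARQL endpoint for testing endpoint mode.

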
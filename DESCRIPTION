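Package: rdfstruct
Title: Recover, Simplify and Export the Class-Level Structure of RDF Resources
Version: 0.1.0
Authors@R: person("rdfstruct", "maintainers", email = "maintainers@rdfstruct.invalid",
    role = c("aut", "cre"))
Description: Recovers the latent schema of an RDF resource - its classes,
    predicates, typed links and their multiplicities - from local files
    (Turtle, RDF/XML, N-Triples) or a SPARQL 1.1 endpoint, simplifies the
    recovered structure over the class hierarchy by merging sibling links,
    and exports the result as structure-RDF, XGMML (Cytoscape network view),
    OWL 2 and ShEx compact syntax, together with a structural-integrity
    report covering untyped subjects, undetermined multiplicities and IRIs
    used both as class and predicate.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    data.table,
    igraph,
    xml2,
    jsonlite,
    optparse,
    stats,
    utils,
    tools
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
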
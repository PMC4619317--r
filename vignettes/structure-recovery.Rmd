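---
title: "Recovering and simplifying the structure of an RDF resource"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Recovering and simplifying the structure of an RDF resource}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

## The problem

An RDF resource is a set of `(subject, predicate, object)` statements with
no enforced schema. To query it one needs its latent structure: the set of
classes, the predicates connecting them, and how many references an
instance typically holds. `rdfstruct` recovers that structure from the
instance data (the A-box) and renders it as a network, an OWL ontology, a
ShEx schema and a structural-integrity report. It describes the *actual*
content of a resource, which for generated resources routinely differs
from the documented, intended content (typos in generated predicates,
missing type declarations, broken cross-references).

## The model

**Type links.** Each statement `(s, p, o)` induces one type link
`(type(s), p, type(o))` per declared type of `s` and per classification of
`o`. Deduplicated tuples are *unique type links*; each stores the number
of distinct `(s, o)` pairs that realised it.

**Object kinds.** The object's type is one of four kinds:
a *class* (one classification per `rdf:type` of the object IRI); a
*datatype* for literals, with plain and language-tagged literals collapsed
onto `xsd:string` (language stratification is deliberately out of scope);
*external* for an untyped IRI outside every configured resource namespace,
represented by its own namespace prefix; *invalid* for an untyped IRI
inside the resource, represented by the matching configured namespace.
Invalid targets are a defect signal: their links are kept, exported
permissively, marked `not_determined`, and reported. We extend the
invalid classification to untyped in-namespace IRIs that never occur as
subjects; an IRI inside the resource with neither type nor statements is
defective in the same way.

**Multiplicity.** For a link between classes, let `T` be the number of
direct instances of the source class, `P ≤ T` the number of instances
that participate, and `m` the maximum number of distinct targets any
participant references. The forward multiplicity is `1..1` if `P = T, m = 1`;
`1..N` if `P = T, m ≥ 2`; `0..1` if `P < T, m = 1`; `0..N` otherwise.
The reverse multiplicity applies the same rule with source and target
roles inverted; it exists only for class targets, since datatypes and
external/invalid markers have no instance total. Exact reverse counts
(such as "every son has exactly two parents") are collapsed into these
four categories plus `not_determined`.

Two counting conventions are fixed here and used consistently:
*direct* instance counting (a subject counts only under the classes it is
explicitly typed with; hierarchy effects belong to the simplification
stage) and *distinct-pair* semantics (a statement asserted twice counts
once — RDF graphs are sets). Both choices are confirmed against an
independent brute-force oracle in the test suite.

**Concept classes.** A class with no direct instances and no transitively
descendant class with instances (the GO-term pattern: referenced
vocabularies). They are flagged so the network export can hide them,
since thousands of vocabulary nodes otherwise drown the structural signal.

## Simplification over the class hierarchy

The class tree holds every class and all `rdfs:subClassOf` edges;
`owl:sameAs` pairs between classes are folded in as one subclass edge in
each direction, so an equivalence group forms a strongly connected
component that behaves as a single node for ancestor queries (its
representative is the lexicographically smallest IRI). Two types are
*shared* if equal, in ancestor/descendant relation, or possessed of a
common ancestor; `child_of(K, L)` is true when `K = L` or `K` is a
transitive subclass of `L`.

Per predicate, five steps run:

1. each unique type link seeds a temporary link on its subject class;
2. temporary links are copied to all ancestor classes, and pairs on the
   same class with shared targets are merged two at a time into a link to
   the common ancestor, iterating copy + merge to a fixpoint;
3. breadth-first from the roots, a temporary link is removed when exactly
   one direct child holds a covering link (a lifted copy justified by a
   single child is unnecessary);
4. ancestors-first, a temporary link is removed when any ancestor class
   holds a covering link;
5. survivors are emitted with summed counts and widened multiplicities.

Where the procedure is underdetermined, this package fixes it as follows:

* **"Common parent class"** resolves to the *nearest* common ancestor
  (minimal maximum hop distance to the pair), ties broken
  lexicographically; with multiple inheritance, copies go to *all*
  parents.
* **Merge order** is deterministic: classes and candidate pairs are
  examined in byte order, first mergeable pair wins each round, so
  identical inputs give bit-identical outputs.
* **Step 2's upward copying** is iterated to a fixpoint, which subsumes
  both a one-sweep and an iterated reading.
* **Step 3 with zero covering children** retains the link (removal is
  specified only for a count of one), and removal is restricted to pure
  lifted copies: a temporary link whose provenance contains an original
  seeded at the processed class is that original's only guaranteed
  representation, and deleting it would silently drop coverage and
  counts.
* **Step 5 partitions provenance.** Under multiple inheritance, steps 2-4
  can leave two incomparable ancestors each holding a merged survivor
  with the same constituents. Every original link is therefore assigned
  to exactly one surviving subsumer (smallest `(source, target)` key) and
  unused survivors are dropped. This makes three invariants hold
  exhaustively, and the suite checks them on every fixture: coverage
  preservation, per-predicate count conservation, and idempotence.
* **Merged multiplicities widen conservatively** over the constituents
  (`0` lower bound and `N` upper bound are absorbing; `not_determined`
  dominates) rather than being recounted from statements — recovery may
  have run against a remote endpoint that is no longer reachable when
  simplification runs. Widening never promises more than every
  constituent guarantees.
* **Non-class targets** merge only when identical; a datatype never
  merges with a class.

## Data access

Local files are parsed by an in-package reader (no R RDF library exists in
the supported environment): Turtle with prefixes, `a`, `;`/`,`
continuation, typed/language-tagged literals, numeric and boolean
shorthand, labelled and anonymous blank nodes with property lists;
N-Triples as the subset it is; RDF/XML through xml2 (typed node elements,
`rdf:resource`, nested nodes, `rdf:parseType="Resource"`, datatyped
text). RDF collections and triple-quoted strings are rejected with a
parse error naming file and line. Blank nodes are skolemised to stable
`urn:skolem:` IRIs per load and treated as internal.

Endpoint mode speaks the SPARQL 1.1 protocol over plain HTTP with JSON
results, using seven fixed query templates (ASK; class, subclass, sameAs,
predicate and subject enumeration; per-predicate statement dumps with
LIMIT). The templates are an implementation detail — any backend meeting
the operations' postconditions is conformant — and results are re-sorted
client-side in byte order, because SPARQL result order is unspecified and
the merge must be reproducible. The bundled fixture server
(`sparql_fixture_server()`) evaluates exactly these templates against a
local file; it is a test double, not a SPARQL engine. Per-predicate
limits take the sorted prefix, not a sample: reproducibility is preferred
over statistical representativeness, and truncated predicates report
`not_determined` multiplicities rather than unsound values.

## Export encodings

**structure-RDF** uses a fixed budget: 2 triples per class (type,
instance count), 1 per subclass edge, 2 per class-property grouping node
(owner, predicate), 6 per link (ownership, kind-bearing type, target,
count, forward, reverse) — at most 8 link-attributable triples per link.
The grouping node's occurrence count is not serialized; it is by
definition the sum of its links' counts and is recomputed on import.
Re-import reproduces the structure exactly up to integrity findings
(re-derivable only from the source resource) and truncation flags.

**XGMML** targets the Cytoscape 3.x dialect; node identifiers are FNV-1a
hashes of the IRIs (collisions disambiguated deterministically) so
repeated exports diff cleanly. Concept-class and datatype nodes can be
hidden; hiding drops their edges.

**OWL** is OWL 2 in RDF/XML: object/data properties with union domains
and ranges, per class property an `allValuesFrom` restriction (an `or`
union when one class property holds several links), and qualified
cardinalities from the forward multiplicity (`1..1` → exactly 1, `1..N` →
min 1, `0..1` → max 1, `0..N` → none). Reverse multiplicities are
expressed, only on request, as restrictions on the target class over an
anonymous `owl:inverseOf` property — the alternative of materialising
named inverse properties would invent IRIs the resource does not contain.
Links with invalid targets have no OWL counterpart and are skipped with a
log message; they remain visible in the report.

**ShEx** targets current ShExC (ShEx 2.x): one shape per class with
instances, one triple constraint per class property, OR groups for
multi-link class properties, cardinality modifiers `?`, `+`, `*` as in
the table above. Class targets without instances, external and invalid
targets become `IRI` node-kind constraints with an explanatory comment;
`not_determined` links are emitted permissively as `*` with a warning
comment, because an undetermined link is an integrity signal, not absent
structure.

## The synthetic-data generator

`generate_fixture()` emits a graph *and* the ground-truth structure it
realises, so recovery tests are exact rather than statistical. It builds
a complete class tree of configurable depth and branching, samples
per-class instance counts (sampling zero creates concept-class
candidates), and realises each requested predicate with a deterministic
reference pattern that attains the requested forward multiplicity
(`1..1`: one reference each; `1..N`: one instance with two; `0..1`: one
instance with none; `0..N`: one with none and one with two).
`fraction_untyped` attaches references to fresh untyped in-resource IRIs
— which also bear a property, making them untyped subjects with
properties — and `fraction_external` references untyped out-of-resource
IRIs. The same seed yields byte-identical Turtle.

The generator emulates the structural features the algorithms consume:
hierarchy, mixed target kinds, controlled reference-count distributions,
seeded defects. It does not emulate real-world scale (millions of
classes, billions of triples), multi-typed instances (covered by
hand-built fixtures instead), cyclic instance graphs, named graphs, or
OWL axioms beyond `subClassOf`/`sameAs`. A green suite therefore
establishes correctness of the recovery and merge semantics on graphs
whose structure is known exactly — it does not establish performance or
fidelity on resources whose defects fall outside these families.

## Degenerate inputs and numerical choices

Empty graphs, classes without instances, predicates with no typed
subjects, and structures without links all flow through every stage and
exporter. All ordering is byte order (`method = "radix"`), never
locale-collated. Instance counts are exact integers; no tolerances are
involved anywhere. The CLI config file is JSON rather than YAML — the
supported environment ships no R YAML reader — with the same keys as the
flags; flags override the file.

## Known limitations

Named graphs (quads) are unsupported; contextual links are invisible. No
OWL reasoning: types come only from explicit `rdf:type`, not from
domain/range inference. The Turtle reader covers the subset documented
above, not the full grammar. Endpoint mode assumes the endpoint answers
the documented templates with standard JSON results and supports no
authentication beyond plain HTTP. Reverse multiplicities of merged links
are widened, not recounted; a recount mode would need the original
statement registries to remain available.
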
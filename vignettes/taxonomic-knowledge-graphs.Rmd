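---
title: "Modeling the taxonomic process as RDF: design and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modeling the taxonomic process as RDF: design and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(taxograph)
```

## The model

`taxograph` treats taxonomy as a *process*, not a fixed classification.
The unit of meaning is the **taxonomic concept** — the circumscription
hypothesis one author publishes in one place — identified by a
**taxonomic concept label**, a Linnaean name joined to a citation by the
keyword `sec.`. Linnaean names themselves are just labels that drift
between concepts; the model therefore separates three node families:

- **document components** (article, treatment, nomenclature section, ...),
  connected by a transitive `contains` property and carrying **taxonomic
  name usages**: mentions of names in text, optionally with a status
  abbreviation;
- **taxonomic names** (scientific names and concept labels), connected by
  directed `replacementName` and symmetric `relatedName` edges;
- **taxonomic concepts**, simultaneously SKOS concepts (for hierarchy),
  FRBR Works (realized by treatments), and Darwin Core Taxa (for
  interoperability), holding at least one concept label each.

Two constraints carry the identification semantics: the concept-label
property is inverse-functional (a label names exactly one concept), and a
minimum-cardinality-1 restriction requires every concept to have a label.
Together they make concept labels unique identifiers while leaving
name-to-concept links unrestricted many-to-many.

Concept alignment uses two parallel mechanisms, deliberately not
conflated: SKOS broader/narrower for plain hierarchy, and reified RCC-5
statements for set-theoretic alignment. `check_graph(import_skos = TRUE)`
can optionally read broader/narrower as `{PP}`/`{PPi}` constraints, but
the default keeps them separate, because a SKOS hierarchy claim is weaker
than a set-theoretic one.

## Assumptions and degenerate inputs

- Graphs are checked **closed-world**. Under open-world OWL semantics an
  inverse-functional property would silently *merge* two concepts sharing
  a label; the intent here is to *flag* that state, so `validate_graph()`
  is a rule checker, not a reasoner. Labels compare as
  normalized strings (case-folded, whitespace-collapsed); the report
  records this in its `label_comparison` field.
- Replacement chains may branch. Resolution returns **all** terminals with
  one witness path each; no year-based or code-based arbitration is
  imposed, because precedence is an editorial judgement, not a structural
  one. Cycles (which should not occur in code-compliant data, but do occur
  in dirty data) are reported with their members, never silently broken.
- `relatedName` is symmetric and irreflexive but **not** transitive;
  neighborhood queries take an explicit hop count instead. Transitivity
  would flood-fill any synonym cluster into one undifferentiated blob.
- An empty graph validates; a single node has an empty containment
  closure; an isolated name resolves to itself and has an empty
  neighborhood.

## Name grammar

The parser implements

```
name = Genus [epithet] [marker epithet]
       [ "(" Author ["," year] ")" | Author [","] [year] ]
```

with markers `var.`, `subsp.`, `ssp.`, `f.`, `subvar.`, `forma`. Strings
are NFC-normalized and whitespace-collapsed first; authorship is kept
opaque (no author-team splitting — out of scope); the year is a four-digit
integer; parenthesized authorship is a boolean flag. A comma before the
year is preserved as a flag so that `format_name()` inverts
`parse_scientific_name()` field-for-field. The `sec.` keyword is matched
case-sensitively as an exact token and is rejected inside a plain name, so
a concept label can never be mis-read as an authorship. Status splitting
in `parse_taxonomic_name_usage()` only accepts a trailing segment that the
status classifier actually recognizes, which is what guarantees that
years and authorships are never consumed as statuses.

The status vocabulary has exactly eight classes. The shipped
abbreviation-to-class mapping carries each class's canonical exemplar
plus common orthographic variants (`sp. nov.`, `n. sp.`, `syn. n.`,
`nom. nov.`, ...); it is a curated starting point, not a closed list, and
can be extended per call with a YAML mapping (`classify_status(x, extra =
"mapping.yaml")`). Matching is case-insensitive, whitespace-collapsing and
trailing-period-insensitive; anything unmatched falls back to
`"Unclassified"` rather than erroring, since prose statuses are open-ended.

## The RCC-5 reasoner

Concepts are read as non-empty sets; the five base relations partition
the possible set relationships. The composition table is stated directly
in `base_composition()` from the set semantics (e.g. `PP ∘ PP = {PP}`,
`PP ∘ PPi` is fully uninformative); the test suite re-derives the whole
table independently by enumerating subset triples over a 4-element
universe, which is sufficient to realize every satisfiable pattern.
`path_consistency()` is the classical refinement loop — intersect each
edge with the union of its two-leg compositions until fixpoint. It is
monotone and idempotent, detects inconsistency when an edge empties, and
is *sound but incomplete*: it can fail to detect some unsatisfiable
networks, but never refutes a satisfiable one (property-tested against
the exhaustive oracle). Full answer-set reasoning is intentionally out of
scope; `model_check_oracle()` covers desk-scale verification instead, with
hard bounds (≤ 6 nodes, universe ≤ 6) because its backtracking search is
exhaustive. A universe of 4 is used in tests: RCC-5 over larger universes
adds no new consistent configurations for the network sizes checked.

Edge labels are disjunctions; a singleton is the determinate case. The
reified `RCC5Statement` nodes carry one vocabulary-relation link per
disjunct, so uncertainty survives serialization. The `rcc5Property`
subproperties are read as denoting base relations (not disjunctions); a
disjunctive claim is expressed by multiple relation links on one
statement.

## The RDF layer

The package carries its own small triple store with Turtle and RDF/XML
serialization (RDF/XML through `xml2`), sufficient for the fragment the
model emits: IRIs, CURIEs, blank-node labels, and literals with language
tags or datatypes. The Turtle reader reports line numbers on malformed
input. Graph comparison is by isomorphism: ground triples must match
exactly; blank nodes are matched by iterative signature refinement with a
bounded permutation search among signature-tied nodes (the package's own
output is blank-node-free — even the OWL restriction node is given an
IRI — so the bound only matters for foreign files). IRIs are minted with a
Lehmer generator modulo 2^31 − 1, independent of R's global RNG, so
minting is reproducible under a seed and never perturbs a simulation.

## The fixture generator

`gen_fixture()` emulates the *structural* properties of a taxonomic
corpus: article trees where every treatment holds a nomenclature section
and optional materials-examined/description/biology subsections; 1–3 name
usages per nomenclature section, 40% of them carrying a status; names as
pronounceable syllable-template pseudo-Latin with authorships and years
(25% parenthesized), so the parser round-trips realistic shapes; a
replacement DAG built on an index ordering (edges only from lower to
higher index, hence acyclic by construction) with edge probability
`p_replacement = 0.15`; related-name links at `p_related = 0.1`; concepts
labelled `name sec. author (year)` with collision regeneration;
`n_hierarchies` independent spanning hierarchies; and RCC-5 statements
*read off a concrete ground-truth assignment* of subsets of a 5-element
universe, which makes every generated network satisfiable without any
reasoning. Defaults (2 articles × 2 treatments, 12 names, 6 concepts) are
chosen as the smallest corpus exercising every structural feature at
once.

What the generator does **not** emulate: the statistical realism of the
literature (journal sizes, rank distributions, status frequencies), OCR
noise, hybrid formulas, or multilingual prose. Passing tests therefore
demonstrate structural correctness of graph construction, validation and
reasoning — not robustness of the name grammar to arbitrary real-world
strings.

Violation injection is manifest-driven: each kind seeds exactly one
defect *after* the clean build and records the validator rule and focus
node it must trigger. The manifest is thus an exact oracle: the validator
must report precisely the manifested (rule, focus) pairs on injected
fixtures and nothing on clean ones. Determinism is strict — one seed, one
byte stream — which the suite checks by comparing serializations.

## Problem sizes and numerical choices

The oracle-agreement suites run at sizes chosen to exhaust the
interesting structure while staying desk-scale: 200 random trees of 2–12
nodes for containment closure, 200 random DAGs of 3–10 names for chain
resolution, all 25 composition pairs, all 125 singleton 3-node networks
plus 200 random 5-node networks for path-consistency soundness. All
comparisons are exact (set or field equality); there are no numeric
tolerances anywhere in the package.

Tie-breaks and orderings are made deterministic throughout: triples are
sorted on serialization, validation reports sort by rule then focus node,
containment-cycle violations are reported once per strongly connected
component on its lexicographically first member.

## Open design points, resolved

- A concept label's reference is kept as an opaque token sequence after
  `sec.`; structured citations can be layered on later without changing
  the label's identity semantics.
- `contains` is used by the API only among document components and
  usages; the model does not forbid other uses, and the validator checks
  only acyclicity.
- The command-line surface is a thin script over the exported functions
  (`inst/cli/taxograph`); the R API is the primary interface and the only
  tested one directly.

## Known limitations

- The Turtle reader covers the emitted fragment (no `@base`, collections,
  or nested blank-node property lists); foreign files using those
  constructs are rejected with a diagnostic rather than misread.
- Path consistency alone cannot prove global satisfiability; for networks
  beyond the oracle's bounds an external complete reasoner would be
  needed.
- The name grammar targets Latin binomials/trinomials with one authorship
  segment; hybrid formulas and multi-rank zoological dialects are out of
  scope.
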
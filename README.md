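# taxograph

RDF knowledge graphs for taxonomic publishing and taxonomic concepts, in R.

## The problem

Biological taxonomy advances by publishing *hypotheses*: a taxonomist
examines specimens and circumscribes a taxon in an article, usually inside a
dedicated **treatment** section. The Linnaean name attached to that taxon is
not the hypothesis — names get reused, replaced (`comb. n.`, `nomen novum`,
`syn. nov.`) and attached to incompatible circumscriptions over time. A
**taxonomic concept** is the name *plus* the circumscribing publication,
written `name sec. reference` (e.g. *Casuarinicola australis* Taylor, 2010
sec. Thorpe), and it is concepts, not names, that can be meaningfully
compared, aligned and reasoned over.

`taxograph` is a toolkit for building, serializing, validating and querying
RDF graphs of this process, for biodiversity informaticians who want a
knowledge graph that can hold multiple, even conflicting, taxonomies at
once. It covers three layers:

1. **Publishing** — FRBR work/expression metadata, a typed document
   component tree (treatment, nomenclature section, materials examined,
   checklist, key, ...) connected by a *transitive* `contains` property, and
   taxonomic name usages (`mentions`) linking document regions to names.
2. **Nomenclature** — a parser/formatter for scientific names, name usages
   with trailing status abbreviations, and concept labels; an
   eight-class SKOS vocabulary of taxonomic statuses (uncertainty,
   discovery, replacement, unavailable, available, type-specimen,
   type-species, new occurrence record); directed `replacementName` chains
   (follow them to the current name) and symmetric `relatedName` links.
3. **Concepts** — concepts typed simultaneously as `skos:Concept`,
   `frbr:Work`, `dwc:Taxon` and operational taxonomic unit, identified by
   their labels (the label property is inverse-functional, with a
   minimum-cardinality-1 restriction); SKOS multi-hierarchies; and reified
   **RCC-5** statements.

RCC-5 reads concept circumscriptions as non-empty sets and relates them
with five base relations — `EQ` (equal), `PP` (proper part), `PPi` (inverse
proper part), `PO` (partial overlap), `DR` (disjoint). An edge may carry a
disjunction of base relations to express uncertainty. The package ships a
composition-based **path-consistency reasoner** (sound, incomplete):
`edge(i,j) <- edge(i,j) ∩ ⋃_k compose(edge(i,k), edge(k,j))` to fixpoint,
with an empty edge proving inconsistency — plus an exhaustive finite-model
oracle (`model_check_oracle`) that decides satisfiability for desk-scale
networks by enumerating subset assignments.

There is no external data dependency anywhere: a deterministic fixture
generator (`gen_fixture`) produces complete synthetic corpora, clean or
with manifest-tracked injected violations, and a closed-world validator
(`validate_graph`, rules R1–R8) checks label cardinality and uniqueness,
domain/range use, mention counts, containment acyclicity, status
vocabulary membership, RCC-5 statement well-formedness and
treatment-realization typing.

## Worked example

```r
library(taxograph)

# an article with one treatment holding a nomenclature section
root <- document_component("TaxonomicArticle", id = "http://openbiodiv.net/ex/article",
  children = list(document_component("Treatment", id = "http://openbiodiv.net/ex/treatment",
    children = list(document_component("NomenclatureSection", id = "http://openbiodiv.net/ex/nomen")))))
meta <- article_metadata("A new spider of the genus Heser", authors = "C. Deltschev",
                         journal = "Zootaxa", work_id = "http://openbiodiv.net/ex/work")
g <- build_article_graph(meta, root, seed = 1)

# a name usage with a trailing status abbreviation
u <- parse_taxonomic_name_usage("Heser stoevi Deltschev 2016, sp. n.")
u
#> <name_usage> Heser stoevi Deltschev 2016 [TaxonDiscovery]
add_name_usage(g, u, "http://openbiodiv.net/ex/nomen", "http://openbiodiv.net/ex/name1",
               usage_id = "http://openbiodiv.net/ex/tnu1")

# two concepts and their alignment: the species-rank concept is a proper
# part of the genus-rank concept
add_concept(g, "http://openbiodiv.net/ex/c-sp",
            labels = list("Casuarinicola australis Taylor, 2010 sec. Thorpe"), seed = 2)
add_concept(g, "http://openbiodiv.net/ex/c-gen",
            labels = list("Casuarinicola Taylor, 2010 sec. Taylor"), seed = 3)
assert_skos_relation(g, "http://openbiodiv.net/ex/c-sp", "http://openbiodiv.net/ex/c-gen")
assert_rcc5(g, "http://openbiodiv.net/ex/c-sp", "http://openbiodiv.net/ex/c-gen", "PP",
            source = "Thorpe (2013)", statement_id = "http://openbiodiv.net/ex/st1")

g
#> <rdf_graph> 60 triples, 17 namespaces
validate_graph(g)
#> <validation_report> PASSED: 0 error(s), 0 warning(s)
check_graph(g)
#> <rcc5_report> verdict: consistent; 1 informative edge(s); 0 warning(s)
check_graph(g)$edges
#>                            from                             to relations
#> 1 http://openbiodiv.net/ex/c-sp http://openbiodiv.net/ex/c-gen        PP
nrow(contains_closure(g))   # transitive containment: 3 tree edges close to
#> [1] 6                     # 6 ancestor/descendant pairs (usage included)

rdf_serialize(g, "article.ttl", format = "turtle")   # or format = "rdfxml"
```

The validation report says the graph satisfies all eight closed-world
rules; the RCC-5 report says the asserted alignment network is
path-consistent, with one informative refined edge (`PP` between the two
concepts).

A thin CLI over the same functions is installed under
`system.file("cli/taxograph", package = "taxograph")` with subcommands
`classify-status`, `parse-name`, `build --from yaml`, `validate`,
`rcc5-check`, `resolve-name` and `fixtures`.

## Scope

Out of scope by design: text-mining names out of article prose, answer-set
(ASP) reasoning over concept alignments, trait vocabularies, occurrence
modeling beyond pass-through IRIs, and any network service.
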
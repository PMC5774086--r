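Package: taxograph
Title: RDF Knowledge Graphs for Taxonomic Publishing and Taxonomic Concepts
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Build, serialize, validate and query RDF knowledge graphs of
    taxonomic articles, scientific names and taxonomic concepts. Provides a
    term registry and core ontology for semantic biodiversity publishing
    (FRBR work/expression metadata, typed document components linked by a
    transitive containment property, taxonomic name usages), controlled
    vocabularies for taxonomic statuses and for the five base relations of
    the Region Connection Calculus (RCC-5), a parser and formatter for
    scientific names, name usages and taxonomic concept labels ("name sec.
    reference"), replacement-name chain resolution, SKOS concept
    hierarchies, reified RCC-5 statements with a composition-based
    path-consistency reasoner and an exhaustive finite-model oracle, a
    closed-world constraint validator, and a deterministic synthetic
    fixture generator with manifest-tracked violation injection.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    igraph,
    jsonlite,
    stats,
    stringi,
    xml2,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
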
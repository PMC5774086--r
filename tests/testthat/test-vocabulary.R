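test_that("term registry declares the model's classes and key characteristics", {
  reg <- term_registry()
  expected <- c("Treatment", "NomenclatureSection", "NomenclatureHeading",
                "NomenclatureCitationList", "MaterialsExamined", "BiologySection",
                "DescriptionSection", "TaxonomicKey", "TaxonomicChecklist",
                "TaxonomicNameUsage", "TaxonomicArticle", "Mention",
                "TaxonomicName", "ScientificName", "TaxonomicConceptLabel",
                "TaxonomicConcept", "OperationalTaxonomicUnit",
                "RCC5Dictionary", "RCC5Relation", "RCC5Statement")
  expect_true(all(expected %in% reg$classes$name))
  expect_false(anyDuplicated(reg$classes$name) > 0)
  contains <- reg$properties[reg$properties$name == "contains", ]
  expect_true(contains$transitive)
  expect_equal(contains$subproperty_of, "po:contains")
  tcl <- reg$properties[reg$properties$name == "taxonomicConceptLabel", ]
  expect_true(tcl$inverse_functional)
  expect_equal(tcl$domain, "openbiodiv:TaxonomicConcept")
})

test_that("core ontology carries the alignment axioms and emits deterministically", {
  g <- emit_core_ontology()
  tc <- "http://openbiodiv.net/TaxonomicConcept"
  expect_true("http://rs.tdwg.org/dwc/terms/Taxon" %in%
                rdf_objects(g, s = tc, p = "owl:equivalentClass"))
  sup <- rdf_objects(g, s = tc, p = "rdfs:subClassOf")
  expect_true(all(c("http://purl.org/vocab/frbr/core#Work",
                    "http://www.w3.org/2004/02/skos/core#Concept",
                    "http://openbiodiv.net/OperationalTaxonomicUnit") %in% sup))
  expect_true("http://purl.org/spar/fabio/JournalArticle" %in%
                rdf_objects(g, s = "openbiodiv:TaxonomicArticle", p = "rdfs:subClassOf"))
  expect_true("http://openbiodiv.net/Mention" %in%
                rdf_objects(g, s = "openbiodiv:TaxonomicNameUsage", p = "rdfs:subClassOf"))
  # transitive containment
  expect_true("http://www.w3.org/2002/07/owl#TransitiveProperty" %in%
                rdf_objects(g, s = "openbiodiv:contains", p = "rdf:type"))
  # min-cardinality-1 restriction on the label property
  restr <- rdf_subjects(g, p = "owl:onProperty", o = "openbiodiv:taxonomicConceptLabel")
  expect_length(restr, 1L)
  expect_true(restr %in% rdf_objects(g, s = tc, p = "rdfs:subClassOf"))
  expect_equal(rdf_match(g, s = restr, p = "owl:minCardinality")$o, "1")
  # determinism and parseability
  expect_true(rdf_isomorphic(g, emit_core_ontology()))
  expect_true(rdf_isomorphic(g, rdf_roundtrip(g, "turtle")))
})

test_that("status classification matches the vocabulary's exemplar rows", {
  exemplars <- c("incertae sedis" = "TaxonomicUncertainty",
                 "sp. n." = "TaxonDiscovery",
                 "comb. n." = "ReplacementName",
                 "nomen dubium" = "UnavailableName",
                 "stat. rev." = "AvailableName",
                 "lectotype designation" = "TypeSpecimenDesignation",
                 "type species" = "TypeSpeciesDesignation",
                 "new country record" = "NewOccurrenceRecord")
  expect_equal(unname(classify_status(names(exemplars))), unname(exemplars))
})

test_that("status classification normalizes, falls back, and extends", {
  expect_equal(classify_status("Sp. N."), "TaxonDiscovery")
  expect_equal(classify_status("  sp.   n  "), "TaxonDiscovery")
  expect_equal(classify_status(c("nomen novum", "syn. nov.", "sp. nov.", "n. sp.")),
               rep(c("ReplacementName", "TaxonDiscovery"), each = 2))
  expect_equal(classify_status("totally unknown status"), "Unclassified")
  expect_error(classify_status(""), "non-empty")
  expect_error(classify_status(character(0)), "non-empty")
  # idempotent under its own normalization
  ab <- unlist(status_abbreviations(), use.names = FALSE)
  expect_equal(classify_status(ab), classify_status(toupper(paste0(ab, "."))))
  # extension via a YAML mapping
  yml <- withr::local_tempfile(fileext = ".yaml")
  writeLines("TaxonDiscovery:\n  - 'shiny new species'", yml)
  expect_equal(classify_status("shiny new species", extra = yml), "TaxonDiscovery")
  expect_equal(classify_status("shiny new species"), "Unclassified")
  expect_error(classify_status("x", extra = list(NotAClass = "y")), "unknown status class")
})

test_that("status vocabulary is a SKOS scheme with exactly eight concepts", {
  g <- status_vocabulary()
  members <- rdf_subjects(g, p = "rdf:type", o = "openbiodiv:TaxonomicStatus")
  expect_length(members, 8L)
  scheme <- rdf_subjects(g, p = "rdf:type", o = "skos:ConceptScheme")
  expect_length(scheme, 1L)
  expect_setequal(rdf_subjects(g, p = "skos:inScheme", o = scheme), members)
  # every concept carries a label and at least one example abbreviation
  for (m in members) {
    expect_length(rdf_match(g, s = m, p = "skos:prefLabel")$o, 1L)
    expect_gte(nrow(rdf_match(g, s = m, p = "skos:example")), 1L)
  }
  expect_true(rdf_isomorphic(g, rdf_roundtrip(g, "turtle")))
})

test_that("RCC-5 vocabulary has five relation concepts with involutive converses", {
  g <- rcc5_vocabulary()
  members <- rdf_subjects(g, p = "rdf:type", o = "openbiodiv:RCC5Relation")
  expect_length(members, 5L)
  expect_setequal(members, vapply(rcc5_relations(), rcc5_iri, character(1)))
  for (r in rcc5_relations()) {
    expect_equal(rcc5_converse(rcc5_converse(r)), r)
    conv <- rdf_objects(g, s = rcc5_iri(r), p = "openbiodiv:converseRelation")
    expect_equal(conv, rcc5_iri(rcc5_converse(r)))
  }
  expect_equal(rcc5_converse("PP"), "PPi")
  expect_setequal(rcc5_converse(c("EQ", "PO", "DR")), c("EQ", "PO", "DR"))
  expect_true(rdf_isomorphic(g, rdf_roundtrip(g, "rdfxml")))
})
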
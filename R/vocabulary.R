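#' Taxonomic status classes
#'
#' The eight classes of the taxonomic-status vocabulary, plus the
#' `"Unclassified"` fallback used when an abbreviation matches no known
#' pattern. The classes cover the most common nomenclatural acts found in
#' taxonomic articles: uncertainty placements, new-taxon discoveries,
#' replacement names (new combinations, nomina nova, junior synonyms),
#' unavailable and available names, type designations and new occurrence
#' records.
#'
#' @return Character vector of the eight status class names.
#' @export
status_classes <- function() {
  c("TaxonomicUncertainty", "TaxonDiscovery", "ReplacementName",
    "UnavailableName", "AvailableName", "TypeSpecimenDesignation",
    "TypeSpeciesDesignation", "NewOccurrenceRecord")
}

# Curated abbreviation patterns per status class. The printed exemplars are
# kept first in each set; orthographic variants follow. Extensible at call
# time via a YAML mapping (see classify_status).
status_abbreviations <- function() {
  list(
    TaxonomicUncertainty = c("incertae sedis", "species inquirenda", "sedis incertae"),
    TaxonDiscovery = c("sp. n.", "sp. nov.", "n. sp.", "spec. nov.",
                       "gen. n.", "gen. nov.", "fam. n.", "subsp. n.",
                       "var. n.", "species nova"),
    ReplacementName = c("comb. n.", "comb. nov.", "n. comb.", "nomen novum",
                        "nom. nov.", "nom. n.", "syn. nov.", "syn. n.",
                        "new synonym", "new combination"),
    UnavailableName = c("nomen dubium", "nom. dub.", "nomen nudum",
                        "nom. nud.", "unavailable name"),
    AvailableName = c("stat. rev.", "stat. n.", "stat. nov.", "nomen protectum",
                      "sp. rev.", "available name"),
    TypeSpecimenDesignation = c("lectotype designation", "neotype designation",
                                "holotype designation", "lectotype designated",
                                "neotype designated"),
    TypeSpeciesDesignation = c("type species", "type species designation",
                               "type genus"),
    NewOccurrenceRecord = c("new country record", "new record", "first record",
                            "new for the fauna")
  )
}

# Normalization shared by patterns and queries: NFC, lower case, collapsed
# whitespace, trailing periods removed.
normalize_status <- function(x) {
  x <- stringi::stri_trans_nfc(x)
  x <- tolower(trimws(gsub("\\s+", " ", x)))
  sub("\\.+$", "", x)
}

#' Classify a taxonomic-status abbreviation
#'
#' Maps an abbreviation such as `"sp. n."` or `"incertae sedis"` to one of
#' the eight status classes (see [status_classes()]). Matching is
#' case-insensitive, whitespace-collapsing and insensitive to a trailing
#' period; unmatched strings yield `"Unclassified"`.
#'
#' @param abbrev Character vector of abbreviations (non-empty strings).
#' @param extra Optional extension of the mapping: a named list of character
#'   vectors (`list(StatusClass = c("abbrev", ...))`) or the path to a YAML
#'   file with that structure. Extensions are consulted before the built-in
#'   patterns.
#' @return Character vector: a status class or `"Unclassified"` per element.
#' @export
#' @examples
#' classify_status("sp. n.")
#' classify_status(c("incertae sedis", "Sp. N.", "mystery"))
classify_status <- function(abbrev, extra = NULL) {
  if (!is.character(abbrev) || !length(abbrev) || any(!nzchar(trimws(abbrev)))) {
    stop("`abbrev` must be one or more non-empty strings")
  }
  mapping <- status_abbreviations()
  if (!is.null(extra)) {
    if (is.character(extra) && length(extra) == 1L) extra <- yaml::read_yaml(extra)
    if (!is.list(extra)) stop("`extra` must be a named list or a YAML path")
    bad <- setdiff(names(extra), status_classes())
    if (length(bad)) stop("unknown status class in extension: ", paste(bad, collapse = ", "))
    for (cl in names(extra)) {
      mapping[[cl]] <- c(unlist(extra[[cl]], use.names = FALSE), mapping[[cl]])
    }
  }
  lut <- stats::setNames(
    rep(names(mapping), lengths(mapping)),
    normalize_status(unlist(mapping, use.names = FALSE))
  )
  out <- unname(lut[normalize_status(abbrev)])
  out[is.na(out)] <- "Unclassified"
  out
}

#' RCC-5 base relations
#'
#' The five base relations of the Region Connection Calculus restricted to
#' five relations, read over non-empty sets: `EQ` (equal), `PP` (proper
#' part), `PPi` (proper part inverse), `PO` (partial overlap), `DR`
#' (disjoint).
#'
#' @return Character vector `c("EQ","PP","PPi","PO","DR")`.
#' @export
rcc5_relations <- function() c("EQ", "PP", "PPi", "PO", "DR")

#' Converse of an RCC-5 base relation
#'
#' `PP` and `PPi` are converses of one another; `EQ`, `PO` and `DR` are
#' self-converse. The map is an involution.
#'
#' @param r Character vector of base relations.
#' @return Character vector of converses.
#' @export
#' @examples
#' rcc5_converse("PP")
rcc5_converse <- function(r) {
  map <- c(EQ = "EQ", PP = "PPi", PPi = "PP", PO = "PO", DR = "DR")
  if (any(!r %in% names(map))) stop("unknown RCC-5 relation: ",
                                    paste(setdiff(r, names(map)), collapse = ", "))
  unname(map[r])
}

# ---------------------------------------------------------------------------
# Term registry

#' The term registry
#'
#' Enumerates the model's namespaces, classes and properties together with
#' their characteristics (superclass/superproperty links, transitivity,
#' inverse functionality, domain, range). [emit_core_ontology()] serializes
#' this registry as RDF.
#'
#' Document-component classes live under the discourse-element class of the
#' external document ontology; the taxonomic article is a journal-article
#' subclass; the taxonomic concept is simultaneously a bibliographic Work, a
#' SKOS concept, an operational taxonomic unit and (by equivalence) a Darwin
#' Core Taxon.
#'
#' @return A list with elements `namespaces` (named character),
#'   `classes` (data frame: `name`, `iri`, `subclass_of`, `equivalent`) and
#'   `properties` (data frame: `name`, `iri`, `subproperty_of`, `domain`,
#'   `range`, `transitive`, `inverse_functional`, `symmetric`).
#' @export
term_registry <- function() {
  ns <- default_namespaces()
  cls <- function(name, subclass_of = NA, equivalent = NA) {
    data.frame(name = name, iri = obn(name),
               subclass_of = subclass_of, equivalent = equivalent,
               stringsAsFactors = FALSE)
  }
  deo_el <- "deo:DiscourseElement"
  classes <- rbind(
    cls("TaxonomicArticle", "fabio:JournalArticle"),
    cls("Treatment", deo_el),
    cls("NomenclatureSection", deo_el),
    cls("NomenclatureHeading", deo_el),
    cls("NomenclatureCitationList", deo_el),
    cls("MaterialsExamined", deo_el),
    cls("BiologySection", deo_el),
    cls("DescriptionSection", deo_el),
    cls("TaxonomicKey", deo_el),
    cls("TaxonomicChecklist", deo_el),
    cls("Mention", deo_el),
    cls("TaxonomicNameUsage", "openbiodiv:Mention"),
    cls("TaxonomicName", NA),
    cls("ScientificName", "openbiodiv:TaxonomicName"),
    cls("TaxonomicConceptLabel", "openbiodiv:TaxonomicName"),
    cls("OperationalTaxonomicUnit", NA),
    cls("TaxonomicConcept", "openbiodiv:OperationalTaxonomicUnit", "dwc:Taxon"),
    cls("TaxonomicStatus", "skos:Concept"),
    cls("RCC5Dictionary", "skos:ConceptScheme"),
    cls("RCC5Relation", "skos:Concept"),
    cls("RCC5Statement", NA)
  )
  prp <- function(name, subproperty_of = NA, domain = NA, range = NA,
                  transitive = FALSE, inverse_functional = FALSE,
                  symmetric = FALSE) {
    data.frame(name = name, iri = obn(name), subproperty_of = subproperty_of,
               domain = domain, range = range, transitive = transitive,
               inverse_functional = inverse_functional, symmetric = symmetric,
               stringsAsFactors = FALSE)
  }
  properties <- rbind(
    prp("contains", "po:contains", transitive = TRUE),
    prp("mentions", domain = "openbiodiv:Mention"),
    prp("taxonomicName", domain = "openbiodiv:OperationalTaxonomicUnit",
        range = "openbiodiv:TaxonomicName"),
    prp("scientificName", "openbiodiv:taxonomicName",
        domain = "openbiodiv:TaxonomicConcept", range = "openbiodiv:ScientificName"),
    prp("taxonomicConceptLabel", "openbiodiv:taxonomicName",
        domain = "openbiodiv:TaxonomicConcept",
        range = "openbiodiv:TaxonomicConceptLabel", inverse_functional = TRUE),
    prp("taxonomicStatus", domain = "openbiodiv:TaxonomicNameUsage",
        range = "openbiodiv:TaxonomicStatus"),
    prp("replacementName", domain = "openbiodiv:TaxonomicName",
        range = "openbiodiv:TaxonomicName"),
    prp("relatedName", domain = "openbiodiv:TaxonomicName",
        range = "openbiodiv:TaxonomicName", symmetric = TRUE),
    prp("rcc5Property", domain = "openbiodiv:TaxonomicConcept",
        range = "openbiodiv:TaxonomicConcept"),
    prp("rcc5Subject", domain = "openbiodiv:RCC5Statement",
        range = "openbiodiv:TaxonomicConcept"),
    prp("rcc5Object", domain = "openbiodiv:RCC5Statement",
        range = "openbiodiv:TaxonomicConcept"),
    prp("rcc5Relation", domain = "openbiodiv:RCC5Statement",
        range = "openbiodiv:RCC5Relation"),
    prp("converseRelation", domain = "openbiodiv:RCC5Relation",
        range = "openbiodiv:RCC5Relation", symmetric = TRUE),
    prp("hasHabitat", domain = "openbiodiv:TaxonomicConcept")
  )
  list(namespaces = ns, classes = classes, properties = properties)
}

#' Emit the core ontology as RDF
#'
#' Declares every class and property of [term_registry()] with its axioms:
#' subclass links into the external publishing ontologies, the Darwin Core
#' Taxon equivalence, transitivity of the containment property, inverse
#' functionality of the concept-label property, and the minimum-cardinality
#' restriction requiring at least one concept label per taxonomic concept.
#'
#' @return An [rdf_graph()]; deterministic (two emissions are isomorphic).
#' @export
#' @examples
#' g <- emit_core_ontology()
#' rdf_size(g) > 50
emit_core_ontology <- function() {
  reg <- term_registry()
  g <- rdf_graph(namespaces = reg$namespaces)
  onto <- obn("ontology")
  rdf_add(g, onto, "rdf:type", "owl:Ontology")
  rdf_add_literal(g, onto, "rdfs:label", "Core ontology of taxonomic publishing")

  for (i in seq_len(nrow(reg$classes))) {
    row <- reg$classes[i, ]
    rdf_add(g, row$iri, "rdf:type", "owl:Class")
    rdf_add_literal(g, row$iri, "rdfs:label", row$name)
    if (!is.na(row$subclass_of)) rdf_add(g, row$iri, "rdfs:subClassOf", row$subclass_of)
    if (!is.na(row$equivalent)) rdf_add(g, row$iri, "owl:equivalentClass", row$equivalent)
  }
  # a taxonomic concept is also a Work and a SKOS concept
  rdf_add(g, "openbiodiv:TaxonomicConcept", "rdfs:subClassOf",
          c("frbr:Work", "skos:Concept"))
  # ...and must carry at least one concept label (min-cardinality restriction)
  restr <- obn("TaxonomicConceptLabelRestriction")
  rdf_add(g, restr, "rdf:type", "owl:Restriction")
  rdf_add(g, restr, "owl:onProperty", "openbiodiv:taxonomicConceptLabel")
  rdf_add_literal(g, restr, "owl:minCardinality", "1",
                  datatype = "xsd:nonNegativeInteger")
  rdf_add(g, "openbiodiv:TaxonomicConcept", "rdfs:subClassOf", restr)

  for (i in seq_len(nrow(reg$properties))) {
    row <- reg$properties[i, ]
    rdf_add(g, row$iri, "rdf:type", "owl:ObjectProperty")
    rdf_add_literal(g, row$iri, "rdfs:label", row$name)
    if (!is.na(row$subproperty_of)) rdf_add(g, row$iri, "rdfs:subPropertyOf", row$subproperty_of)
    if (!is.na(row$domain)) rdf_add(g, row$iri, "rdfs:domain", row$domain)
    if (!is.na(row$range)) rdf_add(g, row$iri, "rdfs:range", row$range)
    if (row$transitive) rdf_add(g, row$iri, "rdf:type", "owl:TransitiveProperty")
    if (row$inverse_functional) rdf_add(g, row$iri, "rdf:type", "owl:InverseFunctionalProperty")
    if (row$symmetric) rdf_add(g, row$iri, "rdf:type", "owl:SymmetricProperty")
  }
  # scientificName aligns to the Darwin Core IRI term of the same meaning
  rdf_add(g, "openbiodiv:scientificName", "rdfs:subPropertyOf", "dwciri:scientificName")
  g
}

# IRI of a status concept
status_iri <- function(class) obn(class)

#' The taxonomic-status vocabulary as RDF
#'
#' A SKOS concept scheme holding exactly eight status concepts, each typed
#' as a status term, placed in-scheme, labelled, and carrying its
#' abbreviation patterns as `skos:example` literals.
#'
#' @return An [rdf_graph()].
#' @export
status_vocabulary <- function() {
  g <- rdf_graph()
  scheme <- obn("TaxonomicStatusTerms")
  rdf_add(g, scheme, "rdf:type", "skos:ConceptScheme")
  rdf_add_literal(g, scheme, "skos:prefLabel", "Vocabulary of Taxonomic Statuses",
                  lang = "en")
  abbr <- status_abbreviations()
  for (cl in status_classes()) {
    iri <- status_iri(cl)
    rdf_add(g, iri, "rdf:type", c("skos:Concept", "openbiodiv:TaxonomicStatus"))
    rdf_add(g, iri, "skos:inScheme", scheme)
    rdf_add_literal(g, iri, "skos:prefLabel", gsub("([a-z])([A-Z])", "\\1 \\2", cl),
                    lang = "en")
    rdf_add_literal(g, iri, "skos:example", abbr[[cl]])
  }
  g
}

#' The RCC-5 relation vocabulary as RDF
#'
#' A SKOS concept scheme (the RCC-5 dictionary) holding the five base
#' relations as SKOS concepts typed `RCC5Relation`, with converse pairs
#' linked symmetrically.
#'
#' @return An [rdf_graph()].
#' @export
rcc5_vocabulary <- function() {
  g <- rdf_graph()
  scheme <- obn("RCC5RelationshipTerms")
  rdf_add(g, scheme, "rdf:type", c("skos:ConceptScheme", "openbiodiv:RCC5Dictionary"))
  rdf_add_literal(g, scheme, "skos:prefLabel", "RCC-5 Vocabulary", lang = "en")
  labels <- c(EQ = "equals", PP = "proper part", PPi = "inverse proper part",
              PO = "partial overlap", DR = "disjoint")
  for (r in rcc5_relations()) {
    iri <- rcc5_iri(r)
    rdf_add(g, iri, "rdf:type", c("skos:Concept", "openbiodiv:RCC5Relation"))
    rdf_add(g, iri, "skos:inScheme", scheme)
    rdf_add_literal(g, iri, "skos:prefLabel", labels[[r]], lang = "en")
    rdf_add_literal(g, iri, "skos:notation", r)
    rdf_add(g, iri, "openbiodiv:converseRelation", rcc5_iri(rcc5_converse(r)))
  }
  g
}

#' IRI of an RCC-5 relation concept
#' @param r Base relation mnemonic (`"EQ"`, `"PP"`, `"PPi"`, `"PO"`, `"DR"`).
#' @return IRI string.
#' @export
rcc5_iri <- function(r) {
  stopifnot(all(r %in% rcc5_relations()))
  obn(paste0("RCC5", r))
}
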
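#' Add a taxonomic concept to a graph
#'
#' A taxonomic concept — the circumscription hypothesis a taxonomist forms
#' in a publication — is typed simultaneously as a taxonomic concept, a
#' SKOS concept, a bibliographic Work and a Darwin Core Taxon. It must
#' carry at least one taxonomic concept label ("name sec. reference"), and
#' no label may identify two concepts: the label property is
#' inverse-functional, which is what makes concept labels unique
#' identifiers where Linnaean names are not. Links from concepts to plain
#' scientific names are unrestricted (many-to-many).
#'
#' @param g An [rdf_graph()].
#' @param concept_id IRI for the concept.
#' @param labels List of `concept_label_parse` objects (length >= 1), or
#'   strings parseable by [parse_concept_label()].
#' @param name_ids Optional IRIs of `ScientificName` nodes linked via the
#'   scientific-name property.
#' @param seed Optional seed for minting label-node IRIs.
#' @return `concept_id`, invisibly; `g` is modified in place.
#' @export
#' @examples
#' g <- rdf_graph()
#' add_concept(g, "http://openbiodiv.net/c1",
#'   labels = list("Casuarinicola australis Taylor, 2010 sec. Thorpe"))
add_concept <- function(g, concept_id, labels, name_ids = character(), seed = NULL) {
  if (!is.list(labels) || !length(labels)) {
    stop(errorCondition("a taxonomic concept requires at least one concept label",
      class = c("taxograph_cardinality_error", "error", "condition")))
  }
  labels <- lapply(labels, function(l) {
    if (inherits(l, "concept_label_parse")) l else parse_concept_label(l)
  })
  # label uniqueness is global: normalized label string -> one concept
  new_strs <- vapply(labels, format_concept_label, character(1))
  existing <- concept_label_index(g)
  clash <- existing$label %in% new_strs & existing$concept != concept_id
  if (any(clash)) {
    stop(errorCondition(
      paste0("concept label already identifies another concept: ",
             paste(unique(existing$label[clash]), collapse = "; ")),
      class = c("taxograph_label_uniqueness_error", "error", "condition")))
  }
  mint <- iri_minter(seed = seed)
  rdf_add(g, concept_id, "rdf:type",
          c("openbiodiv:TaxonomicConcept", "skos:Concept", "frbr:Work",
            "dwc:Taxon", "openbiodiv:OperationalTaxonomicUnit"))
  for (lab in labels) {
    str <- format_concept_label(lab)
    # reuse the node if this concept already carries the same label
    prior <- existing$node[existing$label == str & existing$concept == concept_id]
    tcl <- if (length(prior)) prior[1] else mint("tcl")
    rdf_add(g, tcl, "rdf:type",
            c("openbiodiv:TaxonomicConceptLabel", "openbiodiv:TaxonomicName"))
    rdf_add_literal(g, tcl, "skos:prefLabel", str)
    rdf_add_literal(g, tcl, "openbiodiv:secReference", lab$secReference)
    rdf_add_literal(g, tcl, "openbiodiv:nameString", format_name(lab$name))
    rdf_add(g, concept_id, "openbiodiv:taxonomicConceptLabel", tcl)
    rdf_add(g, concept_id, "openbiodiv:taxonomicName", tcl)
  }
  for (nid in name_ids) {
    rdf_add(g, concept_id, "openbiodiv:scientificName", nid)
    rdf_add(g, concept_id, "openbiodiv:taxonomicName", nid)
  }
  invisible(concept_id)
}

# All (concept, label-node, label-string) triples currently in a graph.
concept_label_index <- function(g) {
  links <- rdf_match(g, p = "openbiodiv:taxonomicConceptLabel")
  if (!nrow(links)) {
    return(data.frame(concept = character(), node = character(),
                      label = character(), stringsAsFactors = FALSE))
  }
  labs <- rdf_match(g, p = "skos:prefLabel")
  labs <- labs[labs$s %in% links$o, c("s", "o")]
  out <- merge(links[, c("s", "o")], labs, by.x = "o", by.y = "s",
               suffixes = c("", ".lab"))
  data.frame(concept = out$s, node = out$o, label = out$o.lab,
             stringsAsFactors = FALSE)
}

#' Assert a name relation (replacement or related name)
#'
#' Two code-compliant patterns connect Linnaean names: *replacement name*
#' (directed; the target name should be used instead of the source, as with
#' new combinations, nomina nova and junior synonyms) and *related name*
#' (symmetric; the names are connected without stating a preference). The
#' symmetric pattern is asserted in both directions.
#'
#' @param g An [rdf_graph()].
#' @param source_id,target_id IRIs of existing `TaxonomicName` nodes.
#' @param kind `"replacementName"` or `"relatedName"`.
#' @return `g`, invisibly.
#' @export
assert_name_relation <- function(g, source_id, target_id,
                                 kind = c("replacementName", "relatedName")) {
  kind <- match.arg(kind)
  if (identical(source_id, target_id)) {
    stop("a name cannot ", if (kind == "replacementName") "replace" else "relate to",
         " itself: ", source_id)
  }
  known <- rdf_subjects(g, p = "rdf:type")
  missing <- setdiff(c(source_id, target_id), known)
  if (length(missing)) {
    stop("name node(s) not in graph: ", paste(missing, collapse = ", "))
  }
  rdf_add(g, source_id, paste0("openbiodiv:", kind), target_id)
  if (kind == "relatedName") {
    rdf_add(g, target_id, "openbiodiv:relatedName", source_id)
  }
  invisible(g)
}

#' Resolve a name along replacement chains
#'
#' Chains of replacement names are followed to find the currently used
#' name(s). A name with no outgoing replacement edge resolves to itself;
#' branching chains return every terminal (no precedence is imposed).
#' Cycles are reported, never silently broken: members of reachable cycles
#' appear in the `cycle_members` field and the `cycle` flag is set.
#'
#' @param g An [rdf_graph()].
#' @param name_id IRI of the starting name.
#' @return A list: `terminals` (character vector of terminal name IRIs),
#'   `cycle` (logical), `cycle_members` (character), `paths` (list of IRI
#'   vectors, one per terminal, giving one witness chain each).
#' @export
resolve_current_names <- function(g, name_id) {
  edges <- rdf_match(g, p = "openbiodiv:replacementName")[, c("s", "o")]
  if (!nrow(edges) || !(name_id %in% c(edges$s, edges$o))) {
    if (!nrow(rdf_match(g, s = name_id))) stop("unknown name: ", name_id)
  }
  adj <- split(edges$o, edges$s)
  reach <- character(0)
  frontier <- name_id
  while (length(frontier)) {
    reach <- union(reach, frontier)
    nxt <- unique(unlist(adj[frontier], use.names = FALSE))
    frontier <- setdiff(nxt, reach)
  }
  terminals <- reach[vapply(reach, function(v) is.null(adj[[v]]), logical(1))]

  cycle_members <- character(0)
  sub <- edges[edges$s %in% reach & edges$o %in% reach, , drop = FALSE]
  if (nrow(sub)) {
    ig <- igraph::graph_from_data_frame(sub, directed = TRUE)
    comp <- igraph::components(ig, mode = "strong")
    big <- which(comp$csize > 1L)
    cycle_members <- names(comp$membership)[comp$membership %in% big]
  }

  paths <- lapply(terminals, function(t) {
    if (identical(t, name_id)) return(name_id)
    sub2 <- edges[edges$s %in% reach, , drop = FALSE]
    ig <- igraph::graph_from_data_frame(sub2, directed = TRUE)
    p <- igraph::shortest_paths(ig, from = name_id, to = t, mode = "out")$vpath[[1]]
    names(p)
  })
  list(terminals = sort(terminals), cycle = length(cycle_members) > 0L,
       cycle_members = sort(cycle_members), paths = paths)
}

#' Names related within a few hops
#'
#' Answers the working taxonomist's question "what other names ought to be
#' considered?": all names reachable within `depth` hops over the union of
#' the related-name and replacement-name patterns, both treated as
#' undirected. The start name itself is excluded.
#'
#' @param g An [rdf_graph()].
#' @param name_id IRI of the starting name.
#' @param depth Maximum number of hops (>= 1).
#' @return Character vector of name IRIs (possibly empty).
#' @export
related_name_neighborhood <- function(g, name_id, depth = 1L) {
  if (!is.numeric(depth) || length(depth) != 1L || depth < 1) {
    stop("`depth` must be a single integer >= 1")
  }
  edges <- rbind(rdf_match(g, p = "openbiodiv:relatedName")[, c("s", "o")],
                 rdf_match(g, p = "openbiodiv:replacementName")[, c("s", "o")])
  if (!nrow(edges)) return(character(0))
  und <- unique(rbind(edges, data.frame(s = edges$o, o = edges$s)))
  adj <- split(und$o, und$s)
  seen <- name_id
  frontier <- name_id
  for (d in seq_len(depth)) {
    frontier <- setdiff(unique(unlist(adj[frontier], use.names = FALSE)), seen)
    if (!length(frontier)) break
    seen <- c(seen, frontier)
  }
  sort(setdiff(seen, name_id))
}

#' Assert a SKOS hierarchical relation between concepts
#'
#' Simple hierarchical (is-a) relations between taxonomic concepts are
#' expressed with SKOS broader/narrower. Multiple simultaneous hierarchies
#' are allowed — the same concept may sit under different parents coming
#' from different classifications — so no single-parent constraint is
#' enforced.
#'
#' @param g An [rdf_graph()].
#' @param narrower_id,broader_id IRIs of existing taxonomic concepts.
#' @return `g`, invisibly.
#' @export
assert_skos_relation <- function(g, narrower_id, broader_id) {
  if (identical(narrower_id, broader_id)) {
    stop("a concept cannot be broader than itself: ", narrower_id)
  }
  concepts <- rdf_subjects(g, p = "rdf:type", o = "openbiodiv:TaxonomicConcept")
  missing <- setdiff(c(narrower_id, broader_id), concepts)
  if (length(missing)) {
    stop("not a taxonomic concept in this graph: ", paste(missing, collapse = ", "))
  }
  rdf_add(g, narrower_id, "skos:broader", broader_id)
  rdf_add(g, broader_id, "skos:narrower", narrower_id)
  invisible(g)
}

#' Assert a reified RCC-5 statement between two concepts
#'
#' An RCC-5 statement records how two taxonomic concepts' circumscriptions
#' relate as sets, as a non-empty disjunction over the five base relations
#' (a singleton set is the determinate case; larger sets encode
#' uncertainty). The statement is reified so that provenance can be
#' attached.
#'
#' @param g An [rdf_graph()].
#' @param subject_id,object_id IRIs of distinct existing concepts.
#' @param relations Character vector, non-empty subset of
#'   [rcc5_relations()].
#' @param source Optional citation string for provenance.
#' @param statement_id Optional IRI; minted when `NULL`.
#' @param seed Optional seed for minting.
#' @return The statement IRI, invisibly; `g` is modified in place.
#' @export
assert_rcc5 <- function(g, subject_id, object_id, relations, source = NULL,
                        statement_id = NULL, seed = NULL) {
  if (!length(relations)) stop("the relation set of an RCC-5 statement must be non-empty")
  bad <- setdiff(relations, rcc5_relations())
  if (length(bad)) stop("unknown RCC-5 relation term: ", paste(bad, collapse = ", "))
  if (identical(subject_id, object_id)) {
    stop("an RCC-5 statement must relate two distinct concepts")
  }
  concepts <- rdf_subjects(g, p = "rdf:type", o = "openbiodiv:TaxonomicConcept")
  missing <- setdiff(c(subject_id, object_id), concepts)
  if (length(missing)) {
    stop("not a taxonomic concept in this graph: ", paste(missing, collapse = ", "))
  }
  if (is.null(statement_id)) statement_id <- iri_minter(seed = seed)("rcc5stmt")
  rdf_add(g, statement_id, "rdf:type", "openbiodiv:RCC5Statement")
  rdf_add(g, statement_id, "openbiodiv:rcc5Subject", subject_id)
  rdf_add(g, statement_id, "openbiodiv:rcc5Object", object_id)
  rdf_add(g, statement_id, "openbiodiv:rcc5Relation", rcc5_iri(relations))
  if (!is.null(source)) rdf_add_literal(g, statement_id, "dcterms:source", source)
  invisible(statement_id)
}

#' Link a treatment to the concept it realizes
#'
#' Taxonomic concepts are Works; the treatment section of an article is
#' their realization (the version-of-record account of the circumscription).
#' Several treatments may realize one concept across revisions.
#'
#' @param g An [rdf_graph()].
#' @param treatment_id IRI of a component typed `Treatment`.
#' @param concept_id IRI of an existing taxonomic concept.
#' @return `g`, invisibly.
#' @export
realize_treatment <- function(g, treatment_id, concept_id) {
  treatments <- rdf_subjects(g, p = "rdf:type", o = "openbiodiv:Treatment")
  if (!treatment_id %in% treatments) {
    stop("'", treatment_id, "' is not a Treatment component")
  }
  concepts <- rdf_subjects(g, p = "rdf:type", o = "openbiodiv:TaxonomicConcept")
  if (!concept_id %in% concepts) {
    stop("'", concept_id, "' is not a taxonomic concept")
  }
  rdf_add(g, concept_id, "frbr:realization", treatment_id)
  invisible(g)
}

#' Attach a habitat term to a concept
#'
#' A pass-through shortcut linking a taxonomic concept to an external
#' environment-ontology term (e.g. an ENVO biome IRI). Idempotent.
#'
#' @param g An [rdf_graph()].
#' @param concept_id IRI of an existing taxonomic concept.
#' @param habitat_iri Absolute IRI of the environment term.
#' @return `g`, invisibly.
#' @export
#' @examples
#' \dontrun{
#' attach_habitat(g, c1, "http://purl.obolibrary.org/obo/ENVO_01000174")
#' }
attach_habitat <- function(g, concept_id, habitat_iri) {
  concepts <- rdf_subjects(g, p = "rdf:type", o = "openbiodiv:TaxonomicConcept")
  if (!concept_id %in% concepts) {
    stop("'", concept_id, "' is not a taxonomic concept")
  }
  if (!is.character(habitat_iri) || length(habitat_iri) != 1L ||
      !grepl("^https?://[^ <>\"{}|\\\\^`]+$", habitat_iri)) {
    stop("`habitat_iri` is not a syntactically valid absolute IRI: ", habitat_iri)
  }
  rdf_add(g, concept_id, "openbiodiv:hasHabitat", habitat_iri)
  invisible(g)
}
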
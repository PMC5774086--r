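#' Deterministic IRI minter
#'
#' Returns a closure minting IRIs under `base` with a type prefix and a
#' UUID-like hex suffix. With a `seed` the sequence is reproducible (an
#' internal linear congruential generator is used, so the global RNG state
#' is untouched); without one the sequence is seeded from the session RNG.
#'
#' @param base Namespace base IRI.
#' @param seed Optional integer seed.
#' @return `function(prefix)` returning a fresh IRI.
#' @export
#' @examples
#' mint <- iri_minter(seed = 1)
#' mint("article")
iri_minter <- function(base = "http://openbiodiv.net/", seed = NULL) {
  state <- if (is.null(seed)) {
    sample.int(.Machine$integer.max, 1L)
  } else {
    as.integer(seed) %% .Machine$integer.max
  }
  state <- as.double(state)
  function(prefix = "id") {
    # Lehmer generator modulo the Mersenne prime 2^31 - 1
    out <- character(2L)
    for (k in 1:2) {
      state <<- (state * 48271) %% 2147483647
      out[k] <- sprintf("%08x", as.integer(state))
    }
    paste0(base, prefix, "-", out[1], out[2])
  }
}

#' Document component kinds
#'
#' The typed nodes of an article's containment tree: the article root, the
#' treatment and its subsections (nomenclature, materials examined, biology,
#' description), identification keys, regional checklists, and a generic
#' discourse element for anything else.
#'
#' @return Character vector of valid `kind` values.
#' @export
component_kinds <- function() {
  c("TaxonomicArticle", "Treatment", "NomenclatureSection",
    "NomenclatureHeading", "NomenclatureCitationList", "MaterialsExamined",
    "BiologySection", "DescriptionSection", "TaxonomicKey",
    "TaxonomicChecklist", "GenericDiscourseElement")
}

#' Create a document component node
#'
#' @param kind One of [component_kinds()].
#' @param children List of child `document_component`s (document order).
#' @param id Optional IRI; minted at build time when `NULL`.
#' @return A `document_component`.
#' @export
#' @examples
#' document_component("Treatment", children = list(
#'   document_component("NomenclatureSection")))
document_component <- function(kind, children = list(), id = NULL) {
  kind <- match.arg(kind, component_kinds())
  if (!is.list(children) ||
      !all(vapply(children, inherits, logical(1), "document_component"))) {
    stop("`children` must be a list of document_component objects")
  }
  structure(list(kind = kind, id = id, children = children),
            class = "document_component")
}

#' Article metadata
#'
#' Bibliographic metadata separated FRBR-style: the work is the intellectual
#' contribution, the expression is the version of record (the taxonomic
#' article itself).
#'
#' @param title Article title (non-empty).
#' @param authors Character vector of agent names.
#' @param doi,journal Optional strings.
#' @param work_id,expression_id Optional IRIs; minted at build time when
#'   `NULL`. They must differ.
#' @return An `article_metadata` object.
#' @export
article_metadata <- function(title, authors = character(), doi = NULL,
                             journal = NULL, work_id = NULL,
                             expression_id = NULL) {
  if (!is.character(title) || length(title) != 1L || !nzchar(trimws(title))) {
    stop("`title` must be a non-empty string")
  }
  if (!is.null(work_id) && !is.null(expression_id) &&
      identical(work_id, expression_id)) {
    stop("work and expression must be distinct resources")
  }
  structure(list(title = title, authors = authors, doi = doi,
                 journal = journal, work_id = work_id,
                 expression_id = expression_id),
            class = "article_metadata")
}

# Depth-first walk; assigns missing ids, collects nodes and edges, and
# rejects duplicate ids (a repeated id is how a cycle manifests in input).
walk_components <- function(root, mint) {
  nodes <- list()
  edges <- list()
  seen <- character(0)
  recurse <- function(node) {
    id <- if (is.null(node$id)) mint(tolower(node$kind)) else node$id
    if (id %in% seen) {
      stop("component tree is not a tree: node '", id, "' occurs twice ",
           "(cyclic or shared component)")
    }
    seen <<- c(seen, id)
    nodes[[length(nodes) + 1L]] <<- list(id = id, kind = node$kind)
    for (k in seq_along(node$children)) {
      child_id <- recurse(node$children[[k]])
      edges[[length(edges) + 1L]] <<- list(parent = id, child = child_id, order = k)
    }
    id
  }
  root_id <- recurse(root)
  list(root = root_id, nodes = nodes, edges = edges)
}

#' Build the RDF graph of a taxonomic article
#'
#' Emits FRBR work/expression metadata and the typed component tree. The
#' article root is the FRBR expression (a `TaxonomicArticle`); a separate
#' work node realizes it. Every parent-child edge in the component tree
#' becomes one asserted `contains` triple (transitive closure is computed on
#' demand by [contains_closure()], not materialized); sibling order is kept
#' in a `componentOrder` annotation.
#'
#' @param meta An [article_metadata()].
#' @param root A [document_component()] of kind `"TaxonomicArticle"`.
#' @param graph Optional existing [rdf_graph()] to extend.
#' @param seed Optional integer for deterministic IRI minting.
#' @return The [rdf_graph()], with attributes `"expression_id"` and
#'   `"work_id"` giving the minted IRIs.
#' @export
build_article_graph <- function(meta, root, graph = NULL, seed = NULL) {
  stopifnot(inherits(meta, "article_metadata"), inherits(root, "document_component"))
  if (root$kind != "TaxonomicArticle") {
    stop("the component tree root must be of kind 'TaxonomicArticle'")
  }
  g <- if (is.null(graph)) rdf_graph() else graph
  mint <- iri_minter(seed = seed)
  if (is.null(root$id)) root$id <- meta$expression_id
  tree <- walk_components(root, mint)
  expr <- tree$root
  work <- if (is.null(meta$work_id)) mint("work") else meta$work_id
  if (identical(work, expr)) stop("work and expression must be distinct resources")

  rdf_add(g, work, "rdf:type", c("frbr:Work", "fabio:ResearchPaper"))
  rdf_add(g, work, "frbr:realization", expr)
  rdf_add_literal(g, work, "dcterms:title", meta$title)
  if (length(meta$authors)) rdf_add_literal(g, work, "dcterms:creator", meta$authors)
  rdf_add_literal(g, expr, "dcterms:title", meta$title)
  if (!is.null(meta$doi)) rdf_add_literal(g, expr, "prism:doi", meta$doi)
  if (!is.null(meta$journal)) {
    j <- mint("journal")
    rdf_add(g, j, "rdf:type", "fabio:Journal")
    rdf_add_literal(g, j, "dcterms:title", meta$journal)
    rdf_add(g, expr, "frbr:partOf", j)
  }

  for (nd in tree$nodes) {
    type <- if (nd$kind == "GenericDiscourseElement") "deo:DiscourseElement"
            else paste0("openbiodiv:", nd$kind)
    rdf_add(g, nd$id, "rdf:type", type)
  }
  for (ed in tree$edges) {
    rdf_add(g, ed$parent, "openbiodiv:contains", ed$child)
    rdf_add_literal(g, ed$child, "openbiodiv:componentOrder",
                    as.character(ed$order), datatype = "xsd:integer")
  }
  attr(g, "expression_id") <- expr
  attr(g, "work_id") <- work
  g
}

#' Add a scientific-name node to a graph
#'
#' Creates (or completes) a `ScientificName` node carrying the structured
#' fields as Darwin Core literals and the verbatim form as its label.
#'
#' @param g An [rdf_graph()].
#' @param name A `scientific_name` (see [parse_scientific_name()]).
#' @param id IRI for the name node.
#' @return `id`, invisibly; `g` is modified in place.
#' @export
add_scientific_name <- function(g, name, id) {
  stopifnot(inherits(name, "scientific_name"))
  rdf_add(g, id, "rdf:type", c("openbiodiv:ScientificName", "openbiodiv:TaxonomicName"))
  rdf_add_literal(g, id, "rdfs:label", format_name(name))
  rdf_add_literal(g, id, "dwc:genus", name$genus)
  if (!is.na(name$specificEpithet)) {
    rdf_add_literal(g, id, "dwc:specificEpithet", name$specificEpithet)
  }
  if (!is.na(name$infraspecificEpithet)) {
    rdf_add_literal(g, id, "dwc:infraspecificEpithet", name$infraspecificEpithet)
    rdf_add_literal(g, id, "dwc:verbatimTaxonRank", name$infraspecificMarker)
  }
  if (!is.na(name$authorship)) {
    auth <- if (isTRUE(name$parenthesizedAuthorship)) {
      paste0("(", name$authorship, if (!is.na(name$year)) paste0(", ", name$year), ")")
    } else {
      name$authorship
    }
    rdf_add_literal(g, id, "dwc:scientificNameAuthorship", auth)
  }
  if (!is.na(name$year)) {
    rdf_add_literal(g, id, "dwc:namePublishedInYear", as.character(name$year),
                    datatype = "xsd:integer")
  }
  invisible(id)
}

#' Add a taxonomic name usage to an article graph
#'
#' A name usage is a mention: an area of a document that mentions a
#' taxonomic name. The usage node is typed `TaxonomicNameUsage`, contained
#' in its section, and linked to the name node by `mentions`; a taxonomic
#' status, when present, is attached as a concept of the status vocabulary
#' together with its verbatim abbreviation.
#'
#' @param g An [rdf_graph()] holding the article.
#' @param usage A `name_usage_parse` (see [parse_taxonomic_name_usage()]).
#' @param container_id IRI of the document component containing the usage;
#'   must exist in `g`.
#' @param name_id IRI for the mentioned name node (one name node may be
#'   mentioned by many usages).
#' @param usage_id Optional IRI for the usage node; minted when `NULL`.
#' @param seed Optional seed for minting.
#' @return The usage node IRI, invisibly; `g` is modified in place.
#' @export
add_name_usage <- function(g, usage, container_id, name_id, usage_id = NULL,
                           seed = NULL) {
  stopifnot(inherits(usage, "name_usage_parse"))
  known <- unique(c(rdf_subjects(g, p = "rdf:type"), rdf_objects(g, p = "openbiodiv:contains")))
  if (!container_id %in% known) {
    stop("unknown container: '", container_id, "' is not a node of this graph")
  }
  if (is.null(usage_id)) usage_id <- iri_minter(seed = seed)("tnu")
  add_scientific_name(g, usage$name, name_id)
  rdf_add(g, usage_id, "rdf:type", "openbiodiv:TaxonomicNameUsage")
  rdf_add_literal(g, usage_id, "rdfs:label", usage$verbatim)
  rdf_add(g, container_id, "openbiodiv:contains", usage_id)
  rdf_add(g, usage_id, "openbiodiv:mentions", name_id)
  if (!is.na(usage$status)) {
    rdf_add(g, usage_id, "openbiodiv:taxonomicStatus", status_iri(usage$status))
    rdf_add_literal(g, usage_id, "openbiodiv:verbatimStatus", usage$statusVerbatim)
  }
  invisible(usage_id)
}

#' Transitive closure of the containment property
#'
#' `contains` is transitive: a sub-subcomponent is contained in the
#' component. The closure is computed on demand from the asserted edges;
#' with `materialize = TRUE` the inferred pairs are also asserted into the
#' graph.
#'
#' @param g An [rdf_graph()].
#' @param materialize Assert the closure into `g` as well?
#' @return Data frame with columns `ancestor`, `descendant` (one row per
#'   pair in the closure; empty when nothing is contained).
#' @export
contains_closure <- function(g, materialize = FALSE) {
  edges <- rdf_match(g, p = "openbiodiv:contains")
  if (!nrow(edges)) {
    return(data.frame(ancestor = character(), descendant = character(),
                      stringsAsFactors = FALSE))
  }
  ig <- igraph::graph_from_data_frame(edges[, c("s", "o")], directed = TRUE)
  verts <- igraph::V(ig)$name
  out <- lapply(verts, function(v) {
    reach <- setdiff(names(igraph::subcomponent(ig, v, mode = "out")), v)
    if (length(reach)) data.frame(ancestor = v, descendant = reach,
                                  stringsAsFactors = FALSE)
  })
  res <- do.call(rbind, out)
  if (is.null(res)) {
    res <- data.frame(ancestor = character(), descendant = character(),
                      stringsAsFactors = FALSE)
  }
  res <- res[order(res$ancestor, res$descendant), , drop = FALSE]
  rownames(res) <- NULL
  if (materialize && nrow(res)) rdf_add(g, res$ancestor, "openbiodiv:contains", res$descendant)
  res
}
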
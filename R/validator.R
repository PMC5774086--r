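#' Validate a graph against the model's testable constraints
#'
#' Runs the closed-world rule set over the asserted triples and returns a
#' structured report. Closed-world checking is deliberate: under open-world
#' OWL semantics an inverse-functional property would *merge* two concepts
#' sharing a label rather than flag them, whereas the model's intent is
#' that concept labels be unique identifiers — a check, not an inference.
#'
#' Rules:
#' \describe{
#'   \item{R1 (error)}{every `TaxonomicConcept` carries at least one
#'     concept label (minimum-cardinality contract).}
#'   \item{R2 (error)}{no label string identifies two concepts
#'     (inverse-functional contract); labels compare as normalized strings.}
#'   \item{R3 (error)}{the scientific-name property runs from a
#'     `TaxonomicConcept` to a `ScientificName` (domain/range).}
#'   \item{R4}{every `TaxonomicNameUsage` mentions exactly one taxonomic
#'     name — zero is an error, more than one a warning.}
#'   \item{R5 (error)}{document containment is acyclic (one violation per
#'     strongly connected component, focus on its lexicographically first
#'     node).}
#'   \item{R6 (error)}{taxonomic statuses are drawn from the eight-member
#'     status vocabulary.}
#'   \item{R7 (error)}{every `RCC5Statement` has exactly one subject, one
#'     object, and at least one vocabulary relation, with subject distinct
#'     from object.}
#'   \item{R8 (error)}{only `Treatment` components realize taxonomic
#'     concepts.}
#' }
#'
#' @param g An [rdf_graph()].
#' @return A `validation_report`: list with `violations` (data frame:
#'   `ruleId`, `severity`, `focusNode`, `message`, ordered by rule then
#'   node), `passed` (no error-severity violations), and
#'   `label_comparison` (`"normalized-string"`, recording how R2 compares
#'   labels).
#' @export
#' @examples
#' g <- rdf_graph()
#' add_concept(g, "http://openbiodiv.net/c1",
#'   labels = list("Aus bus L. 1758 sec. Smith (1900)"))
#' validate_graph(g)$passed
validate_graph <- function(g) {
  stopifnot(inherits(g, "rdf_graph"))
  v <- list()
  note <- function(rule, severity, focus, msg) {
    v[[length(v) + 1L]] <<- data.frame(ruleId = rule, severity = severity,
                                       focusNode = focus, message = msg,
                                       stringsAsFactors = FALSE)
  }
  type_of <- function(o) rdf_subjects(g, p = "rdf:type", o = o)
  concepts <- type_of("openbiodiv:TaxonomicConcept")

  # R1: minimum label cardinality
  with_label <- rdf_subjects(g, p = "openbiodiv:taxonomicConceptLabel")
  for (c0 in setdiff(concepts, with_label)) {
    note("R1", "error", c0, "taxonomic concept carries no taxonomic concept label")
  }

  # R2: label uniqueness (normalized-string comparison)
  idx <- concept_label_index(g)
  if (nrow(idx)) {
    idx$norm <- squish(tolower(idx$label))
    for (lb in unique(idx$norm)) {
      owners <- unique(idx$concept[idx$norm == lb])
      if (length(owners) > 1L) {
        for (c0 in owners) {
          note("R2", "error", c0,
               paste0("concept label '", idx$label[idx$norm == lb][1],
                      "' identifies ", length(owners), " concepts"))
        }
      }
    }
  }

  # R3: scientificName domain and range
  sn <- rdf_match(g, p = "openbiodiv:scientificName")
  sci_names <- type_of("openbiodiv:ScientificName")
  for (k in seq_len(nrow(sn))) {
    if (!sn$s[k] %in% concepts) {
      note("R3", "error", sn$s[k],
           "scientific-name property used on a node that is not a taxonomic concept")
    } else if (!sn$o[k] %in% sci_names) {
      note("R3", "error", sn$s[k],
           paste0("scientific-name property points at '", sn$o[k],
                  "', which is not a ScientificName"))
    }
  }

  # R4: every name usage mentions exactly one name
  usages <- type_of("openbiodiv:TaxonomicNameUsage")
  mentions <- rdf_match(g, p = "openbiodiv:mentions")
  for (u in usages) {
    k <- sum(mentions$s == u)
    if (k == 0L) {
      note("R4", "error", u, "taxonomic name usage mentions no taxonomic name")
    } else if (k > 1L) {
      note("R4", "warning", u,
           paste0("taxonomic name usage mentions ", k, " names (expected one)"))
    }
  }

  # R5: containment acyclic
  ce <- rdf_match(g, p = "openbiodiv:contains")
  if (nrow(ce)) {
    ig <- igraph::graph_from_data_frame(ce[, c("s", "o")], directed = TRUE)
    comp <- igraph::components(ig, mode = "strong")
    loops <- ce$s[ce$s == ce$o]
    cyc <- which(comp$csize > 1L)
    for (cc in cyc) {
      members <- sort(names(comp$membership)[comp$membership == cc])
      note("R5", "error", members[1],
           paste0("containment cycle through: ", paste(members, collapse = " -> ")))
    }
    for (l in unique(loops)) {
      note("R5", "error", l, "component contains itself")
    }
  }

  # R6: statuses from the eight-member vocabulary
  st <- rdf_match(g, p = "openbiodiv:taxonomicStatus")
  valid_status <- vapply(status_classes(), status_iri, character(1))
  for (k in seq_len(nrow(st))) {
    if (!st$o[k] %in% valid_status) {
      note("R6", "error", st$s[k],
           paste0("taxonomic status '", st$o[k], "' is not in the status vocabulary"))
    }
  }

  # R7: RCC-5 statements well-formed
  stmts <- type_of("openbiodiv:RCC5Statement")
  rel_iris <- vapply(rcc5_relations(), rcc5_iri, character(1))
  for (s0 in stmts) {
    subj <- rdf_objects(g, s = s0, p = "openbiodiv:rcc5Subject")
    obj <- rdf_objects(g, s = s0, p = "openbiodiv:rcc5Object")
    rels <- rdf_objects(g, s = s0, p = "openbiodiv:rcc5Relation")
    if (length(subj) != 1L || length(obj) != 1L) {
      note("R7", "error", s0, "RCC-5 statement must have exactly one subject and one object")
    } else if (identical(subj, obj)) {
      note("R7", "error", s0, "RCC-5 statement relates a concept to itself")
    } else if (!length(rels) || !all(rels %in% rel_iris)) {
      note("R7", "error", s0, "RCC-5 statement lacks a valid vocabulary relation")
    }
  }

  # R8: realization type check (concepts are realized by treatments)
  treatments <- type_of("openbiodiv:Treatment")
  re <- rdf_match(g, p = "frbr:realization")
  for (k in seq_len(nrow(re))) {
    if (re$s[k] %in% concepts && !re$o[k] %in% treatments) {
      note("R8", "error", re$o[k],
           paste0("concept '", re$s[k], "' realized by a non-treatment component"))
    }
  }

  violations <- if (length(v)) do.call(rbind, v) else
    data.frame(ruleId = character(), severity = character(),
               focusNode = character(), message = character(),
               stringsAsFactors = FALSE)
  violations <- violations[order(violations$ruleId, violations$focusNode), , drop = FALSE]
  rownames(violations) <- NULL
  structure(list(violations = violations,
                 passed = !any(violations$severity == "error"),
                 label_comparison = "normalized-string"),
            class = "validation_report")
}

#' @export
print.validation_report <- function(x, ...) {
  cat("<validation_report> ", if (x$passed) "PASSED" else "FAILED",
      ": ", sum(x$violations$severity == "error"), " error(s), ",
      sum(x$violations$severity == "warning"), " warning(s)\n", sep = "")
  if (nrow(x$violations)) print(x$violations)
  invisible(x)
}
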
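#' @title RCC-5 qualitative reasoning
#' @name rcc5_reasoner
#' @description
#' Constraint-based reasoning over the five base relations of RCC-5 read
#' over non-empty sets: `EQ` (equal), `PP` (strict subset), `PPi` (strict
#' superset), `PO` (partial overlap), `DR` (disjoint). Edge labels are
#' *relation sets* — non-empty disjunctions over the base relations, with
#' the full five-set meaning "no information". The reasoner implements
#' composition-based path consistency (sound but incomplete) together with
#' an exhaustive finite-model oracle for desk-scale verification; full
#' answer-set reasoning is deliberately out of scope.
NULL

# Bit encoding of relation sets, in rcc5_relations() order.
rcc5_bits <- c(EQ = 1L, PP = 2L, PPi = 4L, PO = 8L, DR = 16L)
RCC5_ALL <- 31L

#' Convert between relation names and bit masks
#' @param relations Character vector of base relations.
#' @return `rcc5_mask()`: integer mask. `rcc5_unmask()`: character vector.
#' @export
rcc5_mask <- function(relations) {
  bad <- setdiff(relations, names(rcc5_bits))
  if (length(bad)) stop("unknown RCC-5 relation: ", paste(bad, collapse = ", "))
  as.integer(sum(rcc5_bits[unique(relations)]))
}

#' @rdname rcc5_mask
#' @param mask Integer bit mask.
#' @export
rcc5_unmask <- function(mask) {
  names(rcc5_bits)[bitwAnd(mask, rcc5_bits) > 0L]
}

mask_converse <- function(mask) {
  out <- 0L
  for (r in names(rcc5_bits)) {
    if (bitwAnd(mask, rcc5_bits[[r]]) > 0L) out <- bitwOr(out, rcc5_bits[[rcc5_converse(r)]])
  }
  out
}

# Hand-stated base composition table: entry [r1, r2] is the set of base
# relations consistent with (a r1 b) and (b r2 c), under the set semantics.
base_composition <- function() {
  R <- rcc5_relations()
  tab <- matrix(vector("list", 25), 5, 5, dimnames = list(R, R))
  all5 <- R
  tab[["EQ", "EQ"]] <- "EQ"; tab[["EQ", "PP"]] <- "PP"; tab[["EQ", "PPi"]] <- "PPi"
  tab[["EQ", "PO"]] <- "PO"; tab[["EQ", "DR"]] <- "DR"
  tab[["PP", "EQ"]] <- "PP"
  tab[["PP", "PP"]] <- "PP"
  tab[["PP", "PPi"]] <- all5
  tab[["PP", "PO"]] <- c("PP", "PO", "DR")
  tab[["PP", "DR"]] <- "DR"
  tab[["PPi", "EQ"]] <- "PPi"
  tab[["PPi", "PP"]] <- c("EQ", "PP", "PPi", "PO")
  tab[["PPi", "PPi"]] <- "PPi"
  tab[["PPi", "PO"]] <- c("PPi", "PO")
  tab[["PPi", "DR"]] <- c("PPi", "PO", "DR")
  tab[["PO", "EQ"]] <- "PO"
  tab[["PO", "PP"]] <- c("PP", "PO")
  tab[["PO", "PPi"]] <- c("PPi", "PO", "DR")
  tab[["PO", "PO"]] <- all5
  tab[["PO", "DR"]] <- c("PPi", "PO", "DR")
  tab[["DR", "EQ"]] <- "DR"
  tab[["DR", "PP"]] <- c("PP", "PO", "DR")
  tab[["DR", "PPi"]] <- "DR"
  tab[["DR", "PO"]] <- c("PP", "PO", "DR")
  tab[["DR", "DR"]] <- all5
  tab
}

# cached 32x32 mask-composition table
rcc5_env <- new.env(parent = emptyenv())

mask_comp_table <- function() {
  if (!is.null(rcc5_env$comp)) return(rcc5_env$comp)
  base <- base_composition()
  R <- rcc5_relations()
  base_masks <- matrix(0L, 5, 5, dimnames = list(R, R))
  for (r1 in R) for (r2 in R) base_masks[r1, r2] <- rcc5_mask(base[[r1, r2]])
  comp <- matrix(0L, 32, 32)
  for (m1 in 1:31) {
    r1s <- rcc5_unmask(m1)
    for (m2 in 1:31) {
      out <- 0L
      for (r1 in r1s) for (r2 in rcc5_unmask(m2)) {
        out <- bitwOr(out, base_masks[r1, r2])
      }
      comp[m1 + 1L, m2 + 1L] <- out
    }
  }
  rcc5_env$comp <- comp
  comp
}

#' Compose two RCC-5 relations
#'
#' The composition of `r1` and `r2` is the set of base relations `r` such
#' that some sets a, b, c satisfy `a r1 b`, `b r2 c` and `a r c`. Accepts
#' base relations or relation sets.
#'
#' @param r1,r2 Character vectors of base relations.
#' @return Character vector: the composed relation set (in
#'   [rcc5_relations()] order).
#' @export
#' @examples
#' rcc5_compose("PP", "PP")
#' rcc5_compose("EQ", "DR")
rcc5_compose <- function(r1, r2) {
  comp <- mask_comp_table()
  rcc5_unmask(comp[rcc5_mask(r1) + 1L, rcc5_mask(r2) + 1L])
}

#' Create an RCC-5 constraint network
#'
#' Edges default to the full five-relation set (no information); the
#' diagonal is fixed at `{EQ}`. The converse closure — `edge(j,i)` equal to
#' the converse set of `edge(i,j)` — is maintained by [rcc5_set_edge()].
#'
#' @param nodes Character vector of node identifiers (concept IDs).
#' @return An `rcc5_network`.
#' @export
rcc5_network <- function(nodes) {
  nodes <- as.character(nodes)
  if (anyDuplicated(nodes)) stop("duplicate node identifiers")
  n <- length(nodes)
  m <- matrix(RCC5_ALL, n, n, dimnames = list(nodes, nodes))
  diag(m) <- rcc5_bits[["EQ"]]
  structure(list(nodes = nodes, m = m), class = "rcc5_network")
}

#' Constrain an edge of a network
#'
#' Intersects the current label of `(i, j)` with `relations` and keeps the
#' converse edge in step. Constraining to the empty set is allowed and
#' marks the network inconsistent.
#'
#' @param net An [rcc5_network()].
#' @param i,j Node identifiers (distinct).
#' @param relations Character vector of base relations.
#' @return The updated network.
#' @export
rcc5_set_edge <- function(net, i, j, relations) {
  stopifnot(inherits(net, "rcc5_network"))
  if (identical(i, j)) stop("the diagonal is fixed at {EQ}")
  mask <- rcc5_mask(relations)
  net$m[i, j] <- bitwAnd(net$m[i, j], mask)
  net$m[j, i] <- mask_converse(net$m[i, j])
  net
}

#' Relation set currently on an edge
#' @param net An [rcc5_network()].
#' @param i,j Node identifiers.
#' @return Character vector of base relations (empty if contradicted).
#' @export
rcc5_edge <- function(net, i, j) rcc5_unmask(net$m[i, j])

#' @export
print.rcc5_network <- function(x, ...) {
  cat("<rcc5_network> ", length(x$nodes), " nodes\n", sep = "")
  invisible(x)
}

#' Enforce path consistency on a constraint network
#'
#' Repeatedly refines `edge(i,j)` by intersecting it with the union of
#' compositions through every third node until a fixpoint is reached.
#' Refinement is monotone (labels only shrink). An empty label proves
#' inconsistency; path consistency is sound but incomplete, so a
#' path-consistent network is only "consistent so far".
#'
#' @param net An [rcc5_network()].
#' @return A list: `consistent` (logical; `FALSE` iff some edge became
#'   empty), `network` (the refined [rcc5_network()]), `empty_edges`
#'   (two-column matrix of node pairs contradicted, if any).
#' @export
path_consistency <- function(net) {
  stopifnot(inherits(net, "rcc5_network"))
  comp <- mask_comp_table()
  m <- net$m
  n <- nrow(m)
  if (n >= 2L) {
    repeat {
      changed <- FALSE
      for (i in seq_len(n)) for (j in seq_len(n)) {
        if (i == j) next
        cur <- m[i, j]
        for (k in seq_len(n)) {
          if (k == i || k == j) next
          if (m[i, k] == 0L || m[k, j] == 0L) { cur <- 0L; break }
          cur <- bitwAnd(cur, comp[m[i, k] + 1L, m[k, j] + 1L])
          if (cur == 0L) break
        }
        if (cur != m[i, j]) {
          m[i, j] <- cur
          m[j, i] <- mask_converse(cur)
          changed <- TRUE
        }
      }
      if (!changed) break
    }
  }
  net$m <- m
  empties <- which(m == 0L, arr.ind = TRUE)
  empties <- empties[empties[, 1] < empties[, 2], , drop = FALSE]
  pairs <- cbind(net$nodes[empties[, 1]], net$nodes[empties[, 2]])
  list(consistent = nrow(pairs) == 0L, network = net, empty_edges = pairs)
}

# Base relation between two concrete subsets encoded as bit masks.
subset_relation <- function(a, b) {
  if (a == b) return("EQ")
  inter <- bitwAnd(a, b)
  if (inter == a) return("PP")
  if (inter == b) return("PPi")
  if (inter == 0L) return("DR")
  "PO"
}

#' Exhaustive finite-model check of a constraint network
#'
#' Decides satisfiability by assigning non-empty subsets of a finite
#' universe to the nodes (backtracking with forward filtering) and testing
#' whether some assignment realizes one base relation from every edge set.
#' This is the verification oracle for [path_consistency()]; the search is
#' exhaustive, so both node count and universe size are capped.
#'
#' @param net An [rcc5_network()] with at most 6 nodes.
#' @param universe_size Universe cardinality, between 1 and 6.
#' @return `TRUE` (satisfiable over that universe) or `FALSE`.
#' @export
model_check_oracle <- function(net, universe_size = 4L) {
  stopifnot(inherits(net, "rcc5_network"))
  n <- length(net$nodes)
  if (n > 6L) stop("exhaustive search bound exceeded: at most 6 nodes")
  if (universe_size < 1L || universe_size > 6L) {
    stop("exhaustive search bound exceeded: universe size must be in 1..6")
  }
  if (n == 0L) return(TRUE)
  if (any(net$m == 0L)) return(FALSE)
  subsets <- seq_len(2L^universe_size - 1L)
  ns <- length(subsets)
  relidx <- matrix(0L, ns, ns)
  for (a in subsets) for (b in subsets) {
    relidx[a, b] <- rcc5_bits[[subset_relation(a, b)]]
  }
  m <- net$m
  assign_next <- function(k, chosen) {
    if (k > n) return(TRUE)
    cand <- subsets
    for (j in seq_len(k - 1L)) {
      cand <- cand[bitwAnd(relidx[cand, chosen[j]], m[k, j]) > 0L]
      if (!length(cand)) return(FALSE)
    }
    for (val in cand) {
      chosen[k] <- val
      if (assign_next(k + 1L, chosen)) return(TRUE)
    }
    FALSE
  }
  assign_next(1L, integer(n))
}

#' Check the RCC-5 statements of an RDF graph for consistency
#'
#' Extracts the constraint network from the reified RCC-5 statements of a
#' graph, runs [path_consistency()], and reports the refined edges together
#' with any inconsistency and the statement IRIs contributing to it.
#' Malformed statements (missing subject/object, empty or unknown relation
#' set, subject equal to object) are listed as warnings and excluded from
#' the network.
#'
#' @param g An [rdf_graph()] containing RCC-5 statement nodes.
#' @param import_skos Also import SKOS broader/narrower links between
#'   concepts as `{PP}`/`{PPi}` edges? Off by default: the two mechanisms
#'   are parallel, not equivalent.
#' @return An `rcc5_report` list: `verdict` (`"consistent"`,
#'   `"inconsistent"` or `"empty"`), `edges` (data frame of refined
#'   edges), `culprits` (statement IRIs contributing to an inconsistency),
#'   `warnings` (character), `network` (the refined [rcc5_network()], or
#'   `NULL` when empty).
#' @export
check_graph <- function(g, import_skos = FALSE) {
  stmts <- rdf_subjects(g, p = "rdf:type", o = "openbiodiv:RCC5Statement")
  warnings <- character(0)
  rows <- list()
  iri2rel <- stats::setNames(rcc5_relations(), vapply(rcc5_relations(), rcc5_iri, character(1)))
  for (st in stmts) {
    subj <- rdf_objects(g, s = st, p = "openbiodiv:rcc5Subject")
    obj <- rdf_objects(g, s = st, p = "openbiodiv:rcc5Object")
    rels <- rdf_objects(g, s = st, p = "openbiodiv:rcc5Relation")
    relnames <- unname(iri2rel[rels])
    if (length(subj) != 1L || length(obj) != 1L) {
      warnings <- c(warnings, paste0(st, ": statement must have exactly one subject and one object"))
      next
    }
    if (identical(subj, obj)) {
      warnings <- c(warnings, paste0(st, ": subject and object concepts coincide"))
      next
    }
    if (!length(relnames) || anyNA(relnames)) {
      warnings <- c(warnings, paste0(st, ": empty or unknown relation set"))
      next
    }
    rows[[length(rows) + 1L]] <- list(id = st, s = subj, o = obj, rel = relnames)
  }
  skos_rows <- list()
  if (import_skos) {
    br <- rdf_match(g, p = "skos:broader")
    for (k in seq_len(nrow(br))) {
      skos_rows[[length(skos_rows) + 1L]] <-
        list(id = paste0("skos:", br$s[k], ">", br$o[k]), s = br$s[k], o = br$o[k], rel = "PP")
    }
  }
  rows <- c(rows, skos_rows)
  if (!length(rows)) {
    return(structure(list(verdict = "empty",
                          edges = data.frame(from = character(), to = character(),
                                             relations = character(), stringsAsFactors = FALSE),
                          culprits = character(0), warnings = warnings, network = NULL),
                     class = "rcc5_report"))
  }
  nodes <- unique(unlist(lapply(rows, function(r) c(r$s, r$o))))
  net <- rcc5_network(nodes)
  for (r in rows) net <- rcc5_set_edge(net, r$s, r$o, r$rel)
  res <- path_consistency(net)

  culprits <- character(0)
  if (!res$consistent) {
    on_empty <- vapply(rows, function(r) {
      any(apply(res$empty_edges, 1L, function(pr) setequal(pr, c(r$s, r$o))))
    }, logical(1))
    culprits <- unique(vapply(rows[on_empty], `[[`, character(1), "id"))
    if (!length(culprits)) {
      # inconsistency surfaced on a derived edge: cite every statement
      # touching the contradicted pairs' connected component
      culprits <- unique(vapply(rows, `[[`, character(1), "id"))
    }
  }
  m <- res$network$m
  idx <- which(upper.tri(m), arr.ind = TRUE)
  informative <- idx[m[idx] != RCC5_ALL, , drop = FALSE]
  edges <- data.frame(
    from = nodes[informative[, 1]], to = nodes[informative[, 2]],
    relations = vapply(seq_len(nrow(informative)), function(k) {
      paste(rcc5_unmask(m[informative[k, 1], informative[k, 2]]), collapse = "|")
    }, character(1)),
    stringsAsFactors = FALSE
  )
  structure(list(verdict = if (res$consistent) "consistent" else "inconsistent",
                 edges = edges, culprits = sort(culprits), warnings = warnings,
                 network = res$network),
            class = "rcc5_report")
}

#' @export
print.rcc5_report <- function(x, ...) {
  cat("<rcc5_report> verdict: ", x$verdict, "; ", nrow(x$edges),
      " informative edge(s); ", length(x$warnings), " warning(s)\n", sep = "")
  invisible(x)
}
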
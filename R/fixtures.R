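#' Specify a synthetic fixture
#'
#' Parameters of the deterministic fixture generator. Defaults describe a
#' small but structurally complete corpus: two articles of two treatments
#' each, a dozen names with sparse replacement/related links, six concepts
#' under one hierarchy, and a moderately dense RCC-5 network.
#'
#' @param seed Integer seed; same seed and spec give byte-identical output.
#' @param n_articles,n_treatments_per_article,n_names,n_concepts,n_hierarchies
#'   Non-negative counts.
#' @param p_replacement,p_related Edge probabilities in `[0, 1]` for the
#'   replacement-name DAG and the related-name pattern.
#' @param rcc5_density Probability in `[0, 1]` that a concept pair receives
#'   an RCC-5 statement.
#' @param injections Character vector of violation kinds to inject, from
#'   [injection_kinds()]; each listed kind is injected once.
#' @return A `fixture_spec`.
#' @export
fixture_spec <- function(seed = 1L, n_articles = 2L, n_treatments_per_article = 2L,
                         n_names = 12L, p_replacement = 0.15, p_related = 0.1,
                         n_concepts = 6L, n_hierarchies = 1L, rcc5_density = 0.3,
                         injections = character()) {
  counts <- c(n_articles, n_treatments_per_article, n_names, n_concepts, n_hierarchies)
  if (any(counts < 0)) stop("counts must be >= 0")
  probs <- c(p_replacement, p_related, rcc5_density)
  if (any(probs < 0 | probs > 1)) stop("probabilities must lie in [0, 1]")
  bad <- setdiff(injections, injection_kinds())
  if (length(bad)) stop("unknown injection kind: ", paste(bad, collapse = ", "))
  if (length(injections)) {
    if ("shared-label" %in% injections && n_concepts < 1L) {
      stop("'shared-label' injection requires at least one concept")
    }
    if ("replacement-cycle" %in% injections && n_names < 2L) {
      stop("'replacement-cycle' injection requires at least two names")
    }
    if (any(injections %in% c("bad-status", "zero-mention", "name-domain",
                              "bad-realization", "containment-cycle")) &&
        (n_articles < 1L || n_treatments_per_article < 1L || n_names < 1L)) {
      stop("document-level injections require an article, a treatment and a name")
    }
    if ("bad-rcc5" %in% injections && n_concepts < 2L) {
      stop("'bad-rcc5' injection requires at least two concepts")
    }
  }
  structure(list(seed = as.integer(seed), n_articles = as.integer(n_articles),
                 n_treatments_per_article = as.integer(n_treatments_per_article),
                 n_names = as.integer(n_names), p_replacement = p_replacement,
                 p_related = p_related, n_concepts = as.integer(n_concepts),
                 n_hierarchies = as.integer(n_hierarchies),
                 rcc5_density = rcc5_density, injections = injections),
            class = "fixture_spec")
}

#' Violation kinds the generator can inject
#'
#' Each kind seeds exactly one defect and records the validator rule and
#' focus node it must trigger in the manifest (`replacement-cycle` is the
#' exception: it defeats chain resolution, not a validator rule, so its
#' manifest entry carries no rule id).
#'
#' @return Character vector of kind names.
#' @export
injection_kinds <- function() {
  c("zero-label", "shared-label", "name-domain", "zero-mention",
    "containment-cycle", "bad-status", "bad-rcc5", "bad-realization",
    "replacement-cycle")
}

# run code under a seed without disturbing the caller's RNG state
with_local_seed <- function(seed, code) {
  if (exists(".Random.seed", globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(if (exists(".Random.seed", globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv()), add = TRUE)
  }
  set.seed(seed)
  force(code)
}

# pronounceable pseudo-Latin, so parser round trips see realistic shapes
syllables <- c("ba", "ca", "da", "fe", "ge", "hi", "ko", "la", "mi", "no",
               "pu", "ra", "si", "ta", "ve", "xo", "zu", "or", "an", "ul")
author_pool <- c("Smith", "Deltschev", "Taylor", "Mulsant", "Poorani",
                 "Blomquist", "Thorpe", "Linnaeus", "Fabricius", "Koch",
                 "Simon", "Walckenaer")

random_word <- function(n_syll) paste(sample(syllables, n_syll, replace = TRUE), collapse = "")

random_name_string <- function() {
  genus <- random_word(sample(2:3, 1))
  substr(genus, 1, 1) <- toupper(substr(genus, 1, 1))
  epithet <- random_word(sample(2:4, 1))
  auth <- sample(author_pool, 1)
  year <- sample(1850:2020, 1)
  paren <- stats::runif(1) < 0.25
  if (paren) {
    paste0(genus, " ", epithet, " (", auth, ", ", year, ")")
  } else {
    paste(genus, epithet, auth, year)
  }
}

fx_iri <- function(...) obn(paste0("fixture/", paste(..., sep = "/")))

#' Generate a synthetic fixture graph
#'
#' Builds a complete knowledge graph from a [fixture_spec()]: articles with
#' typed component trees (every treatment carries a nomenclature section,
#' optionally materials-examined, description and biology subsections),
#' pseudo-Latin scientific names with usages and statuses drawn from the
#' eight-class vocabulary, an acyclic replacement-name graph, symmetric
#' related-name links, concepts with globally unique labels arranged in one
#' or more parallel SKOS hierarchies, treatment realizations, and RCC-5
#' statements read off a concrete ground-truth set assignment over a small
#' universe (hence satisfiable by construction). Requested violations are
#' injected afterwards and recorded in the manifest.
#'
#' @param spec A [fixture_spec()].
#' @return A list: `graph` (the [rdf_graph()]) and `manifest` (a list with
#'   `spec` echo, entity inventories — `articles`, `treatments`, `names`,
#'   `usages`, `concepts`, `statements` —, the `ground_truth` set
#'   assignment, and `violations`, a data frame of kind/rule/focus rows for
#'   every injected defect).
#' @export
#' @examples
#' fx <- gen_fixture(fixture_spec(seed = 42, injections = "shared-label"))
#' validate_graph(fx$graph)$passed
gen_fixture <- function(spec) {
  stopifnot(inherits(spec, "fixture_spec"))
  with_local_seed(spec$seed, gen_fixture_impl(spec))
}

gen_fixture_impl <- function(spec) {
  g <- rdf_graph()
  manifest <- list(spec = unclass(spec))
  sid <- spec$seed

  # --- names ------------------------------------------------------------
  name_strings <- character(0)
  while (length(name_strings) < spec$n_names) {
    name_strings <- unique(c(name_strings, random_name_string()))
  }
  name_ids <- vapply(seq_len(spec$n_names), function(i) fx_iri(sid, paste0("name", i)),
                     character(1))
  parsed_names <- lapply(name_strings, parse_scientific_name)
  for (i in seq_len(spec$n_names)) add_scientific_name(g, parsed_names[[i]], name_ids[i])

  # --- articles and usages ----------------------------------------------
  articles <- character(0)
  treatments <- character(0)
  usages <- character(0)
  usage_counter <- 0L
  for (a in seq_len(spec$n_articles)) {
    art_id <- fx_iri(sid, paste0("article", a))
    tr_list <- list()
    for (t in seq_len(spec$n_treatments_per_article)) {
      subsections <- list(document_component("NomenclatureSection",
        id = fx_iri(sid, paste0("a", a, "-t", t, "-nomen")),
        children = list(document_component("NomenclatureHeading",
          id = fx_iri(sid, paste0("a", a, "-t", t, "-heading"))))))
      for (extra in c("MaterialsExamined", "DescriptionSection", "BiologySection")) {
        if (stats::runif(1) < 0.5) {
          subsections <- c(subsections, list(document_component(extra,
            id = fx_iri(sid, paste0("a", a, "-t", t, "-", tolower(extra))))))
        }
      }
      tr_list <- c(tr_list, list(document_component("Treatment",
        id = fx_iri(sid, paste0("a", a, "-t", t)), children = subsections)))
    }
    root <- document_component("TaxonomicArticle", id = art_id, children = tr_list)
    meta <- article_metadata(
      title = paste("Synthetic revision", a, "of", random_word(3)),
      authors = sample(author_pool, 2),
      doi = sprintf("10.9999/fx.%d.%d", sid, a),
      journal = "Journal of Synthetic Taxonomy",
      work_id = fx_iri(sid, paste0("work", a))
    )
    g <- build_article_graph(meta, root, graph = g, seed = sid * 1000L + a)
    articles <- c(articles, art_id)
    tr_ids <- vapply(tr_list, function(x) x$id, character(1))
    treatments <- c(treatments, tr_ids)

    if (spec$n_names > 0L) {
      for (t in seq_along(tr_list)) {
        nomen <- tr_list[[t]]$children[[1]]$id
        for (u in seq_len(sample(1:3, 1))) {
          usage_counter <- usage_counter + 1L
          ni <- sample(spec$n_names, 1)
          txt <- name_strings[ni]
          if (stats::runif(1) < 0.4) {
            cls <- sample(status_classes(), 1)
            txt <- paste0(txt, ", ", status_abbreviations()[[cls]][1])
          }
          uid <- fx_iri(sid, paste0("tnu", usage_counter))
          add_name_usage(g, parse_taxonomic_name_usage(txt), nomen,
                         name_ids[ni], usage_id = uid)
          usages <- c(usages, uid)
        }
      }
    }
  }

  # --- name relations (replacement DAG + related links) ------------------
  if (spec$n_names >= 2L) {
    for (i in seq_len(spec$n_names - 1L)) {
      for (j in (i + 1L):spec$n_names) {
        if (stats::runif(1) < spec$p_replacement) {
          assert_name_relation(g, name_ids[i], name_ids[j], "replacementName")
        }
        if (stats::runif(1) < spec$p_related) {
          assert_name_relation(g, name_ids[i], name_ids[j], "relatedName")
        }
      }
    }
  }

  # --- concepts, hierarchies, realizations, RCC-5 ------------------------
  concept_ids <- character(0)
  statements <- character(0)
  ground_truth <- integer(0)
  if (spec$n_concepts > 0L && spec$n_names > 0L) {
    concept_ids <- vapply(seq_len(spec$n_concepts),
                          function(i) fx_iri(sid, paste0("concept", i)), character(1))
    refs <- paste0(sample(author_pool, spec$n_concepts, replace = TRUE),
                   " (", sample(1900:2020, spec$n_concepts, replace = TRUE), ")")
    for (i in seq_len(spec$n_concepts)) {
      ni <- ((i - 1L) %% spec$n_names) + 1L
      label <- paste(name_strings[ni], "sec.", refs[i])
      # regenerate the reference on collision so labels stay unique
      while (label %in% concept_label_index(g)$label) {
        refs[i] <- paste0(sample(author_pool, 1), " (", sample(1900:2020, 1), ")")
        label <- paste(name_strings[ni], "sec.", refs[i])
      }
      add_concept(g, concept_ids[i], labels = list(label),
                  name_ids = name_ids[ni], seed = sid * 100L + i)
      if (length(treatments)) {
        tr <- treatments[((i - 1L) %% length(treatments)) + 1L]
        realize_treatment(g, tr, concept_ids[i])
      }
    }
    if (spec$n_concepts >= 2L) {
      for (h in seq_len(spec$n_hierarchies)) {
        ord <- sample(spec$n_concepts)
        for (k in 2:spec$n_concepts) {
          parent <- ord[sample(k - 1L, 1)]
          assert_skos_relation(g, concept_ids[ord[k]], concept_ids[parent])
        }
      }
      # ground-truth sets over a 5-element universe make every statement
      # satisfiable by construction
      ground_truth <- sample.int(31L, spec$n_concepts, replace = TRUE)
      names(ground_truth) <- concept_ids
      stmt_counter <- 0L
      for (i in seq_len(spec$n_concepts - 1L)) {
        for (j in (i + 1L):spec$n_concepts) {
          if (stats::runif(1) < spec$rcc5_density) {
            stmt_counter <- stmt_counter + 1L
            rel <- subset_relation(ground_truth[i], ground_truth[j])
            stid <- fx_iri(sid, paste0("rcc5stmt", stmt_counter))
            assert_rcc5(g, concept_ids[i], concept_ids[j], rel,
                        source = "fixture ground truth", statement_id = stid)
            statements <- c(statements, stid)
          }
        }
      }
    }
    attach_habitat(g, concept_ids[1],
                   "http://purl.obolibrary.org/obo/ENVO_01000174")
  }

  # --- injections ---------------------------------------------------------
  viol <- list()
  mark <- function(kind, rule, focus) {
    viol[[length(viol) + 1L]] <<- data.frame(kind = kind, rule = rule,
                                             focus = focus, stringsAsFactors = FALSE)
  }
  for (kind in spec$injections) {
    switch(kind,
      "zero-label" = {
        bad <- fx_iri(sid, "inj-concept-nolabel")
        rdf_add(g, bad, "rdf:type", "openbiodiv:TaxonomicConcept")
        mark(kind, "R1", bad)
      },
      "shared-label" = {
        victim <- concept_ids[1]
        lab <- concept_label_index(g)
        lab <- lab[lab$concept == victim, , drop = FALSE]
        thief <- fx_iri(sid, "inj-concept-sharedlabel")
        tcl <- fx_iri(sid, "inj-tcl-shared")
        rdf_add(g, thief, "rdf:type", "openbiodiv:TaxonomicConcept")
        rdf_add(g, tcl, "rdf:type", "openbiodiv:TaxonomicConceptLabel")
        rdf_add_literal(g, tcl, "skos:prefLabel", lab$label[1])
        rdf_add(g, thief, "openbiodiv:taxonomicConceptLabel", tcl)
        mark(kind, "R2", victim)
        mark(kind, "R2", thief)
      },
      "name-domain" = {
        rdf_add(g, treatments[1], "openbiodiv:scientificName", name_ids[1])
        mark(kind, "R3", treatments[1])
      },
      "zero-mention" = {
        bad <- fx_iri(sid, "inj-tnu-nomention")
        rdf_add(g, bad, "rdf:type", "openbiodiv:TaxonomicNameUsage")
        rdf_add(g, treatments[1], "openbiodiv:contains", bad)
        mark(kind, "R4", bad)
      },
      "containment-cycle" = {
        # close the chain article -> treatment -> article; the validator
        # reports the resulting SCC once, on its lexicographic minimum
        rdf_add(g, treatments[1], "openbiodiv:contains", articles[1])
        scc <- scc_members_containing(g, articles[1])
        mark(kind, "R5", sort(scc)[1])
      },
      "bad-status" = {
        bad <- fx_iri(sid, "inj-tnu-badstatus")
        rdf_add(g, bad, "rdf:type", "openbiodiv:TaxonomicNameUsage")
        rdf_add(g, treatments[1], "openbiodiv:contains", bad)
        rdf_add(g, bad, "openbiodiv:mentions", name_ids[1])
        rdf_add(g, bad, "openbiodiv:taxonomicStatus", obn("NotAStatus"))
        mark(kind, "R6", bad)
      },
      "bad-rcc5" = {
        bad <- fx_iri(sid, "inj-rcc5-norel")
        rdf_add(g, bad, "rdf:type", "openbiodiv:RCC5Statement")
        rdf_add(g, bad, "openbiodiv:rcc5Subject", concept_ids[1])
        rdf_add(g, bad, "openbiodiv:rcc5Object", concept_ids[2])
        mark(kind, "R7", bad)
      },
      "bad-realization" = {
        target <- rdf_objects(g, s = treatments[1], p = "openbiodiv:contains")[1]
        rdf_add(g, concept_ids[1], "frbr:realization", target)
        mark(kind, "R8", target)
      },
      "replacement-cycle" = {
        assert_name_relation(g, name_ids[1], name_ids[2], "replacementName")
        assert_name_relation(g, name_ids[2], name_ids[1], "replacementName")
        mark(kind, NA_character_, sort(c(name_ids[1], name_ids[2]))[1])
      }
    )
  }

  manifest$articles <- articles
  manifest$treatments <- treatments
  manifest$names <- name_ids
  manifest$name_strings <- name_strings
  manifest$usages <- usages
  manifest$concepts <- concept_ids
  manifest$statements <- statements
  manifest$ground_truth <- ground_truth
  manifest$violations <- if (length(viol)) do.call(rbind, viol) else
    data.frame(kind = character(), rule = character(), focus = character(),
               stringsAsFactors = FALSE)
  list(graph = g, manifest = manifest)
}

# strongly connected component (size > 1) containing `node`, over contains
scc_members_containing <- function(g, node) {
  ce <- rdf_match(g, p = "openbiodiv:contains")
  ig <- igraph::graph_from_data_frame(ce[, c("s", "o")], directed = TRUE)
  comp <- igraph::components(ig, mode = "strong")
  members <- names(comp$membership)[comp$membership == comp$membership[[node]]]
  members
}

#' Write a fixture to disk
#'
#' Serializes the graph as Turtle and the manifest as JSON.
#'
#' @param fx Result of [gen_fixture()].
#' @param dir Output directory (created if missing).
#' @return Invisibly, the two file paths.
#' @export
write_fixture <- function(fx, dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  ttl <- file.path(dir, "fixture.ttl")
  man <- file.path(dir, "manifest.json")
  rdf_serialize(fx$graph, ttl, format = "turtle")
  jsonlite::write_json(fx$manifest, man, auto_unbox = TRUE, pretty = TRUE,
                       dataframe = "rows", null = "null")
  invisible(c(ttl, man))
}
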
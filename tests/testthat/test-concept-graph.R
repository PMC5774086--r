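test_that("concepts require at least one label and labels are unique identifiers", {
  g <- rdf_graph()
  c1 <- "http://x.org/c1"
  add_concept(g, c1, labels = list("Casuarinicola australis Taylor, 2010 sec. Thorpe"))
  types <- rdf_objects(g, s = c1, p = "rdf:type")
  expect_true(all(c("http://openbiodiv.net/TaxonomicConcept",
                    "http://www.w3.org/2004/02/skos/core#Concept",
                    "http://purl.org/vocab/frbr/core#Work",
                    "http://rs.tdwg.org/dwc/terms/Taxon") %in% types))
  # a second concept reusing the label is rejected
  expect_error(
    add_concept(g, "http://x.org/c2",
                labels = list("Casuarinicola australis Taylor, 2010 sec. Thorpe")),
    class = "taxograph_label_uniqueness_error")
  # zero labels violate the minimum cardinality
  expect_error(add_concept(g, "http://x.org/c3", labels = list()),
               class = "taxograph_cardinality_error")
  # one concept may carry several distinct labels (one-to-many)
  add_concept(g, "http://x.org/c4",
              labels = list("Aus bus L. 1758 sec. Smith (1900)",
                            "Aus bus L. 1758 sec. Jones (1950)"),
              seed = 4)
  expect_length(rdf_objects(g, s = "http://x.org/c4",
                            p = "openbiodiv:taxonomicConceptLabel"), 2L)
})

test_that("name relations honour direction, symmetry and irreflexivity", {
  ng <- make_name_graph(3)
  g <- ng$g; ids <- ng$ids
  assert_name_relation(g, ids[1], ids[2], "relatedName")
  # related-name is asserted in both directions
  expect_equal(rdf_objects(g, s = ids[1], p = "openbiodiv:relatedName"), ids[2])
  expect_equal(rdf_objects(g, s = ids[2], p = "openbiodiv:relatedName"), ids[1])
  assert_name_relation(g, ids[2], ids[3], "replacementName")
  expect_equal(nrow(rdf_match(g, p = "openbiodiv:replacementName")), 1L)
  expect_error(assert_name_relation(g, ids[1], ids[1], "replacementName"), "itself")
  expect_error(assert_name_relation(g, ids[1], "http://x.org/ghost", "relatedName"),
               "not in graph")
})

test_that("replacement chains resolve to terminals and flag cycles", {
  ng <- make_name_graph(4)
  g <- ng$g; ids <- ng$ids
  assert_name_relation(g, ids[1], ids[2], "replacementName")
  assert_name_relation(g, ids[2], ids[3], "replacementName")
  res <- resolve_current_names(g, ids[1])
  expect_equal(res$terminals, ids[3])
  expect_false(res$cycle)
  expect_equal(res$paths[[1]], c(ids[1], ids[2], ids[3]))
  # isolated name resolves to itself
  iso <- resolve_current_names(g, ids[4])
  expect_equal(iso$terminals, ids[4])
  # terminals are fixpoints
  expect_equal(resolve_current_names(g, ids[3])$terminals, ids[3])
  # injected 2-cycle: flagged, members reported, not silently broken
  assert_name_relation(g, ids[3], ids[4], "replacementName")
  assert_name_relation(g, ids[4], ids[3], "replacementName")
  cyc <- resolve_current_names(g, ids[1])
  expect_true(cyc$cycle)
  expect_setequal(cyc$cycle_members, ids[3:4])
  expect_error(resolve_current_names(g, "http://x.org/ghost"), "unknown name")
})

test_that("chain resolution equals the reachability oracle on random DAGs", {
  set.seed(51)
  for (rep in 1:25) {
    n <- sample(4:12, 1)
    ng <- make_name_graph(n)
    g <- ng$g; ids <- ng$ids
    from <- character(0); to <- character(0)
    for (i in seq_len(n - 1)) for (j in (i + 1):n) {
      if (runif(1) < 0.25) {
        assert_name_relation(g, ids[i], ids[j], "replacementName")
        from <- c(from, ids[i]); to <- c(to, ids[j])
      }
    }
    start <- ids[sample(n, 1)]
    res <- resolve_current_names(g, start)
    expect_equal(res$terminals, oracle_terminals(from, to, start))
    expect_false(res$cycle)
    # idempotence: every terminal resolves to itself
    for (t in res$terminals) {
      expect_equal(resolve_current_names(g, t)$terminals, t)
    }
  }
})

test_that("related-name neighborhoods grow with depth and match the component oracle", {
  ng <- make_name_graph(2)
  g <- ng$g; ids <- ng$ids
  assert_name_relation(g, ids[1], ids[2], "relatedName")
  expect_equal(related_name_neighborhood(g, ids[1], 1), ids[2])
  expect_equal(related_name_neighborhood(g, ids[2], 1), ids[1])
  expect_error(related_name_neighborhood(g, ids[1], 0), "depth")

  set.seed(61)
  for (rep in 1:10) {
    n <- sample(5:12, 1)
    ng <- make_name_graph(n)
    g <- ng$g; ids <- ng$ids
    a <- character(0); b <- character(0)
    for (i in seq_len(n - 1)) for (j in (i + 1):n) {
      if (runif(1) < 0.3) {
        kind <- sample(c("relatedName", "replacementName"), 1)
        assert_name_relation(g, ids[i], ids[j], kind)
        a <- c(a, ids[i]); b <- c(b, ids[j])
      }
    }
    start <- ids[sample(n, 1)]
    # large depth reaches the whole connected component minus the start
    deep <- related_name_neighborhood(g, start, n + 1)
    expect_equal(deep, oracle_neighborhood(a, b, start, n + 1))
    # depth-1 symmetry
    for (other in related_name_neighborhood(g, start, 1)) {
      expect_true(start %in% related_name_neighborhood(g, other, 1))
    }
  }
  # isolated name has an empty neighborhood
  ng <- make_name_graph(1)
  expect_length(related_name_neighborhood(ng$g, ng$ids[1], 3), 0L)
})

test_that("SKOS hierarchies are multi-parent and non-destructive", {
  cg <- make_concept_graph(3)
  g <- cg$g; ids <- cg$ids
  assert_skos_relation(g, ids[1], ids[2])
  expect_equal(rdf_objects(g, s = ids[1], p = "skos:broader"), ids[2])
  expect_equal(rdf_objects(g, s = ids[2], p = "skos:narrower"), ids[1])
  snapshot <- canonical_graph_lines(g)
  # a second hierarchy placing the same child under a different parent
  assert_skos_relation(g, ids[1], ids[3])
  expect_setequal(rdf_objects(g, s = ids[1], p = "skos:broader"), ids[2:3])
  # nothing from the first hierarchy was deleted or altered
  expect_true(all(snapshot %in% canonical_graph_lines(g)))
  expect_error(assert_skos_relation(g, ids[1], ids[1]), "itself")
  expect_error(assert_skos_relation(g, ids[1], "http://x.org/ghost"),
               "not a taxonomic concept")
})

test_that("RCC-5 statements are reified with one link per relation member", {
  cg <- make_concept_graph(2)
  g <- cg$g; ids <- cg$ids
  st <- assert_rcc5(g, ids[1], ids[2], "PP", source = "Thorpe 2013",
                    statement_id = "http://x.org/st1")
  expect_equal(rdf_objects(g, s = st, p = "openbiodiv:rcc5Subject"), ids[1])
  expect_equal(rdf_objects(g, s = st, p = "openbiodiv:rcc5Object"), ids[2])
  expect_length(rdf_objects(g, s = st, p = "openbiodiv:rcc5Relation"), 1L)
  expect_equal(rdf_match(g, s = st, p = "dcterms:source")$o, "Thorpe 2013")
  # an uncertainty disjunction carries one link per member
  st2 <- assert_rcc5(g, ids[1], ids[2], c("PP", "EQ"), statement_id = "http://x.org/st2")
  expect_length(rdf_objects(g, s = st2, p = "openbiodiv:rcc5Relation"), 2L)
  expect_error(assert_rcc5(g, ids[1], ids[2], character(0)), "non-empty")
  expect_error(assert_rcc5(g, ids[1], ids[2], "XX"), "unknown RCC-5 relation")
  expect_error(assert_rcc5(g, ids[1], ids[1], "EQ"), "distinct")
})

test_that("treatments realize concepts with type checking", {
  fx <- gen_fixture(fixture_spec(seed = 13, n_articles = 1, n_names = 3, n_concepts = 2))
  g <- fx$graph
  tr <- fx$manifest$treatments[1]
  c1 <- fx$manifest$concepts[1]
  realize_treatment(g, tr, c1)  # already realized; idempotent re-assertion
  expect_true(tr %in% rdf_objects(g, s = c1, p = "frbr:realization"))
  # two treatments may realize one concept (revisions)
  tr2 <- fx$manifest$treatments[2]
  realize_treatment(g, tr2, c1)
  expect_length(intersect(rdf_objects(g, s = c1, p = "frbr:realization"),
                          fx$manifest$treatments), 2L)
  nomen <- rdf_objects(g, s = tr, p = "openbiodiv:contains")[1]
  expect_error(realize_treatment(g, nomen, c1), "not a Treatment")
  expect_error(realize_treatment(g, tr, "http://x.org/ghost"), "not a taxonomic concept")
})

test_that("habitat attachment is a validated, idempotent pass-through", {
  cg <- make_concept_graph(1)
  g <- cg$g; c1 <- cg$ids[1]
  envo <- "http://purl.obolibrary.org/obo/ENVO_01000174"
  attach_habitat(g, c1, envo)
  attach_habitat(g, c1, envo)  # idempotent
  expect_equal(nrow(rdf_match(g, p = "openbiodiv:hasHabitat")), 1L)
  expect_equal(rdf_objects(g, s = c1, p = "openbiodiv:hasHabitat"), envo)
  expect_error(attach_habitat(g, c1, "not an iri"), "valid absolute IRI")
  expect_error(attach_habitat(g, "http://x.org/ghost", envo), "not a taxonomic concept")
})
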
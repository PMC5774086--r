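test_that("composition has EQ as identity and strict-subset transitivity", {
  for (r in rcc5_relations()) {
    expect_equal(rcc5_compose("EQ", r), r)
    expect_equal(rcc5_compose(r, "EQ"), r)
  }
  expect_equal(rcc5_compose("PP", "PP"), "PP")
  expect_equal(rcc5_compose("PP", "DR"), "DR")
})

test_that("the full composition table equals the finite-model oracle", {
  for (r1 in rcc5_relations()) for (r2 in rcc5_relations()) {
    expect_equal(sort(rcc5_compose(r1, r2)), oracle_compose(r1, r2),
                 info = paste(r1, "o", r2))
  }
})

test_that("composition satisfies the converse-symmetry identity", {
  for (r1 in rcc5_relations()) for (r2 in rcc5_relations()) {
    lhs <- sort(rcc5_compose(r1, r2))
    rhs <- sort(rcc5_converse(rcc5_compose(rcc5_converse(r2), rcc5_converse(r1))))
    expect_equal(lhs, rhs, info = paste(r1, r2))
  }
})

test_that("networks maintain converse closure and a fixed diagonal", {
  net <- rcc5_network(c("A", "B"))
  expect_equal(rcc5_edge(net, "A", "A"), "EQ")
  expect_setequal(rcc5_edge(net, "A", "B"), rcc5_relations())  # no information
  net <- rcc5_set_edge(net, "A", "B", c("PP", "PO"))
  expect_setequal(rcc5_edge(net, "B", "A"), c("PPi", "PO"))
  expect_error(rcc5_set_edge(net, "A", "A", "PP"), "diagonal")
  expect_error(rcc5_network(c("A", "A")), "duplicate")
})

test_that("path consistency refines chains and detects antisymmetry violations", {
  net <- rcc5_network(c("A", "B", "C"))
  net <- rcc5_set_edge(net, "A", "B", "PP")
  net <- rcc5_set_edge(net, "B", "C", "PP")
  pc <- path_consistency(net)
  expect_true(pc$consistent)
  expect_equal(rcc5_edge(pc$network, "A", "C"), "PP")
  # refinement is monotone: no label grew
  expect_true(all(bitwAnd(pc$network$m, net$m) == pc$network$m))
  # mutual proper parthood is contradictory
  bad <- rcc5_network(c("A", "B"))
  bad <- rcc5_set_edge(bad, "A", "B", "PP")
  bad <- rcc5_set_edge(bad, "B", "A", "PP")
  res <- path_consistency(bad)
  expect_false(res$consistent)
  expect_equal(nrow(res$empty_edges), 1L)
})

test_that("path consistency is idempotent (a fixpoint)", {
  set.seed(71)
  for (rep in 1:20) {
    net <- random_rcc5_network(paste0("n", 1:4))
    once <- path_consistency(net)
    twice <- path_consistency(once$network)
    expect_identical(once$network$m, twice$network$m)
    expect_equal(once$consistent, twice$consistent)
  }
})

test_that("the exhaustive oracle enforces its search bounds and base facts", {
  expect_true(model_check_oracle({
    n <- rcc5_network(c("A", "B")); rcc5_set_edge(n, "A", "B", "EQ")
  }, 3))
  # a proper part overlaps its whole, so PP plus DR is unsatisfiable
  expect_false(model_check_oracle({
    n <- rcc5_network(c("A", "B"))
    n <- rcc5_set_edge(n, "A", "B", "PP")
    rcc5_set_edge(n, "B", "A", "DR")
  }, 4))
  expect_error(model_check_oracle(rcc5_network(paste0("n", 1:7)), 3), "at most 6 nodes")
  expect_error(model_check_oracle(rcc5_network("A"), 7), "universe size")
})

test_that("path consistency and the oracle agree on all singleton 3-node networks", {
  R <- rcc5_relations()
  for (r1 in R) for (r2 in R) for (r3 in R) {
    net <- rcc5_network(c("A", "B", "C"))
    net <- rcc5_set_edge(net, "A", "B", r1)
    net <- rcc5_set_edge(net, "B", "C", r2)
    net <- rcc5_set_edge(net, "A", "C", r3)
    expect_equal(path_consistency(net)$consistent,
                 model_check_oracle(net, 4),
                 info = paste(r1, r2, r3))
  }
})

test_that("path consistency never refutes a network the oracle satisfies", {
  set.seed(81)
  for (rep in 1:60) {
    net <- random_rcc5_network(paste0("n", 1:5))
    if (!path_consistency(net)$consistent) {
      expect_false(model_check_oracle(net, 4))
    }
  }
})

test_that("graph-level checking extracts statements, reports culprits and warns", {
  # the worked pair: species concept a proper part of the genus concept
  cg <- make_concept_graph(2)
  g <- cg$g; ids <- cg$ids
  assert_rcc5(g, ids[1], ids[2], "PP", statement_id = "http://x.org/st1")
  rep1 <- check_graph(g)
  expect_equal(rep1$verdict, "consistent")
  expect_equal(nrow(rep1$edges), 1L)
  expect_equal(rep1$edges$relations, "PP")
  # contradictory statements on the same pair cite both statement IRIs
  assert_rcc5(g, ids[1], ids[2], "DR", statement_id = "http://x.org/st2")
  rep2 <- check_graph(g)
  expect_equal(rep2$verdict, "inconsistent")
  expect_setequal(rep2$culprits, c("http://x.org/st1", "http://x.org/st2"))
  # malformed statements are warned about and excluded
  rdf_add(g, "http://x.org/st3", "rdf:type", "openbiodiv:RCC5Statement")
  rdf_add(g, "http://x.org/st3", "openbiodiv:rcc5Subject", ids[1])
  rep3 <- check_graph(g)
  expect_length(rep3$warnings, 1L)
  expect_match(rep3$warnings, "st3")
  # no statements -> empty report
  empty <- check_graph(make_concept_graph(1)$g)
  expect_equal(empty$verdict, "empty")
  expect_equal(nrow(empty$edges), 0L)
})

test_that("SKOS links can optionally seed the network as proper-parthood", {
  cg <- make_concept_graph(3)
  g <- cg$g; ids <- cg$ids
  assert_skos_relation(g, ids[1], ids[2])
  # without the flag SKOS is ignored
  expect_equal(check_graph(g)$verdict, "empty")
  rep <- check_graph(g, import_skos = TRUE)
  expect_equal(rep$verdict, "consistent")
  expect_equal(rep$edges$relations, "PP")
  # a contradicting statement is then caught
  assert_rcc5(g, ids[1], ids[2], "DR", statement_id = "http://x.org/st1")
  expect_equal(check_graph(g, import_skos = TRUE)$verdict, "inconsistent")
})
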
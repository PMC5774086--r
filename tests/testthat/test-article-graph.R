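simple_article <- function() {
  root <- document_component("TaxonomicArticle", id = "http://x.org/art", children = list(
    document_component("Treatment", id = "http://x.org/tr", children = list(
      document_component("NomenclatureSection", id = "http://x.org/nom")))))
  meta <- article_metadata("A treatment of Heser", c("Author A"),
                           doi = "10.1/x", journal = "TestJ",
                           work_id = "http://x.org/work")
  build_article_graph(meta, root, seed = 9)
}

test_that("article graphs carry FRBR metadata and one contains triple per edge", {
  g <- simple_article()
  expect_equal(attr(g, "expression_id"), "http://x.org/art")
  # work realized by the article expression, distinct nodes
  expect_equal(rdf_objects(g, s = "http://x.org/work", p = "frbr:realization"),
               "http://x.org/art")
  expect_true("http://purl.org/vocab/frbr/core#Work" %in%
                rdf_objects(g, s = "http://x.org/work", p = "rdf:type"))
  # 3 components -> 2 asserted containment edges
  expect_equal(nrow(rdf_match(g, p = "openbiodiv:contains")), 2L)
  expect_true("http://openbiodiv.net/Treatment" %in%
                rdf_objects(g, s = "http://x.org/tr", p = "rdf:type"))
})

test_that("component trees are validated structurally", {
  # a node reused across branches manifests as a duplicated id
  shared <- document_component("Treatment", id = "http://x.org/dup")
  root <- document_component("TaxonomicArticle", id = "http://x.org/art",
                             children = list(shared, shared))
  meta <- article_metadata("t", work_id = "http://x.org/w")
  expect_error(build_article_graph(meta, root), "not a tree")
  expect_error(document_component("NotAKind"), "arg")
  expect_error(article_metadata(""), "non-empty")
  expect_error(article_metadata("t", work_id = "http://x.org/same",
                                expression_id = "http://x.org/same"), "distinct")
  root2 <- document_component("Treatment", id = "http://x.org/t")
  expect_error(build_article_graph(meta, root2), "TaxonomicArticle")
})

test_that("article with N components asserts exactly N-1 containment triples", {
  set.seed(31)
  for (rep in 1:5) {
    n <- sample(2:12, 1)
    edges <- random_tree_edges(n, paste0("http://x.org/c", 1:n))
    build <- function(v) {
      kids <- edges$child[edges$parent == v]
      kind <- if (v == "http://x.org/c1") "TaxonomicArticle" else "GenericDiscourseElement"
      document_component(kind, id = v, children = lapply(kids, build))
    }
    g <- build_article_graph(article_metadata("t", work_id = "http://x.org/w"),
                             build("http://x.org/c1"), seed = rep)
    expect_equal(nrow(rdf_match(g, p = "openbiodiv:contains")), n - 1L)
  }
})

test_that("name usages are mentions contained in their section", {
  g <- simple_article()
  u <- parse_taxonomic_name_usage("Heser stoevi Deltschev 2016, sp. n.")
  uid <- add_name_usage(g, u, "http://x.org/tr", "http://x.org/name1",
                        usage_id = "http://x.org/tnu1")
  expect_equal(uid, "http://x.org/tnu1")
  expect_true(uid %in% rdf_objects(g, s = "http://x.org/tr", p = "openbiodiv:contains"))
  expect_equal(rdf_objects(g, s = uid, p = "openbiodiv:mentions"), "http://x.org/name1")
  expect_equal(rdf_objects(g, s = uid, p = "openbiodiv:taxonomicStatus"),
               "http://openbiodiv.net/TaxonDiscovery")
  # usage without status carries no status triple
  u2 <- parse_taxonomic_name_usage("Heser stoevi Deltschev 2016")
  uid2 <- add_name_usage(g, u2, "http://x.org/nom", "http://x.org/name1",
                         usage_id = "http://x.org/tnu2")
  expect_equal(nrow(rdf_match(g, s = uid2, p = "openbiodiv:taxonomicStatus")), 0L)
  # two usages of one name share a single name node
  expect_length(rdf_subjects(g, p = "rdf:type", o = "openbiodiv:ScientificName"), 1L)
  expect_length(rdf_subjects(g, p = "openbiodiv:mentions", o = "http://x.org/name1"), 2L)
  # unknown container refused
  expect_error(add_name_usage(g, u, "http://x.org/nowhere", "http://x.org/n"),
               "unknown container")
})

test_that("containment closure equals the recursive-DFS oracle on random trees", {
  set.seed(41)
  for (rep in 1:25) {
    n <- sample(2:15, 1)
    labels <- paste0("http://x.org/t", rep, "n", 1:n)
    edges <- random_tree_edges(n, labels)
    g <- rdf_graph()
    rdf_add(g, edges$parent, "openbiodiv:contains", edges$child)
    got <- contains_closure(g)
    want <- oracle_closure(edges$parent, edges$child)
    expect_equal(got$ancestor, want$ancestor)
    expect_equal(got$descendant, want$descendant)
    # closure dominates the asserted edges and is idempotent
    expect_gte(nrow(got), nrow(edges))
    g2 <- rdf_graph()
    rdf_add(g2, got$ancestor, "openbiodiv:contains", got$descendant)
    expect_equal(nrow(contains_closure(g2)), nrow(got))
  }
})

test_that("closure of a childless node is empty and chains close transitively", {
  g <- rdf_graph()
  rdf_add(g, "http://x.org/solo", "rdf:type", "openbiodiv:TaxonomicArticle")
  expect_equal(nrow(contains_closure(g)), 0L)
  g2 <- simple_article()
  cc <- contains_closure(g2)
  expect_true(any(cc$ancestor == "http://x.org/art" & cc$descendant == "http://x.org/nom"))
  # opt-in materialization asserts the inferred pairs
  before <- nrow(rdf_match(g2, p = "openbiodiv:contains"))
  contains_closure(g2, materialize = TRUE)
  expect_equal(nrow(rdf_match(g2, p = "openbiodiv:contains")), nrow(cc))
  expect_gte(nrow(cc), before)
})

test_that("article graphs round-trip through both serializations", {
  g <- simple_article()
  add_name_usage(g, parse_taxonomic_name_usage("Aus bus Smith 1900, syn. n."),
                 "http://x.org/nom", "http://x.org/name2",
                 usage_id = "http://x.org/tnu3")
  expect_true(rdf_isomorphic(g, rdf_roundtrip(g, "turtle")))
  expect_true(rdf_isomorphic(g, rdf_roundtrip(g, "rdfxml")))
})

test_that("YAML article descriptions build the same structure", {
  yml <- withr::local_tempfile(fileext = ".yaml")
  writeLines(c(
    "title: A treatment of Heser",
    "authors: [Author A]",
    "journal: TestJ",
    "work_id: http://x.org/work",
    "components:",
    "  kind: TaxonomicArticle",
    "  id: http://x.org/art",
    "  children:",
    "    - kind: Treatment",
    "      id: http://x.org/tr",
    "      children:",
    "        - kind: NomenclatureSection",
    "          id: http://x.org/nom",
    "usages:",
    "  - text: 'Heser stoevi Deltschev 2016, sp. n.'",
    "    container: http://x.org/nom",
    "    name_id: http://x.org/name1",
    "    id: http://x.org/tnu1"
  ), yml)
  g <- build_article_from_yaml(yml, seed = 2)
  expect_equal(nrow(rdf_match(g, p = "openbiodiv:contains")), 3L)  # 2 tree + usage
  expect_equal(rdf_objects(g, s = "http://x.org/tnu1", p = "openbiodiv:mentions"),
               "http://x.org/name1")
  expect_true(validate_graph(g)$passed)
})
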
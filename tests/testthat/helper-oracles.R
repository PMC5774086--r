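# Brute-force oracles, deliberately independent of the package's own
# algorithms: plain recursion and exhaustive enumeration only.

# transitive closure of a parent->child edge list by recursive DFS
oracle_closure <- function(parents, children) {
  adj <- split(children, parents)
  pairs <- list()
  descend <- function(anc, v) {
    for (ch in adj[[v]]) {
      pairs[[length(pairs) + 1L]] <<- c(anc, ch)
      descend(anc, ch)
    }
  }
  for (a in unique(c(parents, children))) descend(a, a)
  if (!length(pairs)) {
    return(data.frame(ancestor = character(), descendant = character(),
                      stringsAsFactors = FALSE))
  }
  m <- unique(do.call(rbind, pairs))
  out <- data.frame(ancestor = m[, 1], descendant = m[, 2], stringsAsFactors = FALSE)
  out[order(out$ancestor, out$descendant), ]
}

# all nodes reachable from start (excluding unreachable), by naive expansion
oracle_reachable <- function(from, to, start) {
  reach <- start
  repeat {
    nxt <- unique(c(reach, to[from %in% reach]))
    if (length(nxt) == length(reach)) return(reach)
    reach <- nxt
  }
}

# terminals of replacement chains: reachable nodes with no outgoing edge
oracle_terminals <- function(from, to, start) {
  reach <- oracle_reachable(from, to, start)
  sort(reach[!reach %in% from])
}

# undirected k-hop neighborhood by naive frontier expansion
oracle_neighborhood <- function(a, b, start, depth) {
  ends <- unique(rbind(cbind(a, b), cbind(b, a)))
  seen <- start
  frontier <- start
  for (d in seq_len(depth)) {
    frontier <- setdiff(unique(ends[ends[, 1] %in% frontier, 2]), seen)
    if (!length(frontier)) break
    seen <- c(seen, frontier)
  }
  sort(setdiff(seen, start))
}

# base RCC-5 relation between two finite sets coded as bit masks
oracle_set_relation <- function(a, b) {
  if (a == b) return("EQ")
  i <- bitwAnd(a, b)
  if (i == a) return("PP")
  if (i == b) return("PPi")
  if (i == 0L) return("DR")
  "PO"
}

# composition of two base relations by enumerating subset triples over a
# 4-element universe (sufficient for RCC-5)
oracle_compose <- function(r1, r2) {
  subsets <- 1:15
  found <- character(0)
  for (a in subsets) for (b in subsets) {
    if (oracle_set_relation(a, b) != r1) next
    for (cc in subsets) {
      if (oracle_set_relation(b, cc) == r2) {
        found <- union(found, oracle_set_relation(a, cc))
      }
    }
  }
  sort(found)
}

# random rooted tree on n labelled nodes: node i's parent drawn from 1..i-1
random_tree_edges <- function(n, labels = paste0("n", seq_len(n))) {
  if (n < 2L) {
    return(data.frame(parent = character(), child = character(),
                      stringsAsFactors = FALSE))
  }
  parent <- vapply(2:n, function(i) sample.int(i - 1L, 1L), integer(1))
  data.frame(parent = labels[parent], child = labels[2:n], stringsAsFactors = FALSE)
}

# a graph pre-populated with n typed name nodes; returns list(g, ids)
make_name_graph <- function(n) {
  g <- rdf_graph()
  ids <- paste0("http://example.org/name", seq_len(n))
  for (i in seq_len(n)) {
    add_scientific_name(g, parse_scientific_name(paste0("Aus name", letters[1 + (i - 1) %% 26], " Smith ", 1899 + i)), ids[i])
  }
  list(g = g, ids = ids)
}

# a graph with n concepts carrying unique labels; returns list(g, ids)
make_concept_graph <- function(n) {
  g <- rdf_graph()
  ids <- paste0("http://example.org/concept", seq_len(n))
  for (i in seq_len(n)) {
    add_concept(g, ids[i],
                labels = list(paste0("Aus bus L. ", 1800 + i, " sec. Ref (", 1900 + i, ")")),
                seed = i)
  }
  list(g = g, ids = ids)
}

# flat canonical view of a graph's triples for set comparisons
canonical_graph_lines <- function(g) {
  tr <- rdf_triples(g)
  sort(paste(tr$s, tr$p, tr$o, tr$o_type, tr$o_dt, tr$o_lang, sep = "\r"))
}

# random RCC-5 network on `nodes` with singleton/doubleton labels
random_rcc5_network <- function(nodes, p_edge = 0.6) {
  net <- rcc5_network(nodes)
  n <- length(nodes)
  for (i in seq_len(n - 1L)) for (j in (i + 1L):n) {
    if (stats::runif(1) < p_edge) {
      rels <- sample(rcc5_relations(), sample(1:2, 1))
      net <- rcc5_set_edge(net, nodes[i], nodes[j], rels)
    }
  }
  net
}
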
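# Per-miRNA network construction, centralities and key-gene extraction.

test_that("expression filter intersects target sets with expressed genes", {
  cat <- target_catalog(list(`miR-A` = c("G1", "G2")))
  prof <- expression_profile("heart muscle", c(G1 = 5, G2 = 0))
  expect_equal(unclass(filter_expressed_targets(cat, prof)),
               list(`miR-A` = "G1"))
  # min_level = 0 keeps every gene present in the profile
  prof2 <- expression_profile("heart muscle", c(G1 = 5, G2 = 0))
  expect_equal(filter_expressed_targets(cat, prof2, min_level = 0), cat)
  # genes missing from the profile count as not expressed
  cat2 <- target_catalog(list(`miR-A` = c("G1", "G9")))
  expect_equal(unclass(filter_expressed_targets(cat2, prof)),
               list(`miR-A` = "G1"))
})

test_that("expression filter retains about the expressed fraction on synthetic data", {
  cfg <- synth_config(n_mirnas = 12, n_query = 6, n_genes = 800,
                      n_pathways = 10, seed = 31)
  d <- generate_dataset(cfg)
  filtered <- filter_expressed_targets(d$catalog, d$profile)
  frac <- unlist(lengths(filtered)) / unlist(lengths(d$catalog))
  expect_lt(abs(mean(frac) - 0.55), 0.05)
})

test_that("target network is the vertex-induced subgraph plus isolated targets", {
  ppi <- graph_from_edges(data.frame(from = c("G1", "G2"),
                                     to = c("G2", "G4")))
  g <- build_target_network(c("G1", "G2", "G3"), ppi)
  expect_setequal(igraph::V(g)$name, c("G1", "G2", "G3"))
  expect_equal(igraph::ecount(g), 1L)
  expect_equal(igraph::degree(g)[["G3"]], 0)

  empty <- build_target_network(character(0), ppi)
  expect_equal(igraph::vcount(empty), 0L)
})

test_that("induced subgraph matches brute-force pairwise membership", {
  set.seed(101)
  for (rep in 1:30) {
    edges <- random_connected_edges(sample(5:12, 1))
    ppi <- graph_from_edges(edges)
    targets <- sample(igraph::V(ppi)$name,
                      sample.int(igraph::vcount(ppi), 1))
    g <- build_target_network(targets, ppi)
    expected <- edges[edges$from %in% targets & edges$to %in% targets, ,
                      drop = FALSE]
    got <- igraph::as_edgelist(g)
    got_keys <- sort(paste(pmin(got[, 1], got[, 2]),
                           pmax(got[, 1], got[, 2])))
    expect_equal(got_keys, sort(paste(expected$from, expected$to)))
  }
})

test_that("largest component selection is maximal and tie-broken deterministically", {
  g <- graph_from_edges(data.frame(from = c("A", "B", "D"),
                                   to = c("B", "C", "E")))
  lcc <- largest_connected_component(g)
  expect_setequal(igraph::V(lcc)$name, c("A", "B", "C"))

  tie <- graph_from_edges(data.frame(from = c("C", "A"), to = c("D", "B")))
  lcc2 <- largest_connected_component(tie)
  expect_setequal(igraph::V(lcc2)$name, c("A", "B"))

  expect_warning(largest_connected_component(igraph::make_empty_graph()),
                 "empty")
})

test_that("largest component size equals exhaustive component enumeration", {
  set.seed(77)
  for (rep in 1:20) {
    n <- sample(4:12, 1)
    edges <- random_connected_edges(n, extra = 2)
    # delete some edges to fragment the graph
    edges <- edges[runif(nrow(edges)) > 0.4, , drop = FALSE]
    if (!nrow(edges)) next
    nodes <- sort(unique(c(edges$from, edges$to)))
    comps <- bf_components(adj_matrix(edges, nodes))
    g <- graph_from_edges(edges)
    lcc <- suppressWarnings(largest_connected_component(g))
    expect_equal(igraph::vcount(lcc), max(lengths(comps)))
  }
})

test_that("centralities match closed forms on path and star", {
  path3 <- graph_from_edges(data.frame(from = c("A", "B"), to = c("B", "C")))
  ct <- compute_centralities(path3)
  rownames(ct) <- ct$gene
  expect_equal(ct["B", c("degree", "betweenness", "combined")],
               data.frame(row.names = "B", degree = 1, betweenness = 1,
                          combined = 2))
  expect_equal(ct["A", "combined"], 0.5)

  star4 <- star_graph(4)
  cs <- compute_centralities(star4)
  rownames(cs) <- cs$gene
  expect_equal(cs["CEN", "combined"], 2)
  expect_equal(cs["L01", "combined"], 0.25)

  expect_error(compute_centralities(igraph::make_graph(character(0))),
               ">= 2 nodes")
})

test_that("betweenness equals exhaustive shortest-path counting on random graphs", {
  set.seed(12)
  for (rep in 1:50) {
    n <- sample(4:25, 1)
    edges <- random_connected_edges(n)
    g <- graph_from_edges(edges)
    ct <- compute_centralities(g)
    oracle <- bf_betweenness(adj_matrix(edges, sort(igraph::V(g)$name)))
    expect_equal(setNames(ct$betweenness, ct$gene), oracle[ct$gene],
                 tolerance = 1e-10)
    deg_oracle <- rowSums(adj_matrix(edges, ct$gene)) / (n - 1)
    expect_equal(setNames(ct$degree, ct$gene), deg_oracle[ct$gene])
  }
})

test_that("plateau detection finds the knee and degenerates to 1", {
  # chord from (0,10) to (5,2): distances 10-1.6k - S(k) peak at k = 2
  expect_equal(detect_plateau(c(10, 9, 3, 2, 2, 2)), 2L)
  expect_equal(detect_plateau(c(5, 5, 5)), 1L)
  expect_equal(detect_plateau(c(6, 5, 4, 3)), 1L)
  expect_error(detect_plateau(7), "at least 2")
})

test_that("key genes of a star are its center", {
  res <- extract_key_genes(star_graph(5))
  expect_equal(res$key_genes, "CEN")
  expect_equal(res$curve, c(6, 1, 1, 1, 1, 1, 0))
  expect_equal(res$plateau, 1L)
})

test_that("key gene of a barbell is the bridge node", {
  # two K4 cliques joined through one bridge node wired to all clique
  # members; the bridge has combined 1 + 32/56, clique members 0.5
  g <- barbell_graph(4)
  ct <- compute_centralities(g)
  rownames(ct) <- ct$gene
  expect_equal(ct["BRIDGE", "combined"], 1 + 32 / 56)
  expect_equal(ct["A1", "combined"], 0.5)
  res <- extract_key_genes(g)
  expect_equal(res$key_genes, "BRIDGE")
  expect_equal(res$curve[1:2], c(9, 4))
  # ties among clique members resolve lexicographically
  expect_equal(res$removal_order[2:5], c("A1", "A2", "A3", "A4"))
})

test_that("extraction is deterministic and the decay curve is honest", {
  set.seed(5150)
  for (rep in 1:10) {
    edges <- random_connected_edges(sample(8:20, 1))
    g <- graph_from_edges(edges)
    r1 <- extract_key_genes(g)
    r2 <- extract_key_genes(g)
    expect_identical(r1, r2)
    # monotone non-increasing decay
    expect_true(all(diff(r1$curve) <= 0))
    # removal order is a permutation of the nodes
    expect_setequal(r1$removal_order, igraph::V(g)$name)
    # removing the key prefix leaves a largest component of exactly S(p*)
    survivor <- igraph::delete_vertices(g, r1$key_genes)
    s_after <- if (igraph::vcount(survivor) == 0) 0
               else max(igraph::components(survivor)$csize)
    expect_equal(s_after, r1$curve[r1$plateau + 1])
  }
})

test_that("window plateau strategy stops at the first constant run", {
  # S = 10 7 5 5 5 2 ...: first run of 3 equal values opens at k = 2
  curve <- c(10, 7, 5, 5, 5, 2)
  expect_equal(mirmod:::plateau_window(curve, 3L), 2L)
  # no run: falls back to the knee
  expect_equal(mirmod:::plateau_window(c(10, 9, 3, 2, 1, 0), 3L),
               detect_plateau(c(10, 9, 3, 2, 1, 0)))
})
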
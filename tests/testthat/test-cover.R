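# Bigraph construction and the greedy maximal-coverage module search.

test_that("bigraph edges mirror the significant-pathway map", {
  bg <- build_bigraph(list(m1 = "P1", m2 = c("P1", "P2")))
  expect_equal(nrow(bg$edges), 3L)
  expect_equal(sum(bg$edges$right == "P1"), 2L)
  expect_equal(bg$right_type, "pathway")

  disjoint <- build_bigraph(list(m1 = "P1", m2 = "P2", m3 = "P3"))
  expect_true(all(table(disjoint$edges$right) == 1L))

  expect_error(build_bigraph(list(m1 = character(0))), "fall back")
})

test_that("miRNA connectivity detection matches component enumeration", {
  expect_true(has_connected_mirnas(build_bigraph(list(m1 = "P1", m2 = "P1"))))
  expect_false(has_connected_mirnas(build_bigraph(list(m1 = "P1", m2 = "P2"))))

  set.seed(55)
  for (rep in 1:40) {
    n_m <- sample(2:5, 1); n_p <- sample(1:5, 1)
    mir <- paste0("m", seq_len(n_m)); pw <- paste0("P", seq_len(n_p))
    edges <- expand.grid(mirna = mir, right = pw,
                         stringsAsFactors = FALSE)
    edges <- edges[runif(nrow(edges)) < 0.35, , drop = FALSE]
    if (!nrow(edges)) next
    sig <- split(edges$right, edges$mirna)
    bg <- build_bigraph(sig)
    # oracle: hand-rolled BFS over the bipartite adjacency
    nodes <- c(unique(edges$mirna), unique(edges$right))
    adj <- adj_matrix(data.frame(from = edges$mirna, to = edges$right),
                      nodes)
    comps <- bf_components(adj)
    two_linked <- any(vapply(comps, function(cp)
      sum(cp %in% edges$mirna) >= 2, logical(1)))
    expect_equal(has_connected_mirnas(bg), two_linked)
  }
})

test_that("greedy search returns all tied pathways and then the remainder", {
  # three pathways tied on the same 8 of 12 miRNAs; everything else weak
  mir <- sprintf("m%02d", 1:12)
  shared <- mir[1:8]
  sig <- setNames(rep(list(character(0)), 12), mir)
  for (m in shared) sig[[m]] <- c("P1", "P2", "P3")
  sig[["m09"]] <- "P4"; sig[["m10"]] <- "P4"
  sig[["m11"]] <- "P5"; sig[["m12"]] <- "P5"
  bg <- build_bigraph(sig)
  mods <- greedy_extract_modules(bg, max_iterations = 2)
  expect_length(mods, 2L)
  expect_setequal(mods[[1]]$pathways, c("P1", "P2", "P3"))
  expect_setequal(mods[[1]]$mirnas, shared)
  expect_equal(mods[[1]]$coverage, 8L)
  # second iteration operates on the remaining 4 miRNAs
  expect_setequal(mods[[2]]$pathways, c("P4", "P5"))
  expect_setequal(mods[[2]]$mirnas, mir[9:12])
})

test_that("single-edge bigraph yields one module and stops", {
  bg <- build_bigraph(list(m1 = "P1", m2 = "P2"))
  # not connected: the greedy precondition fails with fallback advice
  expect_error(greedy_extract_modules(bg), "fallback|fall back")

  bg2 <- build_bigraph(list(m1 = "P1", m2 = "P1"))
  mods <- greedy_extract_modules(bg2, max_iterations = 5)
  expect_length(mods, 1L)
})

test_that("tied neighborhoods union into the module miRNA set", {
  # two pathways tied at coverage 2 with different neighborhoods
  sig <- list(m1 = "P1", m2 = c("P1", "P2"), m3 = "P2")
  mods <- greedy_extract_modules(build_bigraph(sig))
  expect_setequal(mods[[1]]$pathways, c("P1", "P2"))
  expect_setequal(mods[[1]]$mirnas, c("m1", "m2", "m3"))
  expect_equal(mods[[1]]$coverage, 2L)
})

test_that("iteration-1 coverage equals the brute-force maximum on random bigraphs", {
  set.seed(808)
  tested <- 0
  for (rep in 1:400) {
    n_m <- sample(2:5, 1); n_p <- sample(1:5, 1)
    grid <- expand.grid(mirna = paste0("m", 1:n_m),
                        right = paste0("P", 1:n_p),
                        stringsAsFactors = FALSE)
    edges <- grid[runif(nrow(grid)) < runif(1, 0.2, 0.8), , drop = FALSE]
    if (!nrow(edges)) next
    sig <- split(edges$right, edges$mirna)
    bg <- build_bigraph(sig)
    if (!has_connected_mirnas(bg)) next
    tested <- tested + 1
    mods <- greedy_extract_modules(bg, max_iterations = Inf)
    expect_equal(mods[[1]]$coverage, bf_max_coverage(edges))
    # modules are disjoint in both node sets
    if (length(mods) > 1) {
      for (i in seq_along(mods)[-1]) {
        expect_length(intersect(mods[[i]]$pathways, mods[[1]]$pathways), 0)
        expect_length(intersect(mods[[i]]$mirnas, mods[[1]]$mirnas), 0)
      }
      # greedy monotonicity of coverage across iterations
      cov <- vapply(mods, `[[`, integer(1), "coverage")
      expect_true(all(diff(cov) <= 0))
    }
  }
  expect_gt(tested, 100)
})

test_that("greedy module count respects the set-cover approximation bound", {
  set.seed(909)
  for (rep in 1:60) {
    n_m <- sample(3:5, 1); n_p <- sample(2:5, 1)
    grid <- expand.grid(mirna = paste0("m", 1:n_m),
                        right = paste0("P", 1:n_p),
                        stringsAsFactors = FALSE)
    edges <- grid[runif(nrow(grid)) < 0.5, , drop = FALSE]
    if (!nrow(edges)) next
    sig <- split(edges$right, edges$mirna)
    bg <- build_bigraph(sig)
    if (!has_connected_mirnas(bg)) next
    mods <- greedy_extract_modules(bg, max_iterations = Inf)
    n_selected <- length(unique(unlist(lapply(mods, `[[`, "pathways"))))
    bound <- bf_min_cover_size(edges) * (1 + log(length(unique(edges$mirna))))
    expect_lte(n_selected, bound + 1e-9)
  }
})

test_that("key-gene fallback bigraph exposes shared targets", {
  bg <- build_gene_bigraph(list(m1 = "G1", m2 = "G1"))
  expect_equal(bg$right_type, "gene")
  expect_equal(sum(bg$edges$right == "G1"), 2L)

  disjoint <- build_gene_bigraph(list(m1 = c("G1", "G2"), m2 = "G3"))
  expect_true(all(table(disjoint$edges$right) == 1L))

  # a gene targeted by six miRNAs has maximal degree and anchors the module
  keys <- c(list(hub = character(0)),
            setNames(lapply(1:6, function(i) c("MYCA", paste0("G", i))),
                     paste0("m", 1:6)))
  keys$hub <- NULL
  bg6 <- build_gene_bigraph(keys)
  degs <- table(bg6$edges$right)
  expect_equal(names(degs)[which.max(degs)], "MYCA")
  mods <- greedy_extract_modules(bg6, max_iterations = 1)
  expect_equal(mods[[1]]$pathways, "MYCA")
  expect_equal(mods[[1]]$coverage, 6L)
})
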
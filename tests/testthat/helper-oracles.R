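# Independent brute-force oracles. These deliberately avoid igraph and the
# package's own code paths: graphs are adjacency matrices, shortest paths
# are enumerated explicitly, probabilities are summed term by term.

# adjacency matrix from an edge data.frame (from, to) over given nodes
adj_matrix <- function(edges, nodes) {
  a <- matrix(0L, length(nodes), length(nodes),
              dimnames = list(nodes, nodes))
  for (i in seq_len(nrow(edges))) {
    a[edges$from[i], edges$to[i]] <- 1L
    a[edges$to[i], edges$from[i]] <- 1L
  }
  a
}

# connected components by hand-rolled BFS; returns list of node-name vectors
bf_components <- function(adj) {
  nodes <- rownames(adj)
  seen <- setNames(rep(FALSE, length(nodes)), nodes)
  comps <- list()
  for (start in nodes) {
    if (seen[start]) next
    queue <- start
    seen[start] <- TRUE
    comp <- character(0)
    while (length(queue)) {
      v <- queue[1L]; queue <- queue[-1L]
      comp <- c(comp, v)
      nb <- nodes[adj[v, ] == 1L & !seen]
      seen[nb] <- TRUE
      queue <- c(queue, nb)
    }
    comps[[length(comps) + 1L]] <- sort(comp)
  }
  comps
}

# all shortest paths between s and t as lists of node names (BFS distances,
# then exhaustive backtracking over predecessors)
bf_shortest_paths <- function(adj, s, t) {
  nodes <- rownames(adj)
  dist <- setNames(rep(Inf, length(nodes)), nodes)
  dist[s] <- 0
  queue <- s
  while (length(queue)) {
    v <- queue[1L]; queue <- queue[-1L]
    for (u in nodes[adj[v, ] == 1L]) {
      if (is.infinite(dist[u])) {
        dist[u] <- dist[v] + 1
        queue <- c(queue, u)
      }
    }
  }
  if (is.infinite(dist[t])) return(list())
  backtrack <- function(v) {
    if (v == s) return(list(s))
    preds <- nodes[adj[v, ] == 1L & dist == dist[v] - 1]
    out <- list()
    for (p in preds)
      for (path in backtrack(p))
        out[[length(out) + 1L]] <- c(path, v)
    out
  }
  backtrack(t)
}

# pair-normalized betweenness by explicit shortest-path enumeration
bf_betweenness <- function(adj) {
  nodes <- rownames(adj)
  n <- length(nodes)
  b <- setNames(numeric(n), nodes)
  if (n < 3) return(b)
  for (i in seq_len(n - 1L)) {
    for (j in seq.int(i + 1L, n)) {
      paths <- bf_shortest_paths(adj, nodes[i], nodes[j])
      if (!length(paths)) next
      for (p in paths) {
        interior <- p[-c(1L, length(p))]
        if (length(interior))
          b[interior] <- b[interior] + 1 / length(paths)
      }
    }
  }
  2 * b / ((n - 1) * (n - 2))
}

# upper-tail hypergeometric by direct summation of the mass function
bf_hyper_upper <- function(N, K, n, k) {
  if (k <= 0) return(1)
  i <- seq.int(k, min(n, K))
  sum(choose(K, i) * choose(N - K, n - i)) / choose(N, n)
}

# step-up Benjamini-Hochberg computed from the definition
bf_bh <- function(p) {
  m <- length(p)
  o <- order(p)
  q <- p[o] * m / seq_len(m)
  q <- rev(cummin(rev(q)))
  q <- pmin(q, 1)
  out <- numeric(m)
  out[o] <- q
  out
}

# maximum single-right-node coverage of a bipartite edge set, by counting
bf_max_coverage <- function(edges) {
  if (!nrow(edges)) return(0L)
  max(vapply(unique(edges$right),
             function(r) length(unique(edges$mirna[edges$right == r])),
             integer(1)))
}

# minimum number of right nodes covering every coverable miRNA (exhaustive)
bf_min_cover_size <- function(edges) {
  rights <- unique(edges$right)
  mirnas <- unique(edges$mirna)
  for (sz in seq_along(rights)) {
    combos <- utils::combn(rights, sz, simplify = FALSE)
    for (cmb in combos) {
      covered <- unique(edges$mirna[edges$right %in% cmb])
      if (length(covered) == length(mirnas)) return(sz)
    }
  }
  length(rights)
}

# random connected graph as an edge data.frame: random spanning tree plus
# extra random edges
random_connected_edges <- function(n, extra = n) {
  nodes <- sprintf("N%02d", seq_len(n))
  from <- character(0); to <- character(0)
  for (i in seq.int(2L, n)) {
    j <- sample.int(i - 1L, 1L)
    from <- c(from, nodes[j]); to <- c(to, nodes[i])
  }
  for (e in seq_len(extra)) {
    pair <- sample(nodes, 2L)
    from <- c(from, min(pair)); to <- c(to, max(pair))
  }
  edges <- unique(data.frame(from = pmin(from, to), to = pmax(from, to),
                             stringsAsFactors = FALSE))
  edges[edges$from != edges$to, , drop = FALSE]
}

# igraph object from an edge data.frame (test input construction only)
graph_from_edges <- function(edges, isolated = character(0)) {
  g <- igraph::graph_from_data_frame(edges, directed = FALSE)
  if (length(isolated)) g <- igraph::add_vertices(g, length(isolated),
                                                  name = isolated)
  g
}

# star: center C plus n leaves L01.., barbell: two k-cliques bridged by one
# node wired to every clique member
star_graph <- function(n_leaves) {
  leaves <- sprintf("L%02d", seq_len(n_leaves))
  graph_from_edges(data.frame(from = "CEN", to = leaves))
}

barbell_graph <- function(k = 4L) {
  a <- sprintf("A%d", seq_len(k)); b <- sprintf("B%d", seq_len(k))
  clique <- function(v) {
    p <- t(utils::combn(v, 2L))
    data.frame(from = p[, 1L], to = p[, 2L], stringsAsFactors = FALSE)
  }
  bridge <- data.frame(from = "BRIDGE", to = c(a, b))
  graph_from_edges(rbind(clique(a), clique(b), bridge))
}

write_tmp_tsv <- function(df, ...) {
  path <- withr::local_tempfile(fileext = ".tsv", .local_envir = parent.frame())
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  path
}
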
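# Per-miRNA network construction, largest connected component, centrality
# ordering and plateau-based key-gene extraction.

#' Restrict a target catalog to tissue-expressed genes
#'
#' Intersects every miRNA's target set with the genes whose expression level
#' is at least `min_level`. Genes absent from the profile count as not
#' expressed. Empty result sets are allowed.
#'
#' @param catalog a [target_catalog()].
#' @param profile an [expression_profile()].
#' @param min_level minimum expression level (nTPM-like units) for a gene to
#'   count as expressed; default 1.
#' @return a [target_catalog()] of expressed targets.
#' @export
filter_expressed_targets <- function(catalog, profile, min_level = 1.0) {
  expressed <- names(profile$levels)[profile$levels >= min_level]
  target_catalog(lapply(unclass(catalog), intersect, y = expressed))
}

#' Vertex-induced target network
#'
#' Induced subgraph of the interaction graph on a target gene set. Targets
#' absent from the interaction graph become isolated nodes, so the vertex
#' set always equals the target set.
#'
#' @param targets character vector of gene symbols.
#' @param ppi undirected interaction graph (igraph).
#' @return igraph on exactly `targets`.
#' @export
build_target_network <- function(targets, ppi) {
  targets <- sort(unique(toupper(targets)))
  present <- intersect(targets, igraph::V(ppi)$name)
  g <- igraph::induced_subgraph(ppi, present)
  missing <- setdiff(targets, present)
  if (length(missing)) g <- igraph::add_vertices(g, length(missing),
                                                 name = missing)
  g
}

#' Largest connected component
#'
#' Returns the component with the most nodes; ties are broken in favour of
#' the component containing the lexicographically smallest gene symbol, so
#' the result is deterministic.
#'
#' @param g igraph.
#' @return igraph restricted to the largest component (empty graph, with a
#'   warning, when `g` has no vertices).
#' @export
largest_connected_component <- function(g) {
  if (igraph::vcount(g) == 0L) {
    warning("empty graph has no connected component")
    return(g)
  }
  comp <- igraph::components(g)
  best <- which(comp$csize == max(comp$csize))
  if (length(best) > 1L) {
    # smallest member symbol per tied component decides
    firsts <- vapply(best, function(ci)
      min(igraph::V(g)$name[comp$membership == ci]), character(1))
    best <- best[order(firsts)[1L]]
  }
  igraph::induced_subgraph(g, which(comp$membership == best))
}

#' Normalized degree, betweenness and combined centrality
#'
#' Degree is normalized by `n - 1`; betweenness uses the standard
#' pair-normalization `2 B(v) / ((n-1)(n-2))` so both centralities live on
#' \[0,1\] before summation. `combined` is their sum.
#'
#' @param g a connected igraph with at least 2 nodes.
#' @return data.frame with columns `gene`, `degree`, `betweenness`,
#'   `combined`, one row per node.
#' @export
compute_centralities <- function(g) {
  n <- igraph::vcount(g)
  if (n < 2L) stop("centralities need a connected graph with >= 2 nodes")
  if (!igraph::is_connected(g)) stop("graph must be connected")
  deg <- igraph::degree(g) / (n - 1)
  btw <- if (n == 2L) setNames(c(0, 0), igraph::V(g)$name)
         else igraph::betweenness(g, directed = FALSE, normalized = TRUE)
  data.frame(gene = igraph::V(g)$name,
             degree = unname(deg),
             betweenness = unname(btw),
             combined = unname(deg + btw),
             stringsAsFactors = FALSE)
}

#' Knee of a component-decay curve
#'
#' Given the decay curve `S(0), ..., S(m)` of largest-component cardinality
#' after successive removals, returns the removal count `p*` maximizing the
#' vertical distance between the chord from `(0, S(0))` to `(m, S(m))` and
#' the curve (the "knee"). A linear or constant curve has no knee and
#' returns 1; ties go to the smallest index.
#'
#' @param curve non-increasing numeric vector `S(0..m)`, length >= 2.
#' @return integer plateau index `p*` in `1..m`.
#' @export
detect_plateau <- function(curve) {
  m <- length(curve) - 1L
  if (m < 1L) stop("decay curve needs at least 2 points")
  if (m == 1L) return(1L)
  k <- seq_len(m - 1L)
  chord <- curve[1L] + (curve[m + 1L] - curve[1L]) * k / m
  d <- chord - curve[k + 1L]
  if (max(d) <= 0) return(1L)
  as.integer(which.max(d))
}

#' Extract key genes from a largest connected component
#'
#' Centralities are computed once on the intact component. Nodes are then
#' removed one-by-one in order of decreasing combined centrality (ties:
#' gene symbol ascending), recording the cardinality of the largest
#' surviving component after each removal. The key genes are the removal
#' prefix up to the decay curve's plateau (see [detect_plateau()]).
#'
#' @param lcc connected igraph with >= 2 nodes (typically from
#'   [largest_connected_component()]).
#' @param id optional miRNA id recorded in the result.
#' @param plateau how to locate the plateau: `"knee"` (maximal distance to
#'   chord, default) or `"window"` (first index opening a run of
#'   `window_k` equal cardinalities).
#' @param window_k run length for the `"window"` strategy.
#' @return object of class `key_gene_result`: list with `mirna`,
#'   `removal_order`, `centrality` (data.frame, removal order), `curve`
#'   (`S(0..n)`), `plateau` and `key_genes`.
#' @export
extract_key_genes <- function(lcc, id = NULL,
                              plateau = c("knee", "window"), window_k = 3L) {
  plateau <- match.arg(plateau)
  n <- igraph::vcount(lcc)
  if (n < 2L) stop("key-gene extraction needs an LCC with >= 2 nodes")
  cent <- compute_centralities(lcc)
  cent <- cent[order(-cent$combined, cent$gene), , drop = FALSE]
  rownames(cent) <- NULL
  order_genes <- cent$gene

  curve <- numeric(n + 1L)
  curve[1L] <- n
  g <- lcc
  for (k in seq_len(n)) {
    g <- igraph::delete_vertices(g, order_genes[k])
    curve[k + 1L] <- if (igraph::vcount(g) == 0L) 0
                     else max(igraph::components(g)$csize)
  }

  p_star <- switch(plateau,
    knee = detect_plateau(curve),
    window = plateau_window(curve, window_k))

  structure(list(mirna = id,
                 removal_order = order_genes,
                 centrality = cent,
                 curve = curve,
                 plateau = p_star,
                 key_genes = order_genes[seq_len(p_star)]),
            class = "key_gene_result")
}

# First removal count after which the curve stays constant for window_k
# consecutive steps; falls back to the knee when no such run exists.
plateau_window <- function(curve, window_k = 3L) {
  m <- length(curve) - 1L
  if (m >= window_k) {
    for (k in seq_len(m - window_k + 1L)) {
      run <- curve[(k + 1L):(k + window_k)]
      if (all(run == run[1L])) return(as.integer(k))
    }
  }
  detect_plateau(curve)
}

#' @export
print.key_gene_result <- function(x, ...) {
  cat(sprintf("Key-gene extraction%s: LCC %d node(s), plateau after %d removal(s)\n",
              if (is.null(x$mirna)) "" else paste0(" [", x$mirna, "]"),
              x$curve[1L], x$plateau))
  cat("Key genes:", paste(x$key_genes, collapse = ", "), "\n")
  invisible(x)
}

#' @export
plot.key_gene_result <- function(x, ...) {
  plot(seq_along(x$curve) - 1L, x$curve, type = "s",
       xlab = "nodes removed", ylab = "largest component size",
       main = if (is.null(x$mirna)) "LCC decay" else x$mirna, ...)
  graphics::abline(v = x$plateau, lty = 2)
  invisible(x)
}

# Removal-trace table for export: rank, gene, combined score, S after removal.
removal_trace <- function(result) {
  data.frame(rank = seq_along(result$removal_order),
             gene = result$removal_order,
             combined = result$centrality$combined,
             lcc_after = result$curve[-1L],
             stringsAsFactors = FALSE)
}
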
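# Algorithm-consistency analysis: progressively eject random non-key nodes
# from an LCC and measure how stable the extracted key-gene set is.

#' Node-ejection consistency test
#'
#' Within each replicate a random permutation of the non-key LCC nodes is
#' fixed and ejection grows cumulatively: at step `s` the first
#' `round(s * step_fraction * n_nonkey)` nodes of that permutation are
#' removed from the LCC, key-gene extraction is rerun on the largest
#' component of the surviving graph, and the resulting "test" key genes are
#' compared with the original "true" key genes.
#'
#' @param lcc connected igraph (the intact largest connected component).
#' @param true_keys a `key_gene_result` for `lcc` (computed when NULL).
#' @param steps number of ejection steps, default 9.
#' @param step_fraction fraction of the original non-key nodes ejected per
#'   step, default 0.1 (so the default schedule removes 10%..90%).
#' @param replicates independent random ejection orders, default 20.
#' @param seed RNG seed.
#' @param plateau,window_k plateau strategy passed to [extract_key_genes()].
#' @return data.frame of class `robustness_report` with one row per
#'   (step, replicate): `step`, `fraction`, `replicate`, `n_test`,
#'   `n_true`, `overlap` (= |test ∩ true| / |test|, NA when no test key
#'   gene survives) and `ratio` (= |test| / |true|).
#' @export
node_ejection_test <- function(lcc, true_keys = NULL, steps = 9L,
                               step_fraction = 0.1, replicates = 20L,
                               seed = NULL, plateau = "knee", window_k = 3L) {
  if (!is.null(seed)) set.seed(seed)
  if (is.null(true_keys))
    true_keys <- extract_key_genes(lcc, plateau = plateau,
                                   window_k = window_k)
  true_set <- true_keys$key_genes
  nodes <- igraph::V(lcc)$name
  non_key <- setdiff(nodes, true_set)
  if (!length(non_key)) stop("LCC has no non-key nodes to eject")

  rows <- vector("list", steps * replicates)
  idx <- 0L
  for (r in seq_len(replicates)) {
    perm <- sample(non_key)
    for (s in seq_len(steps)) {
      n_out <- round(s * step_fraction * length(non_key))
      if (n_out >= length(non_key)) {
        warning("step ", s, " would eject all non-key nodes; truncated")
        n_out <- length(non_key) - 1L
      }
      survivor <- igraph::delete_vertices(lcc, perm[seq_len(n_out)])
      sub_lcc <- suppressWarnings(largest_connected_component(survivor))
      test_set <- if (igraph::vcount(sub_lcc) >= 2L)
        extract_key_genes(sub_lcc, plateau = plateau,
                          window_k = window_k)$key_genes
      else character(0)
      idx <- idx + 1L
      rows[[idx]] <- data.frame(
        step = s, fraction = s * step_fraction, replicate = r,
        n_test = length(test_set), n_true = length(true_set),
        overlap = if (length(test_set))
          length(intersect(test_set, true_set)) / length(test_set)
        else NA_real_,
        ratio = length(test_set) / length(true_set))
    }
  }
  report <- do.call(rbind, rows)
  class(report) <- c("robustness_report", "data.frame")
  report
}

#' @export
print.robustness_report <- function(x, ...) {
  agg <- aggregate(cbind(overlap, ratio) ~ step,
                   data = as.data.frame(x), FUN = median, na.rm = TRUE)
  cat("Node-ejection consistency (medians per step):\n")
  print.data.frame(agg, digits = 3, row.names = FALSE)
  invisible(x)
}

#' @export
plot.robustness_report <- function(x, ...) {
  df <- as.data.frame(x)
  graphics::boxplot(overlap ~ fraction, data = df,
                    xlab = "fraction of non-key nodes ejected",
                    ylab = "fraction of test keys among true keys",
                    ylim = c(0, 1), ...)
  invisible(x)
}
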
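# Pathway overrepresentation of key genes: one-sided hypergeometric test
# with Benjamini-Hochberg control across the pathways tested per miRNA.

#' Benjamini-Hochberg adjustment
#'
#' Standard step-up BH with monotonicity enforcement, order-preserving.
#'
#' @param pvalues numeric vector of p-values in (0, 1].
#' @return vector of adjusted q-values, same order as the input.
#' @export
bh_adjust <- function(pvalues) {
  stopifnot(all(pvalues > 0 & pvalues <= 1))
  p.adjust(pvalues, method = "BH")
}

#' Hypergeometric overrepresentation analysis
#'
#' Tests every pathway in the collection for overrepresentation of the key
#' genes with the upper-tail hypergeometric probability `P(X >= k)` where
#' the universe has `N` genes, `K` of them in the pathway and `n` key genes
#' are drawn. Key genes outside the universe are dropped with a warning;
#' pathway memberships are likewise intersected with the universe.
#'
#' @param key_genes character vector of gene symbols.
#' @param collection a [gene_set_collection()].
#' @param universe character vector of gene symbols defining the sampling
#'   population (typically the pathway-annotated genes intersected with the
#'   tissue-expressed set).
#' @param alpha significance level for the `significant` flag, default 0.05.
#' @param gate `"q"` (default) flags pathways with BH q < alpha; `"p"` uses
#'   the raw p-value.
#' @param method `"hypergeometric"` (default, Fisher exact upper tail) or
#'   `"binomial"`, the approximation `P(Bin(n, K/N) >= k)` used by some
#'   annotation web services, offered for comparison.
#' @return data.frame of class `enrichment_table`, sorted by p ascending,
#'   with columns `pathway`, `name`, `k` (overlap), `K` (pathway size in
#'   universe), `n` (key genes in universe), `N` (universe size), `p`, `q`,
#'   `significant`.
#' @export
hypergeometric_enrichment <- function(key_genes, collection, universe,
                                      alpha = 0.05, gate = c("q", "p"),
                                      method = c("hypergeometric", "binomial")) {
  gate <- match.arg(gate)
  method <- match.arg(method)
  universe <- unique(toupper(universe))
  if (!length(universe)) stop("empty universe")
  if (!length(collection)) stop("empty gene-set collection")
  key_genes <- unique(toupper(key_genes))
  outside <- setdiff(key_genes, universe)
  if (length(outside))
    warning(length(outside), " key gene(s) outside the universe dropped")
  keys <- intersect(key_genes, universe)
  n <- length(keys)
  N <- length(universe)

  ids <- names(collection)
  K <- vapply(ids, function(id)
    sum(collection[[id]]$members %in% universe), integer(1))
  k <- vapply(ids, function(id)
    sum(keys %in% collection[[id]]$members), integer(1))
  # upper tail including k itself
  p <- if (method == "binomial")
    stats::pbinom(k - 1L, n, K / N, lower.tail = FALSE)
  else phyper(k - 1L, K, N - K, n, lower.tail = FALSE)
  p[k == 0L] <- 1
  tab <- data.frame(pathway = ids,
                    name = vapply(collection, `[[`, character(1), "name"),
                    k = k, K = K, n = n, N = N, p = p,
                    stringsAsFactors = FALSE)
  tab$q <- bh_adjust(tab$p)
  tab$significant <- if (gate == "q") tab$q < alpha else tab$p < alpha
  tab <- tab[order(tab$p, tab$pathway), , drop = FALSE]
  rownames(tab) <- NULL
  class(tab) <- c("enrichment_table", "data.frame")
  tab
}

#' @export
print.enrichment_table <- function(x, ...) {
  cat(sprintf("Enrichment: %d pathway(s) tested, %d significant\n",
              nrow(x), sum(x$significant)))
  print.data.frame(head(as.data.frame(x), 10L), digits = 3)
  if (nrow(x) > 10L) cat("... (", nrow(x) - 10L, " more rows)\n", sep = "")
  invisible(x)
}
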
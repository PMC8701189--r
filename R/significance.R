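# Monte Carlo empirical p-values for the observed bigraph: (a) shift of the
# pathway-degree distribution against random miRNA sets, (b) probability of
# a greedy module covering at least the observed number of miRNAs.
#
# The per-miRNA stage (expression filter -> network -> LCC -> key genes ->
# enrichment) depends only on the miRNA, not on which random set it is drawn
# into, so each catalog miRNA is evaluated once and cached; every Monte Carlo
# iteration then reduces to sampling ids and assembling a bigraph. The
# sampled null is identical to re-running the full pipeline per iteration.

# Environment-backed memo of per-miRNA significant-pathway sets.
significance_cache <- function(catalog, profile, ppi, collection, config) {
  env <- new.env(parent = emptyenv())
  universe <- enrichment_universe(collection, profile, config)
  list(
    sig_sets = function(mirna) {
      if (!is.null(env[[mirna]])) return(env[[mirna]])
      res <- mirna_stage(catalog[[mirna]], profile, ppi, collection,
                         universe, config)
      env[[mirna]] <- res$significant
      res$significant
    }
  )
}

# One miRNA through the per-miRNA stages; returns counts, key result and
# significant pathway ids. `targets` is the miRNA's raw target set.
mirna_stage <- function(targets, profile, ppi, collection, universe, config) {
  expressed_genes <- names(profile$levels)[profile$levels >= config$min_level]
  expressed <- intersect(toupper(targets), expressed_genes)
  net <- build_target_network(expressed, ppi)
  lcc <- if (igraph::vcount(net)) suppressWarnings(
    largest_connected_component(net)) else net
  lcc_n <- igraph::vcount(lcc)
  if (lcc_n < 2L) {
    return(list(total = length(unique(toupper(targets))),
                expressed = length(expressed), lcc = 0L,
                key = NULL, key_genes = character(0),
                enrichment = NULL, significant = character(0)))
  }
  key <- extract_key_genes(lcc, plateau = config$plateau,
                           window_k = config$window_k)
  enr <- suppressWarnings(hypergeometric_enrichment(
    key$key_genes, collection, universe,
    alpha = config$alpha, gate = config$gate, method = config$enrich_method))
  list(total = length(unique(toupper(targets))),
       expressed = length(expressed), lcc = as.integer(lcc_n),
       lcc_graph = lcc,
       key = key, key_genes = key$key_genes,
       enrichment = enr, significant = enr$pathway[enr$significant])
}

# Universe for the overrepresentation test (see pipeline_config()).
enrichment_universe <- function(collection, profile, config) {
  anno <- unique(unlist(lapply(collection, `[[`, "members")))
  if (identical(config$universe, "collection")) return(anno)
  expressed <- names(profile$levels)[profile$levels >= config$min_level]
  intersect(anno, expressed)
}

#' miRNAs eligible for random resampling
#'
#' A catalog miRNA is eligible when its expressed-target network has a
#' largest connected component with at least 2 nodes (a degenerate network
#' cannot yield key genes).
#'
#' @param catalog a [target_catalog()].
#' @param profile an [expression_profile()].
#' @param ppi interaction graph.
#' @param min_level expression threshold, default 1.
#' @return character vector of eligible miRNA ids.
#' @export
eligible_mirnas <- function(catalog, profile, ppi, min_level = 1.0) {
  expressed_genes <- names(profile$levels)[profile$levels >= min_level]
  ok <- vapply(names(catalog), function(m) {
    expressed <- intersect(catalog[[m]], expressed_genes)
    if (length(expressed) < 2L) return(FALSE)
    net <- build_target_network(expressed, ppi)
    max(igraph::components(net)$csize) >= 2L
  }, logical(1))
  names(catalog)[ok]
}

#' Sample a random miRNA set
#'
#' Uniform sample without replacement from the eligible miRNAs of the
#' catalog (see [eligible_mirnas()]).
#'
#' @param catalog a [target_catalog()].
#' @param size number of miRNAs to draw.
#' @param eligible optional precomputed eligible id vector; when NULL it is
#'   computed from `profile` and `ppi` (or falls back to the whole catalog
#'   if those are not given).
#' @param profile,ppi inputs for the eligibility rule.
#' @param min_level expression threshold used for eligibility.
#' @param seed optional RNG seed for a reproducible draw.
#' @return character vector of `size` miRNA ids.
#' @export
sample_random_mirna_set <- function(catalog, size, eligible = NULL,
                                    profile = NULL, ppi = NULL,
                                    min_level = 1.0, seed = NULL) {
  if (is.null(eligible)) {
    eligible <- if (!is.null(profile) && !is.null(ppi))
      eligible_mirnas(catalog, profile, ppi, min_level)
    else names(catalog)
  }
  if (length(eligible) < size)
    stop("only ", length(eligible), " eligible miRNA(s) for a sample of ",
         size)
  if (!is.null(seed)) set.seed(seed)
  sort(sample(eligible, size))
}

# Right-side (pathway-node) degree statistics of a bigraph.
bigraph_statistic <- function(bg, statistic) {
  if (is.null(bg) || !nrow(bg$edges)) return(0)
  degree_statistic(as.numeric(table(bg$edges$right)), statistic)
}

degree_statistic <- function(d, statistic) {
  if (!length(d)) return(0)
  switch(statistic,
         mean_degree = mean(d),
         max_degree = max(d),
         skewness = if (length(d) < 2L || stats::sd(d) == 0) 0
                    else mean((d - mean(d))^3) / stats::sd(d)^3)
}

new_null_distribution <- function(statistic, observed, samples, seed) {
  structure(list(statistic = statistic, observed = observed,
                 samples = samples, iterations = length(samples),
                 seed = seed, p = empirical_p(observed, samples)),
            class = "null_distribution")
}

#' @export
print.null_distribution <- function(x, ...) {
  cat(sprintf("Monte Carlo null ('%s'): observed %.4g, %d iteration(s), empirical p = %.4g\n",
              x$statistic, x$observed, x$iterations, x$p))
  invisible(x)
}

# Shared Monte Carlo loop over random miRNA sets.
mc_null_samples <- function(per_set_statistic, catalog, profile, ppi,
                            collection, config, size, iterations) {
  cache <- significance_cache(catalog, profile, ppi, collection, config)
  eligible <- eligible_mirnas(catalog, profile, ppi, config$min_level)
  if (length(eligible) < size)
    stop("only ", length(eligible), " eligible miRNA(s) for samples of ",
         size)
  vapply(seq_len(iterations), function(i) {
    ids <- sample(eligible, size)
    sig <- lapply(ids, cache$sig_sets)
    names(sig) <- ids
    per_set_statistic(sig)
  }, numeric(1))
}

#' Monte Carlo test for the shift of the bigraph degree distribution
#'
#' Compares a degree statistic of the observed miRNA-pathway bigraph with
#' its distribution over bigraphs built from random similar-sized miRNA
#' sets, each run through the full per-miRNA pipeline (expression filter,
#' network, key genes, enrichment). Right-tailed empirical p with add-one
#' correction.
#'
#' @param observed the observed `mirna_bigraph`.
#' @param catalog,profile,ppi,collection the pipeline inputs; random sets
#'   are drawn from the whole catalog (eligibility: expressed-target LCC
#'   with >= 2 nodes).
#' @param config a [pipeline_config()].
#' @param size size of each random miRNA set (use the observed set size).
#' @param iterations Monte Carlo iterations, default 10000.
#' @param seed RNG seed.
#' @param statistic `"mean_degree"` (default), `"max_degree"` or
#'   `"skewness"` of the pathway-node degree distribution.
#' @return object of class `null_distribution` with fields `statistic`,
#'   `observed`, `samples`, `iterations`, `seed`, `p`.
#' @export
degree_shift_test <- function(observed, catalog, profile, ppi, collection,
                              config = pipeline_config(), size,
                              iterations = 10000, seed = NULL,
                              statistic = c("mean_degree", "max_degree",
                                            "skewness")) {
  statistic <- match.arg(statistic)
  if (iterations < 100) warning("fewer than 100 iterations: unstable p")
  if (!is.null(seed)) set.seed(seed)
  obs <- bigraph_statistic(observed, statistic)
  samples <- mc_null_samples(
    function(sig) degree_statistic(as.numeric(table(unlist(sig))), statistic),
    catalog, profile, ppi, collection, config, size, iterations)
  new_null_distribution(statistic, obs, samples, seed)
}

#' Monte Carlo test for greedy-module miRNA coverage
#'
#' Estimates the probability that a random similar-sized miRNA set yields a
#' first greedy iteration covering at least `observed_coverage` miRNAs.
#'
#' @param observed_coverage miRNA count covered by the observed first
#'   module.
#' @inheritParams degree_shift_test
#' @return a `null_distribution` (statistic `"coverage"`).
#' @export
module_coverage_test <- function(observed_coverage, catalog, profile, ppi,
                                 collection, config = pipeline_config(),
                                 size, iterations = 10000, seed = NULL) {
  if (iterations < 100) warning("fewer than 100 iterations: unstable p")
  if (!is.null(seed)) set.seed(seed)
  coverage_stat <- function(sig) {
    sig <- sig[lengths(sig) > 0L]
    if (length(sig) < 2L) return(0)
    bg <- build_bigraph(sig)
    if (!has_connected_mirnas(bg)) return(0)
    mods <- greedy_extract_modules(bg, max_iterations = 1)
    if (!length(mods)) 0 else length(mods[[1L]]$mirnas)
  }
  samples <- mc_null_samples(coverage_stat, catalog, profile, ppi,
                             collection, config, size, iterations)
  new_null_distribution("coverage", observed_coverage, samples, seed)
}

#' Write a null distribution as TSV samples plus JSON summary
#'
#' @param nd a `null_distribution`.
#' @param prefix output path prefix; writes `<prefix>_samples.tsv` and
#'   `<prefix>_summary.json`.
#' @return the JSON path, invisibly.
#' @export
write_null_distribution <- function(nd, prefix) {
  write_tsv(data.frame(iteration = seq_along(nd$samples),
                       statistic = nd$samples), paste0(prefix, "_samples.tsv"))
  out <- paste0(prefix, "_summary.json")
  jsonlite::write_json(
    list(statistic = nd$statistic, observed = nd$observed,
         iterations = nd$iterations,
         seed = if (is.null(nd$seed)) NA else nd$seed, p = nd$p),
    out, auto_unbox = TRUE, digits = NA)
  invisible(out)
}
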
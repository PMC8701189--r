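# End-to-end orchestration: expression filter -> per-miRNA network and key
# genes -> enrichment -> bigraph -> greedy modules -> optional Monte Carlo,
# with a per-miRNA audit summary in the style of a target-count table.

#' Pipeline configuration
#'
#' Bundles every tunable analysis parameter with its default.
#'
#' @param min_score inclusive interaction-confidence threshold (applied at
#'   read time), default 0.9 ("highest confidence").
#' @param min_level minimum expression level for a gene to count as
#'   expressed, default 1 (nTPM-like units).
#' @param alpha significance level for enrichment, default 0.05.
#' @param gate `"q"` (BH FDR, default) or `"p"` gate for bigraph edges.
#' @param universe `"expressed"` (pathway-annotated genes intersected with
#'   the expressed set, default) or `"collection"` (annotated genes only).
#' @param plateau decay-curve plateau strategy, `"knee"` or `"window"`.
#' @param window_k run length for the `"window"` strategy.
#' @param max_iterations greedy-search iterations, default 2.
#' @param enrich_method `"hypergeometric"` or `"binomial"`.
#' @param mc_iterations Monte Carlo iterations for the significance tests
#'   (0 disables them), default 0.
#' @param statistic degree-shift statistic, see [degree_shift_test()].
#' @return object of class `pipeline_config`.
#' @export
pipeline_config <- function(min_score = 0.9, min_level = 1.0, alpha = 0.05,
                            gate = c("q", "p"),
                            universe = c("expressed", "collection"),
                            plateau = c("knee", "window"), window_k = 3L,
                            max_iterations = 2,
                            enrich_method = c("hypergeometric", "binomial"),
                            mc_iterations = 0,
                            statistic = "mean_degree") {
  structure(list(min_score = min_score, min_level = min_level,
                 alpha = alpha, gate = match.arg(gate),
                 universe = match.arg(universe),
                 plateau = match.arg(plateau), window_k = window_k,
                 max_iterations = max_iterations,
                 enrich_method = match.arg(enrich_method),
                 mc_iterations = mc_iterations, statistic = statistic),
            class = "pipeline_config")
}

# Tiny polynomial hash of the deparsed config, for run provenance lines.
config_hash <- function(config) {
  bytes <- utf8ToInt(paste(deparse(unclass(config)), collapse = ""))
  h <- 0
  for (b in bytes) h <- (h * 31 + b) %% 2147483647
  sprintf("%08x", h)
}

#' Run the full miRNA-module pipeline
#'
#' For every query miRNA: restrict targets to expressed genes, build the
#' induced interaction network, extract key genes from its largest
#' connected component, and test pathway overrepresentation. Significant
#' (miRNA, pathway) pairs form a bigraph mined by the greedy
#' maximal-coverage search. When no two miRNAs are connected through
#' pathways, the search falls back to the miRNA-key gene bigraph. With
#' `config$mc_iterations > 0` the degree-shift and module-coverage Monte
#' Carlo tests are run against random miRNA sets of the same size.
#'
#' @param catalog a [target_catalog()].
#' @param profile an [expression_profile()].
#' @param ppi interaction graph (already score-filtered, see
#'   [read_interactions()]).
#' @param collection a [gene_set_collection()].
#' @param mirnas query miRNA ids; ids absent from the catalog are dropped
#'   with a warning (error when none remain).
#' @param config a [pipeline_config()].
#' @param seed RNG seed for the Monte Carlo stage.
#' @param out_dir when given, all artifact tables are written beneath it.
#' @return object of class `mirmod_run`: `summary` (per-miRNA counts and
#'   percentages), `per_mirna` (stage details), `enrichment` (combined
#'   long-format table), `bigraph`, `bigraph_type` (`"pathway"` or
#'   `"gene"` fallback), `modules`, `null_degree`, `null_coverage`,
#'   `config`, `config_hash`.
#' @export
run_pipeline <- function(catalog, profile, ppi, collection, mirnas,
                         config = pipeline_config(), seed = NULL,
                         out_dir = NULL) {
  if (!length(mirnas)) stop("query miRNA list is empty")
  missing <- setdiff(mirnas, names(catalog))
  if (length(missing)) {
    warning("query miRNA(s) absent from catalog: ",
            paste(missing, collapse = ", "))
    mirnas <- setdiff(mirnas, missing)
  }
  if (!length(mirnas)) stop("no query miRNA is present in the catalog")
  mirnas <- sort(mirnas)

  universe <- enrichment_universe(collection, profile, config)
  per <- lapply(mirnas, function(m)
    mirna_stage(catalog[[m]], profile, ppi, collection, universe, config))
  names(per) <- mirnas

  pct <- function(n, total) ifelse(total > 0, round_half_up(100 * n / total), 0)
  summary_df <- data.frame(
    mirna = mirnas,
    total = vapply(per, `[[`, integer(1), "total"),
    expressed = vapply(per, `[[`, integer(1), "expressed"),
    in_lcc = vapply(per, `[[`, integer(1), "lcc"),
    key_genes = vapply(per, function(x) length(x$key_genes), integer(1)),
    stringsAsFactors = FALSE)
  summary_df$expressed_pct <- pct(summary_df$expressed, summary_df$total)
  summary_df$in_lcc_pct <- pct(summary_df$in_lcc, summary_df$total)
  summary_df$key_genes_pct <- pct(summary_df$key_genes, summary_df$total)
  rownames(summary_df) <- NULL

  sig <- lapply(per, `[[`, "significant")
  bigraph_type <- "pathway"
  bg <- if (any(lengths(sig) > 0L)) build_bigraph(sig) else NULL
  if (is.null(bg) || !has_connected_mirnas(bg)) {
    # pathway bigraph cannot link two miRNAs: key-gene fallback
    bigraph_type <- "gene"
    keys <- lapply(per, `[[`, "key_genes")
    bg <- build_gene_bigraph(keys)
  }
  modules <- if (has_connected_mirnas(bg))
    greedy_extract_modules(bg, max_iterations = config$max_iterations)
  else list()

  null_degree <- NULL
  null_coverage <- NULL
  if (config$mc_iterations > 0 && bigraph_type == "pathway") {
    null_degree <- degree_shift_test(
      bg, catalog, profile, ppi, collection, config,
      size = length(mirnas), iterations = config$mc_iterations,
      seed = seed, statistic = config$statistic)
    if (length(modules)) {
      null_coverage <- module_coverage_test(
        length(modules[[1L]]$mirnas), catalog, profile, ppi, collection,
        config, size = length(mirnas), iterations = config$mc_iterations,
        seed = if (is.null(seed)) NULL else seed + 1L)
      modules[[1L]]$p <- null_coverage$p
    }
  }

  run <- structure(
    list(summary = summary_df, per_mirna = per,
         enrichment = combined_enrichment(per),
         bigraph = bg, bigraph_type = bigraph_type, modules = modules,
         null_degree = null_degree, null_coverage = null_coverage,
         config = config, config_hash = config_hash(config),
         collection = collection),
    class = "mirmod_run")
  if (!is.null(out_dir)) write_run_artifacts(run, out_dir)
  run
}

# Long-format (miRNA, pathway, k, K, n, N, p, q, significant) table.
combined_enrichment <- function(per) {
  rows <- lapply(names(per), function(m) {
    enr <- per[[m]]$enrichment
    if (is.null(enr)) return(NULL)
    cbind(mirna = m, as.data.frame(enr), stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  if (!is.null(out)) rownames(out) <- NULL
  out
}

write_run_artifacts <- function(run, out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  write_tsv(run$summary, file.path(out_dir, "summary.tsv"))
  if (!is.null(run$enrichment))
    write_tsv(run$enrichment, file.path(out_dir, "enrichment.tsv"))
  write_bigraph(run$bigraph, file.path(out_dir, "bigraph.tsv"))
  if (length(run$modules))
    write_tsv(modules_table(run$modules, run$collection),
              file.path(out_dir, "modules.tsv"))
  for (m in names(run$per_mirna)) {
    st <- run$per_mirna[[m]]
    if (is.null(st$key)) next
    safe <- gsub("[^A-Za-z0-9._-]", "_", m)
    write_tsv(removal_trace(st$key),
              file.path(out_dir, paste0(safe, "_removal_trace.tsv")))
    write_tsv(data.frame(gene = st$key_genes),
              file.path(out_dir, paste0(safe, "_key_genes.tsv")))
    write_edge_list(st$lcc_graph,
                    file.path(out_dir, paste0(safe, "_lcc_edges.tsv")))
  }
  if (!is.null(run$null_degree))
    write_null_distribution(run$null_degree,
                            file.path(out_dir, "null_degree"))
  if (!is.null(run$null_coverage))
    write_null_distribution(run$null_coverage,
                            file.path(out_dir, "null_coverage"))
  invisible(out_dir)
}

#' @export
print.mirmod_run <- function(x, ...) {
  cat(sprintf("miRNA-module run [%s]: %d miRNA(s), %s bigraph, %d module(s)\n",
              x$config_hash, nrow(x$summary), x$bigraph_type,
              length(x$modules)))
  print.data.frame(x$summary, row.names = FALSE)
  for (m in x$modules) print(m)
  if (!is.null(x$null_degree))
    cat(sprintf("Degree-shift test (%s): p = %.4g\n",
                x$null_degree$statistic, x$null_degree$p))
  if (!is.null(x$null_coverage))
    cat(sprintf("Module-coverage test: p = %.4g\n", x$null_coverage$p))
  invisible(x)
}

#' @export
summary.mirmod_run <- function(object, ...) {
  object$summary
}
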
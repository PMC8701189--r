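# miRNA-pathway bigraph and greedy maximal-coverage module extraction.
# The fallback bigraph (miRNA-key gene) shares the same structure, so the
# greedy search applies unchanged.

new_bigraph <- function(edges, right_type) {
  edges <- unique(edges[order(edges$mirna, edges$right), , drop = FALSE])
  rownames(edges) <- NULL
  structure(list(edges = edges,
                 mirnas = sort(unique(edges$mirna)),
                 right = sort(unique(edges$right)),
                 right_type = right_type),
            class = "mirna_bigraph")
}

#' Build the miRNA-pathway bigraph
#'
#' One edge per (miRNA, pathway) pair where the miRNA's key genes are
#' significantly overrepresented in the pathway.
#'
#' @param enrichments named list mapping each miRNA id to the character
#'   vector of its significant pathway ids.
#' @return object of class `mirna_bigraph` with fields `edges` (data.frame
#'   `mirna`, `right`), `mirnas`, `right`, `right_type`.
#' @export
build_bigraph <- function(enrichments) {
  sizes <- lengths(enrichments)
  if (!length(enrichments) || all(sizes == 0L))
    stop("no miRNA has a significant pathway; fall back to the key-gene ",
         "bigraph (build_gene_bigraph)")
  edges <- data.frame(
    mirna = rep(names(enrichments), sizes),
    right = as.character(unlist(enrichments, use.names = FALSE)),
    stringsAsFactors = FALSE)
  new_bigraph(edges, "pathway")
}

#' Build the fallback miRNA-key gene bigraph
#'
#' Same bipartite structure as [build_bigraph()] with key genes on the
#' right side; [greedy_extract_modules()] applies unchanged.
#'
#' @param key_results named list mapping miRNA id to its key-gene set.
#' @return a `mirna_bigraph` with `right_type = "gene"`.
#' @export
build_gene_bigraph <- function(key_results) {
  edges <- data.frame(
    mirna = rep(names(key_results), lengths(key_results)),
    right = as.character(unlist(key_results, use.names = FALSE)),
    stringsAsFactors = FALSE)
  new_bigraph(edges, "gene")
}

#' @export
print.mirna_bigraph <- function(x, ...) {
  cat(sprintf("miRNA-%s bigraph: %d miRNA(s), %d %s node(s), %d edge(s)\n",
              x$right_type, length(x$mirnas), length(x$right),
              x$right_type, nrow(x$edges)))
  invisible(x)
}

#' Are at least two miRNAs connected through the bigraph?
#'
#' In a bipartite graph two miRNAs lie in the same component exactly when a
#' chain of shared right-side nodes links them; equivalently, some right
#' node has degree >= 2.
#'
#' @param bg a `mirna_bigraph`.
#' @return TRUE iff two or more miRNAs share a connected component.
#' @export
has_connected_mirnas <- function(bg) {
  if (!nrow(bg$edges)) return(FALSE)
  any(table(bg$edges$right) >= 2L)
}

#' Greedy extraction of maximal-coverage modules
#'
#' Iteratively selects, from the remaining right-side nodes, ALL nodes tied
#' at the maximal number of covered (remaining) miRNAs; the module's miRNA
#' set is the union of their neighborhoods. Selected nodes and covered
#' miRNAs are removed before the next iteration. The search stops when the
#' maximal coverage drops to 1 or the bigraph is exhausted.
#'
#' @param bg a `mirna_bigraph` with at least two connected miRNAs (see
#'   [has_connected_mirnas()]); otherwise an error instructs the key-gene
#'   fallback.
#' @param max_iterations iterations to run, default 2; `Inf` runs to
#'   exhaustion.
#' @return list of `cover_module` objects: `iteration`, `pathways` (the
#'   tied right-side nodes), `mirnas` (covered set), `coverage` (the tie
#'   value c*), `neighborhoods` (named list, per selected node), `p`
#'   (empirical p-value, NA until filled by [module_coverage_test()]).
#' @export
greedy_extract_modules <- function(bg, max_iterations = 2) {
  if (!has_connected_mirnas(bg))
    stop("bigraph has no connected miRNAs; use the key-gene fallback ",
         "(build_gene_bigraph) instead")
  edges <- bg$edges
  modules <- list()
  it <- 0L
  while (it < max_iterations && nrow(edges)) {
    it <- it + 1L
    cov <- table(edges$right)
    c_star <- max(cov)
    if (c_star < 1L) break
    chosen <- sort(names(cov)[cov == c_star])
    nbhd <- lapply(chosen, function(r)
      sort(edges$mirna[edges$right == r]))
    names(nbhd) <- chosen
    covered <- sort(unique(unlist(nbhd)))
    modules[[it]] <- structure(
      list(iteration = it, pathways = chosen, mirnas = covered,
           coverage = as.integer(c_star), neighborhoods = nbhd, p = NA_real_),
      class = "cover_module")
    edges <- edges[!(edges$right %in% chosen) & !(edges$mirna %in% covered), ,
                   drop = FALSE]
    if (c_star <= 1L) break
  }
  modules
}

#' @export
print.cover_module <- function(x, ...) {
  cat(sprintf("Module (iteration %d): %d node(s) covering %d miRNA(s)%s\n",
              x$iteration, length(x$pathways), length(x$mirnas),
              if (is.na(x$p)) "" else sprintf(", empirical p = %.4g", x$p)))
  cat("  nodes: ", paste(x$pathways, collapse = ", "), "\n", sep = "")
  cat("  miRNAs: ", paste(x$mirnas, collapse = ", "), "\n", sep = "")
  invisible(x)
}

# Long-format table of modules for TSV export.
modules_table <- function(modules, collection = NULL) {
  rows <- lapply(modules, function(m) {
    data.frame(iteration = m$iteration,
               pathway = m$pathways,
               name = if (!is.null(collection))
                 vapply(m$pathways, function(p)
                   if (!is.null(collection[[p]])) collection[[p]]$name
                   else NA_character_, character(1))
               else NA_character_,
               coverage = m$coverage,
               mirnas = vapply(m$neighborhoods, paste, character(1),
                               collapse = ","),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Write a bigraph as an edge-list TSV
#' @param bg a `mirna_bigraph`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_bigraph <- function(bg, path) {
  df <- bg$edges
  names(df) <- c("mirna", bg$right_type)
  write_tsv(df, path)
}
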
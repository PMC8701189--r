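# Readers and writers for the four tabular inputs and the result tables.
# Every file-dialect decision (column matching, score scaling, GMT quirks)
# lives in this file; the rest of the package works on in-memory objects.

# ---- constructors -----------------------------------------------------------

#' Target catalog: miRNA id -> set of target gene symbols
#'
#' @param entries named list; names are miRNA ids, elements are character
#'   vectors of gene symbols. Symbols are uppercased and deduplicated.
#' @return an object of class `target_catalog` (a named list of character
#'   vectors).
#' @export
target_catalog <- function(entries = list()) {
  if (length(entries)) {
    ids <- names(entries)
    if (is.null(ids) || any(!nzchar(ids)))
      stop("every catalog entry needs a non-empty miRNA id")
    entries <- lapply(entries, function(g) {
      g <- unique(toupper(as.character(g)))
      g <- g[nzchar(g)]
      sort(g)
    })
    entries <- entries[order(ids)]
  }
  structure(entries, class = "target_catalog")
}

#' @export
print.target_catalog <- function(x, ...) {
  cat(sprintf("Target catalog: %d miRNA(s), %d distinct target gene(s)\n",
              length(x), length(unique(unlist(x)))))
  invisible(x)
}

#' Tissue expression profile
#'
#' @param tissue tissue name.
#' @param levels named non-negative numeric vector of expression values
#'   (nTPM-like units), one value per gene.
#' @return an object of class `expression_profile`.
#' @export
expression_profile <- function(tissue, levels) {
  levels <- unlist(levels)
  if (is.null(names(levels)) && length(levels))
    stop("expression levels must be named by gene symbol")
  names(levels) <- toupper(names(levels))
  if (anyDuplicated(names(levels)))
    stop("one expression value per gene per tissue is required")
  if (length(levels) && (any(!is.finite(levels)) || any(levels < 0)))
    stop("expression levels must be finite and >= 0")
  structure(list(tissue = tissue, levels = levels[order(names(levels))]),
            class = "expression_profile")
}

#' @export
print.expression_profile <- function(x, ...) {
  cat(sprintf("Expression profile: tissue '%s', %d gene(s)\n",
              x$tissue, length(x$levels)))
  invisible(x)
}

#' Gene-set (pathway) collection
#'
#' @param sets named list; names are pathway ids, each element a list with
#'   fields `name` (description) and `members` (character vector of gene
#'   symbols, uppercased and deduplicated).
#' @return an object of class `gene_set_collection`.
#' @export
gene_set_collection <- function(sets = list()) {
  if (length(sets)) {
    if (is.null(names(sets)) || anyDuplicated(names(sets)))
      stop("pathway ids must be present and unique")
    sets <- lapply(sets, function(s) {
      members <- sort(unique(toupper(as.character(s$members))))
      if (!length(members)) stop("pathway member sets must be non-empty")
      list(name = as.character(s$name), members = members)
    })
    sets <- sets[order(names(sets))]
  }
  structure(sets, class = "gene_set_collection")
}

#' @export
print.gene_set_collection <- function(x, ...) {
  cat(sprintf("Gene-set collection: %d set(s), sizes %s\n", length(x),
              if (length(x)) paste0(range(lengths(lapply(x, `[[`, "members"))),
                                    collapse = "-") else "-"))
  invisible(x)
}

# Case-insensitive column lookup; returns the first matching name or NA.
match_column <- function(cols, candidates) {
  lc <- tolower(cols)
  for (cand in candidates) {
    hit <- which(lc == tolower(cand))
    if (length(hit)) return(cols[hit[1L]])
  }
  NA_character_
}

read_tsv_file <- function(path) {
  read.delim(path, sep = "\t", header = TRUE, check.names = FALSE,
             stringsAsFactors = FALSE, quote = "", comment.char = "",
             fileEncoding = "UTF-8")
}

# ---- readers ----------------------------------------------------------------

#' Read a miRNA-target catalog from a miRTarBase-like TSV
#'
#' Expects a tab-separated file with a header containing a miRNA-id column
#' and a target-gene column (matched case-insensitively against the usual
#' database headers). Rows are deduplicated per miRNA.
#'
#' @param path path to the TSV file.
#' @param species_filter optional species name; when given, rows whose
#'   species column(s) do not equal it are dropped.
#' @return a [target_catalog()].
#' @export
read_target_catalog <- function(path, species_filter = NULL) {
  df <- read_tsv_file(path)
  mir_col <- match_column(names(df), c("miRNA", "mirna_id", "mirna"))
  gene_col <- match_column(names(df),
                           c("Target Gene", "target_gene", "target", "gene",
                             "gene_symbol", "symbol"))
  if (is.na(mir_col))
    format_error("target catalog '%s' lacks a miRNA column", path)
  if (is.na(gene_col))
    format_error("target catalog '%s' lacks a target-gene column", path)
  if (!nrow(df)) {
    warning("target catalog '", path, "' has no data rows")
    return(target_catalog())
  }
  if (!is.null(species_filter)) {
    sp_cols <- grep("species", names(df), ignore.case = TRUE, value = TRUE)
    for (sc in sp_cols) df <- df[df[[sc]] == species_filter, , drop = FALSE]
  }
  keep <- nzchar(df[[mir_col]]) & nzchar(df[[gene_col]])
  df <- df[keep, , drop = FALSE]
  if (!nrow(df)) {
    warning("target catalog '", path, "' has no usable rows")
    return(target_catalog())
  }
  target_catalog(split(df[[gene_col]], df[[mir_col]]))
}

#' Read a tissue expression table (long format)
#'
#' @param path TSV with gene, tissue and value columns (value column may be
#'   named `nTPM`, `value`, `expression` or `level`).
#' @param tissue tissue to extract; an error lists the available tissues if
#'   it is absent.
#' @return an [expression_profile()] restricted to `tissue`.
#' @export
read_expression <- function(path, tissue) {
  df <- read_tsv_file(path)
  gene_col <- match_column(names(df), c("Gene name", "gene", "gene_symbol",
                                        "symbol"))
  tissue_col <- match_column(names(df), c("Tissue", "tissue"))
  value_col <- match_column(names(df), c("nTPM", "value", "expression",
                                         "level", "TPM"))
  if (is.na(gene_col)) format_error("expression table '%s' lacks a gene column", path)
  if (is.na(tissue_col)) format_error("expression table '%s' lacks a tissue column", path)
  if (is.na(value_col)) format_error("expression table '%s' lacks a value column", path)
  df[[value_col]] <- suppressWarnings(as.numeric(df[[value_col]]))
  if (anyNA(df[[value_col]]))
    format_error("non-numeric expression value in '%s'", path)
  if (any(df[[value_col]] < 0))
    stop("negative expression value in '", path, "'")
  sel <- df[[tissue_col]] == tissue
  if (!any(sel))
    stop("tissue '", tissue, "' not found in '", path, "'; available: ",
         paste(sort(unique(df[[tissue_col]])), collapse = ", "))
  df <- df[sel, , drop = FALSE]
  expression_profile(tissue, setNames(df[[value_col]], df[[gene_col]]))
}

#' Read scored gene-gene interactions into an undirected graph
#'
#' Scores are auto-detected as either fractions in \[0,1\] or integers on the
#' 0-1000 scale used by interaction databases (detected from the maximum
#' value; the 0-1000 scale is divided by 1000). Self-loops are dropped with a
#' warning, duplicate edges keep the maximum score, and only edges with
#' score >= `min_score` are retained (inclusive threshold).
#'
#' @param path TSV with two gene columns and a score column.
#' @param min_score minimum confidence score kept, default 0.9 ("highest
#'   confidence").
#' @return an undirected simple [igraph::igraph] with edge attribute `score`
#'   and vertex names equal to uppercase gene symbols.
#' @export
read_interactions <- function(path, min_score = 0.9) {
  df <- read_tsv_file(path)
  score_col <- grep("score", names(df), ignore.case = TRUE, value = TRUE)
  if (!length(score_col))
    format_error("interaction table '%s' lacks a score column", path)
  score_col <- score_col[1L]
  gene_cols <- setdiff(names(df), score_col)[1:2]
  if (length(gene_cols) < 2 || anyNA(gene_cols))
    format_error("interaction table '%s' needs two gene columns", path)
  score <- suppressWarnings(as.numeric(df[[score_col]]))
  if (anyNA(score) && nrow(df))
    format_error("non-numeric interaction score in '%s'", path)
  interaction_graph(df[[gene_cols[1L]]], df[[gene_cols[2L]]], score,
                    min_score = min_score)
}

#' Build an interaction graph from edge vectors
#'
#' The in-memory counterpart of [read_interactions()]; applies the same
#' scale detection, self-loop removal, duplicate resolution and threshold.
#'
#' @param gene_a,gene_b character vectors of interacting gene symbols.
#' @param score numeric scores, \[0,1\] or 0-1000.
#' @param min_score inclusive confidence threshold.
#' @return undirected simple igraph with edge attribute `score`.
#' @export
interaction_graph <- function(gene_a, gene_b, score, min_score = 0.9) {
  a <- toupper(as.character(gene_a))
  b <- toupper(as.character(gene_b))
  score <- as.numeric(score)
  stopifnot(length(a) == length(b), length(a) == length(score))
  if (length(score) && max(score) > 1) score <- score / 1000
  if (any(score < 0 | score > 1))
    format_error("interaction scores outside [0,1] after scaling")
  loops <- a == b
  if (any(loops)) {
    warning(sum(loops), " self-loop interaction row(s) dropped")
    a <- a[!loops]; b <- b[!loops]; score <- score[!loops]
  }
  # canonical (sorted) unordered pairs keep vertex order deterministic;
  # duplicate pairs collapse to their maximum score
  lo <- pmin(a, b); hi <- pmax(a, b)
  o <- order(lo, hi)
  g <- igraph::graph_from_data_frame(
    data.frame(from = lo[o], to = hi[o],
               score = score[o], stringsAsFactors = FALSE),
    directed = FALSE)
  g <- igraph::simplify(g, edge.attr.comb = list(score = "max"))
  if (igraph::ecount(g)) {
    g <- igraph::delete_edges(g, igraph::E(g)[igraph::E(g)$score < min_score])
    g <- igraph::delete_vertices(g, igraph::degree(g) == 0)
  }
  # canonical vertex order, so equal edge sets give identical graphs
  igraph::permute(g, rank(igraph::V(g)$name))
}

#' Read pathway gene sets in GMT format
#'
#' Standard GMT: one set per line, `id <TAB> description <TAB> member ...`.
#'
#' @param path path to the GMT file.
#' @return a [gene_set_collection()] with deduplicated members.
#' @export
read_gmt <- function(path) {
  lines <- readLines(path, encoding = "UTF-8")
  lines <- lines[nzchar(lines)]
  sets <- list()
  for (i in seq_along(lines)) {
    fields <- strsplit(lines[[i]], "\t", fixed = TRUE)[[1L]]
    if (length(fields) < 3L)
      format_error("GMT line %d has fewer than 3 fields", i)
    id <- fields[1L]
    if (!is.null(sets[[id]]))
      format_error("GMT line %d repeats pathway id '%s'", i, id)
    sets[[id]] <- list(name = fields[2L], members = fields[-(1:2)])
  }
  gene_set_collection(sets)
}

# ---- writers ----------------------------------------------------------------

#' Write a target catalog as a two-column TSV
#' @param catalog a [target_catalog()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_target_catalog <- function(catalog, path) {
  df <- data.frame(
    miRNA = rep(names(catalog), lengths(catalog)),
    `Target Gene` = unlist(catalog, use.names = FALSE),
    check.names = FALSE, stringsAsFactors = FALSE)
  write_tsv(df, path)
}

#' Write an expression profile as a long-format TSV
#' @param profile an [expression_profile()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_expression <- function(profile, path) {
  df <- data.frame(Gene = names(profile$levels), Tissue = profile$tissue,
                   nTPM = unname(profile$levels), stringsAsFactors = FALSE)
  write_tsv(df, path)
}

#' Write a graph as a scored edge-list TSV
#'
#' The output re-reads through [read_interactions()] and is loadable by
#' standard graph viewers. Edges without a `score` attribute are written
#' with score 1.
#'
#' @param graph an igraph object.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_edge_list <- function(graph, path) {
  el <- igraph::as_edgelist(graph)
  score <- if ("score" %in% igraph::edge_attr_names(graph))
    igraph::E(graph)$score else rep(1, nrow(el))
  lo <- pmin(el[, 1L], el[, 2L]); hi <- pmax(el[, 1L], el[, 2L])
  o <- order(lo, hi)
  df <- data.frame(protein1 = lo[o], protein2 = hi[o],
                   combined_score = score[o], stringsAsFactors = FALSE)
  write_tsv(df, path)
}

#' Write a gene-set collection in GMT format
#' @param collection a [gene_set_collection()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_gmt <- function(collection, path) {
  lines <- vapply(names(collection), function(id) {
    s <- collection[[id]]
    paste(c(id, s$name, s$members), collapse = "\t")
  }, character(1))
  writeLines(lines, path, useBytes = TRUE)
  invisible(path)
}
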
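# Shared small helpers.

#' Round half away from zero
#'
#' Integer rounding where exact halves move away from zero (so 54.5 -> 55),
#' as used in the run-summary percentage columns. Base `round()` rounds
#' half-to-even and is not what summary tables in this field print.
#'
#' @param x numeric vector.
#' @return integer-valued numeric vector.
#' @export
round_half_up <- function(x) {
  sign(x) * floor(abs(x) + 0.5)
}

#' Empirical Monte Carlo p-value with add-one correction
#'
#' Right-tailed empirical p-value `(1 + #\{samples >= observed\}) /
#' (iterations + 1)`. The +1 correction guarantees p > 0 at any finite number
#' of iterations and corresponds to counting the observed value as one more
#' draw from the null.
#'
#' @param observed observed value of the statistic.
#' @param samples numeric vector of null samples.
#' @return p-value in (0, 1].
#' @export
empirical_p <- function(observed, samples) {
  stopifnot(is.finite(observed), length(samples) >= 1L)
  (1 + sum(samples >= observed)) / (length(samples) + 1)
}

# Write a data.frame as UTF-8 TSV with header, no quoting, no row names.
write_tsv <- function(df, path) {
  write.table(df, path, sep = "\t", quote = FALSE,
              row.names = FALSE, col.names = TRUE, fileEncoding = "UTF-8")
  invisible(path)
}

# Stop with a classed condition so callers/tests can distinguish
# format errors from runtime errors.
format_error <- function(msg, ...) {
  stop(errorCondition(sprintf(msg, ...),
                      class = c("mirmod_format_error", "error")))
}
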
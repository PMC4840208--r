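# Shared small helpers.

#' Round half away from zero
#'
#' Decimal rounding with ties going up (0.005 -> 0.01), the convention used
#' for all reported percentages. Base \code{round()} rounds half to even,
#' which would turn e.g. 99.765 into 99.76.
#'
#' @param x numeric vector.
#' @param digits number of decimal places.
#' @return rounded numeric vector.
#' @export
round_half_up <- function(x, digits = 0) {
  scale <- 10^digits
  sign(x) * floor(abs(x) * scale + 0.5) / scale
}

#' Percent methylated, 2 decimals
#'
#' \code{100 * n_methylated / n_total}, rounded half-up to two decimals --
#' the precision used in per-motif methylome summary tables.
#'
#' @param n_methylated count of methylated sites.
#' @param n_total total motif sites.
#' @return percentage (NA if \code{n_total} is 0).
#' @export
pct_methylated <- function(n_methylated, n_total) {
  ifelse(n_total > 0, round_half_up(100 * n_methylated / n_total, 2), NA_real_)
}

#' Fraction of a total as a percentage, 1 decimal
#'
#' Headline fractions (e.g. island candidate genes out of island genes,
#' annotated proteins out of all proteins) are conventionally reported at
#' one decimal.
#'
#' @param n_part numerator count.
#' @param n_total denominator count, must be positive.
#' @return percentage rounded half-up to 1 decimal.
#' @export
annotated_fraction <- function(n_part, n_total) {
  stopifnot(length(n_part) == length(n_total))
  if (any(n_total <= 0)) stop("zero or negative denominator")
  if (any(n_part > n_total)) stop("numerator exceeds denominator")
  round_half_up(100 * n_part / n_total, 1)
}

# internal: tab-separated writer with stable formatting (determinism contract)
write_tsv <- function(df, path) {
  utils::write.table(df, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, na = "NA")
  invisible(path)
}

read_tsv <- function(path, ...) {
  utils::read.table(path, header = TRUE, sep = "\t", quote = "",
                    comment.char = "", stringsAsFactors = FALSE, ...)
}
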
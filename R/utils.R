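#' Round half away from zero
#'
#' Commercial rounding as used by the survey-analysis conventions in this
#' package: halves move away from zero (2.5 -> 3, -2.5 -> -3), unlike base
#' [round()], which rounds halves to even. The convention matters because item
#' scores are produced by rounding latent values and a half-to-even rule would
#' shift the score distribution.
#'
#' @param x Numeric vector.
#' @param digits Number of decimal places (default 0).
#' @return Numeric vector of the same length.
#' @export
#' @examples
#' round_half_away(c(2.5, 3.5, -2.5))
round_half_away <- function(x, digits = 0) {
  m <- 10^digits
  sign(x) * floor(abs(x) * m + 0.5) / m
}

#' Percentile by the (n + 1)p position rule
#'
#' Quantile convention used throughout the package for medians, quartiles and
#' activation thresholds: the p-th percentile sits at position p * (n + 1) in
#' the sorted sample, with linear interpolation between order statistics and
#' the position clamped to \[1, n\]. This is the convention of classical
#' survey-statistics software (type 6 in [stats::quantile()]).
#'
#' @param x Numeric vector (NAs removed).
#' @param probs Probabilities in \[0, 1\].
#' @return Numeric vector, one value per probability.
#' @export
#' @examples
#' percentile_nplus1(1:5, 0.75) # position 4.5 -> 4.5
percentile_nplus1 <- function(x, probs) {
  x <- sort(x[!is.na(x)])
  n <- length(x)
  if (n == 0L) abort("cannot take percentiles of an empty sample")
  vapply(probs, function(p) {
    h <- min(max(p * (n + 1), 1), n)
    lo <- floor(h)
    hi <- ceiling(h)
    x[lo] + (h - lo) * (x[hi] - x[lo])
  }, numeric(1))
}

# shared input check: a cohort must carry all 19 item columns
check_cohort <- function(cohort) {
  if (!is.data.frame(cohort) || nrow(cohort) == 0L) {
    abort("`cohort` must be a non-empty data frame of survey records")
  }
  missing <- setdiff(item_columns(), names(cohort))
  if (length(missing) > 0L) {
    abort(paste0("cohort is missing item columns: ",
                 paste(missing, collapse = ", ")))
  }
  invisible(cohort)
}
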
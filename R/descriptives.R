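# Demand descriptives: dimension scores, score rates, median/IQR summaries,
# P75 activation thresholds, and study-accounting utilities.

#' Per-respondent dimension demand scores
#'
#' A respondent's demand score on a dimension is the unweighted mean of that
#' dimension's items, so scores live on the same 1-5 scale as the items.
#'
#' @param cohort Cohort tibble with the 19 item columns.
#' @param dimensions Dimensions to score (default all five).
#' @return A long tibble `respondent_id`, `dimension`, `score`.
#' @export
#' @examples
#' cohort <- generate_cohort(demographic_config(n = 5, seed = 1))
#' dimension_scores(cohort)
dimension_scores <- function(cohort, dimensions = care_dimensions()) {
  check_cohort(cohort)
  check_dimension(dimensions)
  ids <- cohort$respondent_id %||% seq_len(nrow(cohort))
  purrr::map_dfr(dimensions, function(d) {
    cols <- dimension_item_columns(d)
    tibble(respondent_id = ids, dimension = d,
           score = rowMeans(as.matrix(cohort[, cols])))
  })
}

#' Cohort score rate per dimension
#'
#' The score rate expresses a dimension's aggregate demand as a percentage
#' of the scale maximum: `100 * mean dimension score / 5`, reported to two
#' decimals (half away from zero). A cohort scoring the midpoint 3
#' everywhere has a score rate of 60%.
#'
#' @inheritParams dimension_scores
#' @return A tibble `dimension`, `mean_score`, `score_rate`.
#' @export
#' @examples
#' cohort <- generate_cohort(demographic_config(n = 100, seed = 1))
#' score_rate(cohort)
score_rate <- function(cohort, dimensions = care_dimensions()) {
  dimension_scores(cohort, dimensions) |>
    summarise(mean_score = mean(.data$score), .by = "dimension") |>
    mutate(score_rate = round_half_away(100 * .data$mean_score / 5, 2))
}

#' Median and interquartile summary of dimension scores
#'
#' Medians and quartiles use the (n + 1)p position rule with linear
#' interpolation ([percentile_nplus1()]).
#'
#' @inheritParams dimension_scores
#' @return A tibble `dimension`, `n`, `p25`, `median`, `p75`.
#' @export
#' @examples
#' cohort <- generate_cohort(demographic_config(n = 100, seed = 1))
#' summarize_dimensions(cohort)
summarize_dimensions <- function(cohort, dimensions = care_dimensions()) {
  dimension_scores(cohort, dimensions) |>
    summarise(
      n = dplyr::n(),
      p25 = percentile_nplus1(.data$score, 0.25),
      median = percentile_nplus1(.data$score, 0.50),
      p75 = percentile_nplus1(.data$score, 0.75),
      .by = "dimension"
    ) |>
    select("dimension", "n", "p25", "median", "p75")
}

#' Module activation thresholds (cohort P75)
#'
#' The activation threshold of each service module is the 75th percentile of
#' the corresponding dimension's demand-score distribution over the whole
#' cohort. Individuals scoring at or above the threshold activate the
#' module ([activation_coefficient()]).
#'
#' @inheritParams dimension_scores
#' @param cohort_id Label recorded in the threshold provenance.
#' @return A tibble `module`, `threshold` with attributes `cohort_id`,
#'   `percentile_rule` and `n`.
#' @export
#' @examples
#' cohort <- generate_cohort(demographic_config(n = 331, seed = 1))
#' compute_thresholds(cohort)
compute_thresholds <- function(cohort, cohort_id = "cohort") {
  out <- summarize_dimensions(cohort) |>
    select(module = "dimension", threshold = "p75")
  attr(out, "cohort_id") <- cohort_id
  attr(out, "percentile_rule") <- "p75_position_(n+1)p_interpolated"
  attr(out, "n") <- nrow(cohort)
  out
}

#' Write or read an activation-threshold set
#'
#' Thresholds travel as JSON carrying the per-module P75 values plus
#' provenance (source cohort id, percentile rule, cohort size).
#'
#' @param thresholds Tibble from [compute_thresholds()].
#' @param path JSON file path.
#' @export
write_thresholds <- function(thresholds, path) {
  jsonlite::write_json(
    list(thresholds = setNames(as.list(thresholds$threshold),
                               thresholds$module),
         provenance = list(
           cohort_id = attr(thresholds, "cohort_id") %||% "cohort",
           percentile_rule = attr(thresholds, "percentile_rule") %||%
             "p75_position_(n+1)p_interpolated",
           n = attr(thresholds, "n"))),
    path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_thresholds
#' @export
read_thresholds <- function(path) {
  raw <- jsonlite::fromJSON(path)
  out <- tibble(module = names(raw$thresholds),
                threshold = as.numeric(unlist(raw$thresholds)))
  check_dimension(out$module)
  attr(out, "cohort_id") <- raw$provenance$cohort_id
  attr(out, "percentile_rule") <- raw$provenance$percentile_rule
  attr(out, "n") <- raw$provenance$n
  out
}

#' Required sample size for a multivariable survey instrument
#'
#' The events-per-variable rule of thumb: 5 to 10 respondents per
#' instrument variable, inflated by an attrition allowance and rounded up.
#' With 19 variables and a 20% allowance this gives 114 to 228 participants.
#'
#' @param n_vars Number of independent variables (>= 1).
#' @param multiplier_low,multiplier_high Respondents per variable.
#' @param attrition Anticipated attrition/missingness fraction in \[0, 1).
#' @return A tibble with columns `low` and `high`.
#' @export
#' @examples
#' sample_size_required(19, 5, 10, 0.20)
sample_size_required <- function(n_vars, multiplier_low = 5,
                                 multiplier_high = 10, attrition = 0.20) {
  if (n_vars < 1) abort("`n_vars` must be >= 1")
  if (attrition < 0 || attrition >= 1) abort("`attrition` must be in [0, 1)")
  if (multiplier_low > multiplier_high) {
    abort("`multiplier_low` must not exceed `multiplier_high`")
  }
  tibble(low = ceiling(n_vars * multiplier_low * (1 + attrition)),
         high = ceiling(n_vars * multiplier_high * (1 + attrition)))
}

#' Valid response rate of a survey
#'
#' @param distributed Questionnaires distributed (> 0).
#' @param valid Valid questionnaires recovered (0 <= valid <= distributed).
#' @return Percentage rounded to two decimals (half away from zero).
#' @export
#' @examples
#' response_rate(357, 331)
response_rate <- function(distributed, valid) {
  if (distributed <= 0) abort("`distributed` must be > 0")
  if (valid < 0 || valid > distributed) {
    abort("`valid` must lie between 0 and `distributed`")
  }
  round_half_away(100 * valid / distributed, 2)
}
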
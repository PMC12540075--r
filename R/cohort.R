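# Synthetic survey cohorts: seeded demographic profiles plus Likert item
# scores produced by a latent-variable model with known ground-truth effects.

# Per-respondent reproducibility scheme: respondent i uses RNG substream
# seed + i and draws, in fixed order, 8 uniforms (one per demographic
# factor) followed by 24 normals (5 shared dimension latents + 19 per-item
# noises). Profiles and scores of respondent i are therefore invariant to
# cohort size and to whether scores are generated at all.
.draw_streams <- function(n, seed) {
  u <- matrix(NA_real_, n, 8L)
  z <- matrix(NA_real_, n, 24L)
  for (i in seq_len(n)) {
    set.seed(seed + i)
    u[i, ] <- runif(8L)
    z[i, ] <- rnorm(24L)
  }
  list(u = u, z = z)
}

.profiles_from_uniforms <- function(u, config) {
  pick_band <- function(uu, probs, levels) {
    levels[findInterval(uu, cumsum(c(0, probs)), rightmost.closed = TRUE)]
  }
  spouse <- ifelse(u[, 3L] < config$p_no_spouse, "none", "yes")
  p_alone <- if (is.null(config$p_living_alone_no_spouse)) {
    rep(config$p_living_alone, nrow(u))
  } else {
    ifelse(spouse == "none", config$p_living_alone_no_spouse,
           config$p_living_alone)
  }
  tibble(
    respondent_id = seq_len(nrow(u)),
    age_band = pick_band(u[, 1L], config$age_probs,
                         .profile_levels$age_band),
    education = ifelse(u[, 2L] < config$p_high_education, "high", "low"),
    spouse = spouse,
    children = ifelse(u[, 4L] < config$p_two_plus_children, ">=2", "<=1"),
    living_alone = u[, 5L] < p_alone,
    disabled = u[, 6L] < config$p_disabled,
    chronic = u[, 7L] < config$p_chronic,
    income_band = pick_band(u[, 8L], config$income_probs,
                            .profile_levels$income_band)
  ) |> as_profile_factors()
}

#' Sample respondent demographic profiles
#'
#' Draws `config$n` profiles with independent factors at the configured
#' marginal prevalences (see [demographic_config()]). Identical seeds give
#' identical profiles, and the first `m` profiles of a size-`n` cohort equal
#' the size-`m` cohort drawn with the same seed.
#'
#' @param config A [demographic_config()].
#' @return A tibble with `respondent_id` and the eight factor columns.
#' @export
#' @examples
#' sample_profiles(demographic_config(n = 5, seed = 42))
sample_profiles <- function(config) {
  stopifnot(inherits(config, "demographic_config"))
  u <- .draw_streams(config$n, config$seed)$u
  .profiles_from_uniforms(u, config)
}

# latent dimension means for a set of profiles: intercept + sum of carried
# effects, as an n x 5 matrix
.latent_means <- function(profiles, truth) {
  dims <- care_dimensions()
  mu <- matrix(rep(truth$intercepts, each = nrow(profiles)),
               nrow(profiles), 5L, dimnames = list(NULL, dims))
  if (nrow(truth$effects) == 0L) return(mu)
  pm <- .predictor_map
  carried <- sapply(seq_len(nrow(pm)), function(j) {
    as.character(profiles[[pm$factor[j]]]) == pm$level[j]
  })
  carried <- matrix(carried, nrow = nrow(profiles))  # n x n_predictors
  E <- matrix(0, nrow(pm), 5L, dimnames = list(pm$predictor, dims))
  for (k in seq_len(nrow(truth$effects))) {
    E[truth$effects$predictor[k], truth$effects$dimension[k]] <-
      truth$effects$effect[k]
  }
  mu + carried %*% E
}

.scores_from_normals <- function(mu, z, noise_sd) {
  dims <- care_dimensions()
  latent_dim <- mu + noise_sd * z[, 1:5, drop = FALSE]
  idx <- match(.item_dimension, dims)
  item_latent <- latent_dim[, idx, drop = FALSE] +
    noise_sd * z[, 6:24, drop = FALSE]
  items <- pmin(pmax(round_half_away(item_latent), 1), 5)
  storage.mode(items) <- "integer"
  colnames(items) <- item_columns()
  colnames(latent_dim) <- paste0("latent_", dims)
  list(items = items, latent = latent_dim)
}

#' Simulate the 19 item scores of one respondent
#'
#' The latent demand of each dimension is `intercept + sum of the truth
#' effects of the profile's non-reference categories + N(0, noise_sd)`; each
#' item adds independent `N(0, noise_sd)` to its dimension's latent and is
#' rounded half-away-from-zero and clamped to \[1, 5\]. With `noise_sd = 0`
#' the scores are a deterministic function of the profile.
#'
#' @param profile A one-row data frame of demographic factors.
#' @param truth A [generator_truth()].
#' @param seed Integer seed for this respondent's draws.
#' @return Named integer vector of 19 scores in 1..5.
#' @export
#' @examples
#' p <- sample_profiles(demographic_config(n = 1, seed = 1))
#' simulate_item_scores(p, generator_truth(), seed = 99)
simulate_item_scores <- function(profile, truth, seed = 1L) {
  stopifnot(inherits(truth, "generator_truth"))
  check_profiles(profile)
  if (nrow(profile) != 1L) abort("`profile` must be a single row")
  set.seed(seed)
  z <- matrix(rnorm(24L), 1L)
  mu <- .latent_means(profile, truth)
  drop(.scores_from_normals(mu, z, truth$noise_sd)$items)
}

#' Generate a synthetic survey cohort
#'
#' Combines [sample_profiles()] and the latent-score model into a complete
#' cohort of survey records: demographic factors, the 19 item scores, and
#' the pre-rounding latent dimension scores (columns `latent_*`, kept for
#' parameter-recovery analyses; they are not part of the CSV interface).
#'
#' @inheritParams sample_profiles
#' @param truth A [generator_truth()]; defaults to the packaged reference
#'   coefficient set with `noise_sd = 0.6`.
#' @return A tibble with one row per respondent.
#' @seealso [write_cohort()], [read_cohort()]
#' @export
#' @examples
#' cohort <- generate_cohort(demographic_config(n = 10, seed = 3))
#' cohort
generate_cohort <- function(config, truth = generator_truth()) {
  stopifnot(inherits(config, "demographic_config"),
            inherits(truth, "generator_truth"))
  s <- .draw_streams(config$n, config$seed)
  profiles <- .profiles_from_uniforms(s$u, config)
  mu <- .latent_means(profiles, truth)
  sc <- .scores_from_normals(mu, s$z, truth$noise_sd)
  bind_cols(profiles, as_tibble(sc$items), as_tibble(sc$latent))
}

#' Write or read a cohort CSV
#'
#' The cohort interchange format is a UTF-8 CSV with header
#' `respondent_id, age_band, education, spouse, children, living_alone,
#' disabled, chronic, income_band, item_01..item_19`; the three boolean
#' columns are written as 0/1. Latent columns are internal and not written.
#' A write/read round trip is lossless for these columns.
#'
#' @param cohort A cohort tibble ([generate_cohort()] or compatible).
#' @param path CSV file path.
#' @return `read_cohort()` returns the cohort tibble with canonical factor
#'   levels; `write_cohort()` returns `path` invisibly.
#' @export
write_cohort <- function(cohort, path) {
  check_cohort(cohort)
  check_profiles(cohort)
  out <- cohort |>
    mutate(across(all_of(c("living_alone", "disabled", "chronic")),
                  as.integer)) |>
    select(all_of(c("respondent_id", profile_factors())),
           all_of(item_columns()))
  readr::write_csv(out, path, progress = FALSE)
  invisible(path)
}

#' @rdname write_cohort
#' @export
read_cohort <- function(path) {
  if (!file.exists(path)) abort(paste0("cohort file not found: ", path))
  df <- readr::read_csv(path, show_col_types = FALSE, progress = FALSE)
  df <- as_profile_factors(df)
  check_cohort(df)
  check_profiles(df)
  df
}
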
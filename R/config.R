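#' Demographic configuration for the synthetic cohort generator
#'
#' Defines cohort size, the master seed and the marginal prevalence of every
#' demographic factor. Defaults reproduce the study sample of 331
#' community-dwelling older adults: age bands 60-65 / 66-70 / 71-80 / >=81
#' at 108/74/110/39 of 331 (32.63/22.36/33.23/11.78%), 24.47% with senior
#' high school education or above, 28.40% without a spouse, 52.57% with two
#' or more children, 17.22% living alone, 19.64% disabled, 71.00% with
#' chronic disease, and monthly income bands 0-1500 / 1501-3000 / 3001-4999 /
#' >5000 yuan at 8.46/41.69/34.14/15.71%.
#'
#' Factors are drawn independently by default (only marginals are known). A
#' single joint-structure override is available: `p_living_alone_no_spouse`
#' replaces the living-alone prevalence among respondents without a spouse
#' (the marginal `p_living_alone` is then used for the with-spouse stratum),
#' for studies of the no-spouse x living-alone association.
#'
#' @param n Number of respondents (>= 1).
#' @param seed Master integer seed; per-respondent substreams are derived as
#'   `seed + respondent index`, so a cohort prefix is invariant to `n`.
#' @param age_probs,income_probs Probability vectors over the four age /
#'   income bands; must sum to 1.
#' @param p_high_education,p_no_spouse,p_two_plus_children,p_living_alone,p_disabled,p_chronic
#'   Marginal prevalences in \[0, 1\].
#' @param p_living_alone_no_spouse Optional conditional prevalence override
#'   (default `NULL`, i.e. independence).
#' @return An object of class `demographic_config`.
#' @export
#' @examples
#' demographic_config(n = 331, seed = 7)
demographic_config <- function(n,
                               seed = 1L,
                               age_probs = c(108, 74, 110, 39) / 331,
                               p_high_education = 81 / 331,
                               p_no_spouse = 94 / 331,
                               p_two_plus_children = 174 / 331,
                               p_living_alone = 57 / 331,
                               p_disabled = 65 / 331,
                               p_chronic = 235 / 331,
                               income_probs = c(28, 138, 113, 52) / 331,
                               p_living_alone_no_spouse = NULL) {
  if (length(n) != 1L || is.na(n) || n < 1) abort("`n` must be >= 1")
  probs <- c(p_high_education, p_no_spouse, p_two_plus_children,
             p_living_alone, p_disabled, p_chronic,
             p_living_alone_no_spouse %||% 0)
  if (any(probs < 0 | probs > 1)) abort("prevalences must lie in [0, 1]")
  for (v in list(age = age_probs, income = income_probs)) {
    if (length(v) != 4L || any(v < 0)) {
      abort("band probability vectors must have 4 non-negative entries")
    }
    if (abs(sum(v) - 1) > 1e-9) {
      abort("band probability vectors must sum to 1 (within 1e-9)")
    }
  }
  structure(
    list(n = as.integer(n), seed = as.integer(seed),
         age_probs = as.numeric(age_probs),
         p_high_education = p_high_education, p_no_spouse = p_no_spouse,
         p_two_plus_children = p_two_plus_children,
         p_living_alone = p_living_alone, p_disabled = p_disabled,
         p_chronic = p_chronic, income_probs = as.numeric(income_probs),
         p_living_alone_no_spouse = p_living_alone_no_spouse),
    class = "demographic_config"
  )
}

#' @export
print.demographic_config <- function(x, ...) {
  cat("<demographic_config> n =", x$n, ", seed =", x$seed, "\n")
  cat("  age bands:    ", paste(sprintf("%.2f%%", 100 * x$age_probs),
                                collapse = " / "), "\n")
  cat("  income bands: ", paste(sprintf("%.2f%%", 100 * x$income_probs),
                                collapse = " / "), "\n")
  cat(sprintf("  high education %.2f%%, no spouse %.2f%%, >=2 children %.2f%%\n",
              100 * x$p_high_education, 100 * x$p_no_spouse,
              100 * x$p_two_plus_children))
  cat(sprintf("  living alone %.2f%%, disabled %.2f%%, chronic %.2f%%\n",
              100 * x$p_living_alone, 100 * x$p_disabled, 100 * x$p_chronic))
  invisible(x)
}

#' Ground-truth effects for the synthetic cohort generator
#'
#' The generator draws each respondent's latent demand per dimension as
#' `intercept + sum of the B effects of the non-reference categories the
#' respondent carries + Gaussian noise`. `generator_truth()` builds that
#' truth set from a coefficient table (by default the packaged reference
#' table, i.e. the published B column and constants); `null_truth()` builds
#' a no-effect truth (all effects zero) for null simulations.
#'
#' @param coefficients Coefficient table in the [care_coefficients()] layout.
#' @param noise_sd Latent noise standard deviation, in score units on the
#'   1-5 scale (>= 0). Default 0.6, chosen so that simulated dimension
#'   medians and interquartile ranges have spread comparable to the study
#'   sample. The same sd is used for the shared dimension latent and for the
#'   independent per-item noise.
#' @param intercept For `null_truth()`: common dimension intercept.
#' @return An object of class `generator_truth`: a list with `effects`
#'   (tibble `dimension`, `predictor`, `effect`), `intercepts` (named
#'   5-vector) and `noise_sd`.
#' @export
#' @examples
#' generator_truth()
#' null_truth(intercept = 3)
generator_truth <- function(coefficients = care_coefficients(),
                            noise_sd = 0.6) {
  if (noise_sd < 0) abort("`noise_sd` must be >= 0")
  check_coefficients(coefficients)
  const <- coefficients |> filter(.data$is_constant)
  if (!setequal(const$dimension, care_dimensions())) {
    abort("truth must provide a constant for each of the five dimensions")
  }
  eff <- coefficients |>
    filter(!.data$is_constant, !.data$is_reference) |>
    select(dimension = "dimension", predictor = "predictor", effect = "B")
  structure(
    list(effects = eff,
         intercepts = setNames(const$B, const$dimension)[care_dimensions()],
         noise_sd = noise_sd),
    class = "generator_truth"
  )
}

#' @rdname generator_truth
#' @export
null_truth <- function(intercept = 3, noise_sd = 0.6) {
  if (noise_sd < 0) abort("`noise_sd` must be >= 0")
  structure(
    list(effects = tibble(dimension = character(), predictor = character(),
                          effect = numeric()),
         intercepts = setNames(rep(intercept, 5), care_dimensions()),
         noise_sd = noise_sd),
    class = "generator_truth"
  )
}

#' @export
print.generator_truth <- function(x, ...) {
  cat("<generator_truth> noise_sd =", x$noise_sd, "\n")
  cat("  intercepts:", paste(sprintf("%s=%.3f", names(x$intercepts),
                                     x$intercepts), collapse = ", "), "\n")
  cat("  ", nrow(x$effects), "non-zero effects\n")
  invisible(x)
}

#' Read a generator run configuration from YAML or JSON
#'
#' A run configuration mirrors [demographic_config()] plus the generator
#' noise under a `demographics:` mapping and an optional `noise_sd:` entry;
#' an optional `coefficients:` entry points at an alternative coefficient
#' table (path resolved relative to the configuration file).
#'
#' @param path Path to a `.yaml`/`.yml` or `.json` file.
#' @return A list with elements `config` ([demographic_config()]) and
#'   `truth` ([generator_truth()]).
#' @export
read_generator_config <- function(path) {
  raw <- if (grepl("\\.json$", path)) {
    jsonlite::fromJSON(path)
  } else {
    yaml::read_yaml(path)
  }
  dem <- raw$demographics %||% raw
  # YAML 1.1 resolves a bare `n` key to a boolean; map it back
  names(dem)[names(dem) %in% c("FALSE", "no")] <- "n"
  args <- dem[intersect(names(dem), names(formals(demographic_config)))]
  config <- do.call(demographic_config, args)
  coefs <- if (!is.null(raw$coefficients)) {
    read_coefficients(file.path(dirname(path), raw$coefficients))
  } else {
    care_coefficients()
  }
  truth <- generator_truth(coefs, noise_sd = raw$noise_sd %||% 0.6)
  list(config = config, truth = truth)
}
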
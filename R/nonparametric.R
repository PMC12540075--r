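# Univariate nonparametric screening: Mann-Whitney (two groups) and
# Kruskal-Wallis (three or more), plus the p < alpha candidate screen that
# feeds the Enter-method regression.

#' Mann-Whitney test with normal approximation (Z statistic)
#'
#' Rank-sum test for two independent groups. U is computed from pooled
#' mid-ranks; the Z statistic uses the normal approximation with the
#' tie-corrected variance and a two-sided p value. The Z is signed from
#' `group_a`'s U, so a negative Z means `group_a` ranks lower. The normal
#' approximation is used at all sample sizes, matching common
#' survey-software output; for small-sample exactness see
#' [mann_whitney_exact_p()].
#'
#' @param group_a,group_b Numeric score vectors (both non-empty).
#' @param factor,dimension Optional labels carried into the result.
#' @return A one-row tibble `factor`, `dimension`, `statistic_kind`
#'   (`"mann_whitney_z"`), `statistic`, `p_value`, `u`, `n_a`, `n_b`.
#' @export
#' @examples
#' mann_whitney_z(c(3, 3, 4, 2), c(4, 5, 5, 4))
mann_whitney_z <- function(group_a, group_b, factor = NA_character_,
                           dimension = NA_character_) {
  if (length(group_a) == 0L || length(group_b) == 0L) {
    abort("both groups must be non-empty")
  }
  na <- length(group_a); nb <- length(group_b); n <- na + nb
  r <- rank(c(group_a, group_b))
  u <- sum(r[seq_len(na)]) - na * (na + 1) / 2
  mu <- na * nb / 2
  ties <- table(c(group_a, group_b))
  tie_term <- sum(ties^3 - ties) / (n * (n - 1))
  v <- na * nb / 12 * ((n + 1) - tie_term)
  z <- if (v <= 0) 0 else (u - mu) / sqrt(v)
  p <- if (v <= 0) 1 else min(1, 2 * pnorm(-abs(z)))
  tibble(factor = factor, dimension = dimension,
         statistic_kind = "mann_whitney_z", statistic = z, p_value = p,
         u = u, n_a = na, n_b = nb)
}

#' Exact two-sided Mann-Whitney p value by enumeration
#'
#' Enumerates every assignment of the pooled mid-ranks to the two groups and
#' returns `P(|U - E[U]| >= |u_obs - E[U]|)`. Intended for small samples
#' (combined n <= 12); ties are handled through mid-ranks.
#'
#' @inheritParams mann_whitney_z
#' @return Exact two-sided p value.
#' @export
#' @examples
#' mann_whitney_exact_p(c(1, 2), c(3, 4)) # 2/6
mann_whitney_exact_p <- function(group_a, group_b) {
  na <- length(group_a); nb <- length(group_b); n <- na + nb
  if (na == 0L || nb == 0L) abort("both groups must be non-empty")
  if (n > 12L) abort("exact enumeration is limited to combined n <= 12")
  r <- rank(c(group_a, group_b))
  u_obs <- sum(r[seq_len(na)]) - na * (na + 1) / 2
  mu <- na * nb / 2
  sets <- utils::combn(n, na)
  u_all <- colSums(matrix(r[sets], nrow = na)) - na * (na + 1) / 2
  mean(abs(u_all - mu) >= abs(u_obs - mu) - 1e-12)
}

#' Kruskal-Wallis test for three or more groups
#'
#' Tie-corrected H statistic with a chi-square p value on k - 1 degrees of
#' freedom (via [stats::kruskal.test()]). For two groups use
#' [mann_whitney_z()]; asymptotically the two agree (H = Z^2).
#'
#' @param groups List of at least three non-empty numeric vectors.
#' @param factor,dimension Optional labels carried into the result.
#' @return A one-row tibble `factor`, `dimension`, `statistic_kind`
#'   (`"kruskal_wallis_h"`), `statistic`, `p_value`, `df`.
#' @export
#' @examples
#' kruskal_wallis_h(list(c(1, 2, 3), c(2, 3, 4), c(4, 5, 5)))
kruskal_wallis_h <- function(groups, factor = NA_character_,
                             dimension = NA_character_) {
  if (!is.list(groups) || length(groups) < 3L) {
    abort("`groups` must be a list of >= 3 groups; use mann_whitney_z() for 2")
  }
  if (any(lengths(groups) == 0L)) abort("all groups must be non-empty")
  if (length(unique(unlist(groups))) == 1L) {
    # all observations tied: no evidence of any shift
    return(tibble(factor = factor, dimension = dimension,
                  statistic_kind = "kruskal_wallis_h", statistic = 0,
                  p_value = 1, df = length(groups) - 1))
  }
  kt <- kruskal.test(groups)
  tibble(factor = factor, dimension = dimension,
         statistic_kind = "kruskal_wallis_h",
         statistic = unname(kt$statistic), p_value = kt$p.value,
         df = unname(kt$parameter))
}

#' Univariate screening tests across factors and dimensions
#'
#' For every (factor, dimension) pair, compares dimension demand scores
#' between the factor's groups: Mann-Whitney Z for two-level factors,
#' Kruskal-Wallis H for factors with three or more levels. Two-level
#' comparisons are signed reference-group-first (e.g. "with spouse" vs
#' "without"), so higher demand in the non-reference group gives Z < 0.
#'
#' @param cohort Cohort tibble (profiles + items).
#' @param factors Factor columns to test; default all eight.
#' @param dimensions Dimensions to test; default all five.
#' @return A tibble of test results, one row per factor x dimension.
#' @seealso [screen_candidates()]
#' @export
#' @examples
#' cohort <- generate_cohort(demographic_config(n = 200, seed = 1))
#' univariate_tests(cohort, factors = c("disabled", "age_band"))
univariate_tests <- function(cohort, factors = profile_factors(),
                             dimensions = care_dimensions()) {
  check_cohort(cohort)
  check_profiles(cohort)
  scores <- dimension_scores(cohort, dimensions)
  purrr::map_dfr(factors, function(f) {
    g <- factor(as.character(cohort[[f]]),
                levels = .factor_level_order(cohort[[f]]))
    purrr::map_dfr(dimensions, function(d) {
      s <- scores$score[scores$dimension == d]
      split_scores <- split(s, g)
      if (nlevels(g) == 2L) {
        mann_whitney_z(split_scores[[1L]], split_scores[[2L]],
                       factor = f, dimension = d) |>
          select(!any_of(c("u", "n_a", "n_b")))
      } else {
        kruskal_wallis_h(split_scores, factor = f, dimension = d) |>
          select(!any_of("df"))
      }
    })
  })
}

.factor_level_order <- function(x) {
  if (is.logical(x)) c("FALSE", "TRUE")
  else if (is.factor(x)) levels(x)
  else sort(unique(as.character(x)))
}

#' Screen candidate factors for the multivariable model
#'
#' Keeps, per dimension, the factors whose univariate p value is strictly
#' below `alpha` (the screening rule "p < 0.05": a factor at exactly
#' `alpha` is excluded).
#'
#' @param tests Test results from [univariate_tests()] (or compatible).
#' @param alpha Screening level in (0, 1); default 0.05.
#' @return A tibble `dimension`, `factor`, `p_value` of retained candidates
#'   (empty if none pass).
#' @export
#' @examples
#' cohort <- generate_cohort(demographic_config(n = 300, seed = 1))
#' univariate_tests(cohort) |> screen_candidates()
screen_candidates <- function(tests, alpha = 0.05) {
  if (alpha <= 0 || alpha >= 1) abort("`alpha` must be in (0, 1)")
  if (is.null(tests) || nrow(tests) == 0L) {
    return(tibble(dimension = character(), factor = character(),
                  p_value = numeric()))
  }
  tests |>
    summarise(p_value = min(.data$p_value),
              .by = c("dimension", "factor")) |>
    filter(.data$p_value < alpha) |>
    arrange(.data$dimension, .data$p_value) |>
    select("dimension", "factor", "p_value")
}
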
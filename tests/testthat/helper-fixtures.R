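# Shared fixture builders: tiny cohorts constructed in code.

# a cohort with specified constant profiles and a fixed item vector per row
make_cohort <- function(items, age_band = "60-65", education = "low",
                        spouse = "yes", children = "<=1",
                        living_alone = FALSE, disabled = FALSE,
                        chronic = FALSE, income_band = "0-1500") {
  items <- if (is.matrix(items)) items else matrix(items, nrow = 1)
  n <- nrow(items)
  colnames(items) <- sprintf("item_%02d", 1:19)
  dplyr::bind_cols(
    tibble::tibble(respondent_id = seq_len(n),
                   age_band = rep_len(age_band, n),
                   education = rep_len(education, n),
                   spouse = rep_len(spouse, n),
                   children = rep_len(children, n),
                   living_alone = rep_len(living_alone, n),
                   disabled = rep_len(disabled, n),
                   chronic = rep_len(chronic, n),
                   income_band = rep_len(income_band, n)),
    tibble::as_tibble(items)
  )
}

constant_cohort <- function(n, value) {
  make_cohort(matrix(value, nrow = n, ncol = 19))
}

# independent brute-force oracle for the exact two-sided Mann-Whitney p:
# walks every subset by index recursion rather than rank combinatorics
oracle_mw_exact_p <- function(x, y) {
  pooled <- c(x, y)
  r <- rank(pooled)
  na <- length(x)
  n <- length(pooled)
  mu <- na * length(y) / 2
  u_stat <- function(idx) sum(r[idx]) - na * (na + 1) / 2
  u_obs <- u_stat(seq_len(na))
  hits <- 0L; total <- 0L
  idx_sets <- utils::combn(n, na, simplify = FALSE)
  for (idx in idx_sets) {
    total <- total + 1L
    if (abs(u_stat(idx) - mu) >= abs(u_obs - mu) - 1e-12) hits <- hits + 1L
  }
  hits / total
}

# direct rank-formula H (tie-corrected), independent of kruskal.test
oracle_kw_h <- function(groups) {
  x <- unlist(groups)
  g <- rep(seq_along(groups), lengths(groups))
  n <- length(x)
  r <- rank(x)
  h <- 12 / (n * (n + 1)) *
    sum(tapply(r, g, sum)^2 / tabulate(g)) - 3 * (n + 1)
  ties <- table(x)
  h / (1 - sum(ties^3 - ties) / (n^3 - n))
}

# the reference worked example: thresholds, scores and explicit predictor
# sets per module
example_thresholds <- function() {
  tibble::tibble(module = carebundles::care_dimensions(),
                 threshold = c(3.8, 3.83, 4.0, 4.0, 4.0))
}

example_scores <- function() {
  c(life_assistance = 4.2, medical_care = 4.2, spiritual_cultural = 3.5,
    rights_protection = 3.5, age_friendly = 4.0)
}

example_predictor_sets <- function() {
  list(life_assistance = c("age_81_plus", "spouse_none", "living_alone",
                           "disabled"),
       medical_care = c("spouse_none", "living_alone", "disabled", "chronic"),
       age_friendly = c("spouse_none", "disabled"))
}
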
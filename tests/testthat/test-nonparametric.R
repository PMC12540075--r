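test_that("Mann-Whitney Z handles no-shift and degenerate inputs", {
  res <- mann_whitney_z(c(3, 3, 3), c(3, 3, 3))
  expect_equal(res$statistic, 0)
  expect_equal(res$p_value, 1)
  expect_error(mann_whitney_z(numeric(0), 1:3), "non-empty")
})

test_that("Mann-Whitney normal-approximation p agrees with wilcox.test", {
  set.seed(12)
  for (i in 1:20) {
    x <- sample(1:5, 15, TRUE) + runif(15, 0, 0.01)
    y <- sample(1:5, 25, TRUE) + runif(25, 0, 0.01)
    ours <- mann_whitney_z(x, y)
    ref <- stats::wilcox.test(x, y, exact = FALSE, correct = FALSE)
    expect_equal(ours$p_value, ref$p.value, tolerance = 1e-12)
    expect_equal(ours$u, unname(ref$statistic))
  }
  # and with heavy ties (mid-rank, tie-corrected variance path)
  x <- c(3, 3, 4, 4, 2); y <- c(4, 4, 4, 5, 5, 3)
  expect_equal(mann_whitney_z(x, y)$p_value,
               stats::wilcox.test(x, y, exact = FALSE,
                                  correct = FALSE)$p.value)
})

test_that("exact Mann-Whitney p matches enumeration oracles", {
  # U = 0 on {1,2} vs {3,4}: 2 of the 6 assignments are as extreme
  expect_equal(mann_whitney_exact_p(c(1, 2), c(3, 4)), 1 / 3)
  set.seed(7)
  for (i in 1:15) {
    x <- runif(sample(2:4, 1)); y <- runif(sample(2:4, 1))
    expect_equal(mann_whitney_exact_p(x, y), oracle_mw_exact_p(x, y))
    # no ties: also agrees with the classical exact distribution
    expect_equal(mann_whitney_exact_p(x, y),
                 stats::wilcox.test(x, y, exact = TRUE)$p.value,
                 tolerance = 1e-12)
  }
  expect_error(mann_whitney_exact_p(runif(8), runif(8)), "n <= 12")
})

test_that("upward shifts in one group move the Z statistic monotonically", {
  # every pairwise comparison flips at most once as group_b rises, so the
  # signed Z (group_a first) is non-increasing in the shift; once group_b
  # dominates, |Z| is therefore non-decreasing
  set.seed(3)
  x <- rnorm(30)
  y <- rnorm(30)
  zs <- vapply(seq(0, 3, by = 0.25), function(d) {
    mann_whitney_z(x, y + d)$statistic
  }, numeric(1))
  expect_true(all(diff(zs) <= 1e-9))
  dominated <- zs[zs <= 0]
  expect_true(all(diff(abs(dominated)) >= -1e-9))
})

test_that("Kruskal-Wallis H matches the rank-formula oracle and is rank-invariant", {
  # equal distributions: no separation
  same <- list(c(1, 2, 3), c(1, 2, 3), c(1, 2, 3))
  expect_equal(kruskal_wallis_h(same)$statistic, 0)
  expect_equal(kruskal_wallis_h(same)$p_value, 1)
  # singleton groups, checked against the direct rank formula
  singles <- list(1, 2, 3)
  expect_equal(kruskal_wallis_h(singles)$statistic, oracle_kw_h(singles))
  set.seed(9)
  for (i in 1:10) {
    g <- list(sample(1:5, 8, TRUE), sample(1:5, 6, TRUE),
              sample(1:5, 7, TRUE), sample(1:5, 5, TRUE))
    h <- kruskal_wallis_h(g)$statistic
    expect_equal(h, oracle_kw_h(g))
    # invariance under a strictly monotone transform
    g2 <- lapply(g, function(v) exp(v) + 1)
    expect_equal(kruskal_wallis_h(g2)$statistic, h)
  }
  expect_error(kruskal_wallis_h(list(1:3, 4:6)), ">= 3")
  expect_error(kruskal_wallis_h(list(1:3, 4:6, numeric(0))), "non-empty")
})

test_that("two-group H equals Z squared without ties", {
  set.seed(15)
  for (i in 1:5) {
    x <- rnorm(35); y <- rnorm(40)
    z <- mann_whitney_z(x, y)$statistic
    h <- stats::kruskal.test(list(x, y))$statistic
    expect_equal(unname(h), z^2, tolerance = 1e-6)
  }
})

test_that("the candidate screen applies strict p < alpha per dimension", {
  tests <- tibble::tibble(
    factor = c("a", "b", "c", "a"),
    dimension = c("d1", "d1", "d1", "d2"),
    statistic_kind = "mann_whitney_z", statistic = 0,
    p_value = c(0.04, 0.05, 0.8, 0.001))
  out <- screen_candidates(tests, alpha = 0.05)
  expect_equal(out$factor[out$dimension == "d1"], "a")
  expect_equal(out$factor[out$dimension == "d2"], "a")
  expect_equal(nrow(screen_candidates(tests, alpha = 0.0005)), 0)
  expect_equal(nrow(screen_candidates(tests[0, ])), 0)
  expect_error(screen_candidates(tests, alpha = 1), "\\(0, 1\\)")
})

test_that("univariate screening chooses the test by group count", {
  co <- generate_cohort(demographic_config(n = 150, seed = 5))
  tests <- univariate_tests(co)
  expect_equal(nrow(tests), 8 * 5)
  kinds <- tests |>
    dplyr::distinct(factor, statistic_kind)
  expect_equal(kinds$statistic_kind[kinds$factor == "age_band"],
               "kruskal_wallis_h")
  expect_equal(kinds$statistic_kind[kinds$factor == "income_band"],
               "kruskal_wallis_h")
  expect_true(all(kinds$statistic_kind[!kinds$factor %in%
                                         c("age_band", "income_band")] ==
                    "mann_whitney_z"))
  expect_true(all(tests$p_value >= 0 & tests$p_value <= 1))
})
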
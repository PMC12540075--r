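test_that("cohorts are deterministic, size-exact and prefix-stable", {
  cfg <- demographic_config(n = 200, seed = 42)
  a <- generate_cohort(cfg)
  b <- generate_cohort(cfg)
  expect_identical(a, b)
  expect_equal(nrow(a), 200)
  # per-respondent substreams: the first 80 rows of a larger cohort equal
  # the size-80 cohort under the same seed
  small <- generate_cohort(demographic_config(n = 80, seed = 42))
  expect_identical(a[1:80, ], small)
})

test_that("degenerate prevalences are honoured exactly", {
  none <- sample_profiles(demographic_config(n = 100, seed = 1,
                                             p_living_alone = 0))
  expect_equal(sum(none$living_alone), 0)
  all_dis <- sample_profiles(demographic_config(n = 50, seed = 1,
                                                p_disabled = 1))
  expect_equal(sum(all_dis$disabled), 50)
})

test_that("zero-noise scores are the deterministic clamp-rounded latent", {
  flat <- null_truth(intercept = 3, noise_sd = 0)
  p <- make_cohort(rep(3L, 19))
  expect_true(all(simulate_item_scores(p, flat, seed = 5) == 3L))

  high <- null_truth(intercept = 10, noise_sd = 0)
  expect_true(all(simulate_item_scores(p, high, seed = 5) == 5L))

  # disabled-only profile with the reference effect set: life-assistance
  # latent 2.789 + 0.403 = 3.192, rounding to item score 3
  truth0 <- generator_truth(noise_sd = 0)
  pd <- make_cohort(rep(3L, 19), disabled = TRUE)
  sc <- simulate_item_scores(pd, truth0, seed = 5)
  expect_true(all(sc[1:5] == 3L))
  co <- generate_cohort(demographic_config(n = 1, seed = 1), truth0)
  mu <- co$latent_life_assistance
  preds <- profile_predictors(co)[[1]]
  eff <- dplyr::filter(generator_truth()$effects,
                       dimension == "life_assistance",
                       predictor %in% preds)
  expect_equal(mu, 2.789 + sum(eff$effect))
})

test_that("all item scores stay on the 1-5 scale across random configs", {
  set.seed(99)
  for (i in 1:400) {
    cfg <- demographic_config(
      n = 5, seed = i,
      age_probs = (p <- runif(4)) / sum(p),
      p_high_education = runif(1), p_no_spouse = runif(1),
      p_two_plus_children = runif(1), p_living_alone = runif(1),
      p_disabled = runif(1), p_chronic = runif(1),
      income_probs = (q <- runif(4)) / sum(q))
    truth <- generator_truth(noise_sd = runif(1, 0, 2))
    co <- generate_cohort(cfg, truth)
    items <- as.matrix(co[, sprintf("item_%02d", 1:19)])
    expect_true(all(items >= 1 & items <= 5))
    expect_true(all(items == round(items)))
  }
})

test_that("marginal frequencies converge to configured prevalences", {
  cfg <- demographic_config(n = 10000, seed = 31)
  p <- sample_profiles(cfg)
  checks <- list(
    c(mean(p$living_alone), cfg$p_living_alone),
    c(mean(p$disabled), cfg$p_disabled),
    c(mean(p$chronic), cfg$p_chronic),
    c(mean(p$education == "high"), cfg$p_high_education),
    c(mean(p$spouse == "none"), cfg$p_no_spouse),
    c(mean(p$children == ">=2"), cfg$p_two_plus_children)
  )
  for (ch in checks) {
    tol <- 3 * sqrt(ch[2] * (1 - ch[2]) / 10000)
    expect_lt(abs(ch[1] - ch[2]), tol)
  }
  age_obs <- as.numeric(table(p$age_band)) / 10000
  expect_true(all(abs(age_obs - cfg$age_probs) <
                    3 * sqrt(cfg$age_probs * (1 - cfg$age_probs) / 10000)))
})

test_that("living-alone counts at n = 331 average to the study's 57", {
  counts <- vapply(1:300, function(s) {
    sum(sample_profiles(demographic_config(n = 331, seed = s * 1000))$living_alone)
  }, numeric(1))
  p <- 57 / 331
  se_mean <- sqrt(331 * p * (1 - p) / 300)
  expect_lt(abs(mean(counts) - 57), 3 * se_mean)
})

test_that("the conditional living-alone override shifts only the no-spouse stratum", {
  cfg <- demographic_config(n = 8000, seed = 3, p_no_spouse = 0.5,
                            p_living_alone = 0.1,
                            p_living_alone_no_spouse = 0.6)
  p <- sample_profiles(cfg)
  expect_gt(mean(p$living_alone[p$spouse == "none"]), 0.5)
  expect_lt(mean(p$living_alone[p$spouse == "yes"]), 0.15)
})

test_that("cohort CSV round trip is lossless", {
  co <- generate_cohort(demographic_config(n = 40, seed = 8))
  path <- withr::local_tempfile(fileext = ".csv")
  write_cohort(co, path)
  back <- read_cohort(path)
  keep <- c("respondent_id", profile_factors(), sprintf("item_%02d", 1:19))
  expect_equal(as.data.frame(co[, keep]), as.data.frame(back[, keep]),
               ignore_attr = TRUE)
})

test_that("invalid configurations are rejected", {
  expect_error(demographic_config(n = 0), ">= 1")
  expect_error(demographic_config(n = 10, age_probs = c(0.5, 0.5, 0.2, 0.2)),
               "sum to 1")
  expect_error(demographic_config(n = 10, p_disabled = 1.2), "\\[0, 1\\]")
  expect_error(generator_truth(noise_sd = -1), ">= 0")
  truth_missing <- generator_truth()
  truth_missing$intercepts <- truth_missing$intercepts[1:4]
  bad_tab <- dplyr::filter(care_coefficients(), dimension != "age_friendly")
  expect_error(generator_truth(bad_tab), "constant for each")
})
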
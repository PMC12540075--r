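# Enter-method dummy-coded multiple regression per demand dimension, with
# per-dummy collinearity diagnostics and the Durbin-Watson statistic.

.reference_predictors <- c(
  age_band = "age_60_65", education = "education_low", spouse = "spouse_yes",
  children = "children_le1", living_alone = "not_living_alone",
  disabled = "fully_independent", chronic = "no_chronic",
  income_band = "income_0_1500"
)

# dummy design matrix: one 0/1 column per non-reference level of the
# requested factors, in registry order
design_matrix <- function(cohort, factors) {
  check_profiles(cohort)
  bad <- setdiff(factors, profile_factors())
  if (length(bad) > 0L) {
    abort(paste0("unknown factor(s): ", paste(bad, collapse = ", ")))
  }
  pm <- .predictor_map |> filter(.data$factor %in% factors)
  X <- vapply(seq_len(nrow(pm)), function(j) {
    as.numeric(as.character(cohort[[pm$factor[j]]]) == pm$level[j])
  }, numeric(nrow(cohort)))
  X <- matrix(X, nrow = nrow(cohort),
              dimnames = list(NULL, pm$predictor))
  list(X = X, meta = pm)
}

#' Fit the Enter-method regression for one demand dimension
#'
#' Ordinary least squares of a dimension's demand score on the dummy-coded
#' demographic factors, all entered simultaneously (the "Enter" strategy: no
#' stepwise selection). Dummies are coded against the fixed reference
#' categories listed by [predictor_map()]. The fit records per-dummy
#' tolerance and VIF (from auxiliary regressions of each dummy on the
#' others) and the Durbin-Watson statistic of the residuals in input row
#' order.
#'
#' @param cohort Cohort tibble (profiles, items and - for
#'   `response = "latent"` - the generator's latent columns).
#' @param dimension One of [care_dimensions()].
#' @param factors Factor columns to enter; default all eight.
#' @param response `"score"` regresses the observed dimension score (item
#'   mean); `"latent"` regresses the generator's pre-rounding latent
#'   dimension score (parameter-recovery analyses).
#' @return An object of class `demand_fit`. Use [tidy()] for the
#'   coefficient table, [glance()] for fit summaries,
#'   [collinearity_diagnostics()] for tolerance/VIF.
#' @export
#' @examples
#' cohort <- generate_cohort(demographic_config(n = 400, seed = 1))
#' fit <- fit_enter_regression(cohort, "life_assistance",
#'                             factors = c("age_band", "disabled"))
#' tidy(fit)
#' glance(fit)
fit_enter_regression <- function(cohort, dimension,
                                 factors = profile_factors(),
                                 response = c("score", "latent")) {
  check_dimension(dimension)
  response <- match.arg(response)
  if (length(factors) == 0L) abort("at least one factor must be entered")
  d <- design_matrix(cohort, factors)
  y <- if (response == "latent") {
    col <- paste0("latent_", dimension)
    if (!col %in% names(cohort)) {
      abort(paste0("cohort has no latent column `", col, "`"))
    }
    cohort[[col]]
  } else {
    check_cohort(cohort)
    rowMeans(as.matrix(cohort[, dimension_item_columns(dimension)]))
  }
  if (nrow(d$X) <= ncol(d$X) + 1L) {
    abort("cohort size must exceed the number of dummy columns + 1")
  }
  df <- as.data.frame(d$X)
  df$.y <- y
  fit <- lm(.y ~ ., data = df)
  b <- coef(fit)
  if (anyNA(b)) {
    abort(paste0("rank-deficient design; collinear column(s): ",
                 paste(names(b)[is.na(b)], collapse = ", ")))
  }
  vt <- vif_tolerance(d$X)
  structure(
    list(dimension = dimension, response = response, lm = fit,
         meta = d$meta, X = d$X, y = y, n_used = nrow(d$X),
         durbin_watson = durbin_watson(residuals(fit)),
         vif = vt),
    class = "demand_fit"
  )
}

#' Per-dummy tolerance and variance inflation factors
#'
#' For each design column j, an auxiliary regression of column j on all
#' remaining columns gives `VIF_j = 1 / (1 - R^2_j)` and
#' `tolerance_j = 1 / VIF_j`. Each dummy is treated as a separate variable
#' (no per-factor grouping), matching how survey software reports
#' collinearity for dummy-coded models. Perfectly collinear columns are
#' reported with infinite VIF and `flagged = TRUE` rather than an error.
#'
#' @param X Numeric design matrix (columns = predictors).
#' @return A tibble `predictor`, `tolerance`, `vif`, `flagged`.
#' @export
#' @examples
#' X <- cbind(a = c(1, 0, 1, 0, 1, 0), b = c(1, 1, 0, 0, 1, 0))
#' vif_tolerance(X)
vif_tolerance <- function(X) {
  X <- as.matrix(X)
  J <- ncol(X)
  vif <- vapply(seq_len(J), function(j) {
    if (J == 1L) return(1)
    xj <- X[, j]
    others <- cbind(1, X[, -j, drop = FALSE])
    f <- stats::lm.fit(others, xj)
    tss <- sum((xj - mean(xj))^2)
    if (tss == 0) return(Inf)
    r2 <- 1 - sum(f$residuals^2) / tss
    if (r2 >= 1 - 1e-12) Inf else 1 / (1 - r2)
  }, numeric(1))
  tibble(predictor = colnames(X) %||% paste0("x", seq_len(J)),
         tolerance = 1 / vif, vif = vif, flagged = !is.finite(vif))
}

#' Durbin-Watson statistic of a residual sequence
#'
#' `sum(diff(e)^2) / sum(e^2)`, bounded in \[0, 4\]; values near 2 indicate
#' uncorrelated residuals. The sequence order is the input row order of the
#' fitted data.
#'
#' @param e Residual vector (length >= 2).
#' @return The statistic.
#' @export
durbin_watson <- function(e) {
  if (length(e) < 2L) abort("need at least two residuals")
  sum(diff(e)^2) / sum(e^2)
}

#' Collinearity and residual diagnostics of a demand fit
#'
#' @param fit A `demand_fit`.
#' @return The tolerance/VIF tibble of [vif_tolerance()] with the
#'   Durbin-Watson statistic attached as attribute `durbin_watson`.
#' @export
collinearity_diagnostics <- function(fit) {
  stopifnot(inherits(fit, "demand_fit"))
  out <- fit$vif
  attr(out, "durbin_watson") <- fit$durbin_watson
  out
}

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' Tidy coefficient table of a demand fit
#'
#' One row per model term in the layout of [care_coefficients()]: the
#' constant, every entered dummy (B, se, standardized beta, t, p,
#' tolerance, VIF) and the reference category of every entered factor
#' (`is_reference = TRUE`, B = 0, inferential fields NA).
#'
#' @param x A `demand_fit`.
#' @param ... Unused.
#' @return A tibble compatible with the bundle engine's coefficient input.
#' @export
tidy.demand_fit <- function(x, ...) {
  sm <- summary(x$lm)$coefficients
  sd_y <- sd(x$y)
  rows <- purrr::map_dfr(seq_len(nrow(x$meta)), function(j) {
    pred <- x$meta$predictor[j]
    tibble(
      dimension = x$dimension, factor = x$meta$factor[j], predictor = pred,
      B = sm[pred, 1], se = sm[pred, 2],
      beta = sm[pred, 1] * sd(x$X[, pred]) / sd_y,
      t = sm[pred, 3], p = sm[pred, 4],
      tolerance = x$vif$tolerance[x$vif$predictor == pred],
      vif = x$vif$vif[x$vif$predictor == pred],
      is_reference = FALSE, is_constant = FALSE
    )
  })
  refs <- tibble(
    dimension = x$dimension, factor = unique(x$meta$factor),
    predictor = unname(.reference_predictors[unique(x$meta$factor)]),
    B = 0, se = NA_real_, beta = NA_real_, t = NA_real_, p = NA_real_,
    tolerance = NA_real_, vif = NA_real_,
    is_reference = TRUE, is_constant = FALSE
  )
  const <- tibble(
    dimension = x$dimension, factor = "(constant)", predictor = "(constant)",
    B = sm["(Intercept)", 1], se = sm["(Intercept)", 2], beta = NA_real_,
    t = sm["(Intercept)", 3], p = sm["(Intercept)", 4],
    tolerance = NA_real_, vif = NA_real_,
    is_reference = FALSE, is_constant = TRUE
  )
  bind_rows(const, rows, refs) |>
    arrange(factor(.data$factor,
                   levels = c("(constant)", unique(x$meta$factor))),
            .data$is_reference)
}

#' Fit summaries of a demand fit
#'
#' @param x A `demand_fit`.
#' @param ... Unused.
#' @return One-row tibble: `dimension`, `r.squared`, `adj.r.squared`,
#'   `sigma`, `durbin_watson`, `n_used`, `response`.
#' @export
glance.demand_fit <- function(x, ...) {
  sm <- summary(x$lm)
  tibble(dimension = x$dimension, r.squared = sm$r.squared,
         adj.r.squared = sm$adj.r.squared, sigma = sm$sigma,
         durbin_watson = x$durbin_watson, n_used = x$n_used,
         response = x$response)
}

#' @export
print.demand_fit <- function(x, ...) {
  cat("<demand_fit>", x$dimension, "on", ncol(x$X), "dummies, n =",
      x$n_used, sprintf("(DW = %.3f)\n", x$durbin_watson))
  print(tidy(x), n = Inf)
  invisible(x)
}

#' Screen-then-fit pipeline over all demand dimensions
#'
#' Runs the univariate screen ([univariate_tests()], [screen_candidates()])
#' and fits the Enter-method regression of every dimension on its retained
#' factors. Dimensions with no factor passing the screen are skipped with a
#' message.
#'
#' @inheritParams fit_enter_regression
#' @param alpha Univariate screening level (default 0.05).
#' @return A named list of `demand_fit` objects (class `demand_fits`).
#' @seealso [coefficient_table()]
#' @export
#' @examples
#' cohort <- generate_cohort(demographic_config(n = 400, seed = 1))
#' fits <- fit_demand_models(cohort)
#' coefficient_table(fits)
fit_demand_models <- function(cohort, alpha = 0.05,
                              response = c("score", "latent")) {
  response <- match.arg(response)
  cand <- screen_candidates(univariate_tests(cohort), alpha = alpha)
  fits <- lapply(care_dimensions(), function(d) {
    f <- cand$factor[cand$dimension == d]
    if (length(f) == 0L) {
      message("no factor passed the screen for ", d, "; dimension skipped")
      return(NULL)
    }
    fit_enter_regression(cohort, d, factors = f, response = response)
  })
  names(fits) <- care_dimensions()
  structure(fits[!vapply(fits, is.null, logical(1))], class = "demand_fits")
}

#' Combined coefficient table of fitted demand models
#'
#' @param fits A `demand_fits` list from [fit_demand_models()], or a list of
#'   `demand_fit` objects.
#' @return The row-bound [tidy()] tables, in the [care_coefficients()]
#'   layout, usable directly by [build_bundles()].
#' @export
coefficient_table <- function(fits) {
  purrr::map_dfr(fits, tidy)
}
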
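# The bundle engine: binary module activation against P75 thresholds,
# coefficient-sum weighting factors, per-person service bundles, and the
# priority-tier classification.

#' Module activation coefficient
#'
#' A module is activated (coefficient 1) when the individual's dimension
#' demand score is at or above the module's threshold; equality activates.
#' Vectorized over scores/thresholds.
#'
#' @param score Dimension demand score(s) on the 1-5 scale.
#' @param threshold Activation threshold(s), typically the cohort P75.
#' @param dimension,module Optional labels; if both are given they must
#'   match, guarding against comparing a score to the wrong module's
#'   threshold.
#' @return Integer vector of 0/1 activation coefficients.
#' @export
#' @examples
#' activation_coefficient(4.2, 3.8) # 1
#' activation_coefficient(3.5, 4.0) # 0
#' activation_coefficient(4.0, 4.0) # 1 (equality activates)
activation_coefficient <- function(score, threshold, dimension = NULL,
                                   module = NULL) {
  if (!is.null(dimension) && !is.null(module) && any(dimension != module)) {
    abort("`dimension` of the score does not match `module` of the rule")
  }
  if (any(score < 1 | score > 5, na.rm = TRUE)) {
    warn("scores outside the 1-5 scale")
  }
  as.integer(score >= threshold)
}

#' Module weighting factor (sum of significant coefficients)
#'
#' The weighting factor of module k for one person is the sum of the
#' unstandardized regression coefficients (B) of the module's significant
#' predictors (p < `alpha_sig`) that the person possesses. Reference
#' categories and non-significant predictors contribute 0. The person may
#' be given either as a one-row profile (categories derived via
#' [profile_predictors()]) or as an explicit character vector of predictor
#' ids, which bypasses profile matching (useful to reproduce published
#' worked examples whose predictor sets are stated directly).
#'
#' @param who One-row profile data frame, or character vector of predictor
#'   ids (see [predictor_map()]).
#' @param module One of [care_dimensions()].
#' @param coefficients Coefficient table; default [care_coefficients()].
#' @param alpha_sig Significance level applied to the coefficient p values.
#' @return One-row tibble `module`, `beta`, `n_contributing`, plus a
#'   list-column `contributing` with the (predictor, B) pairs summed.
#' @export
#' @examples
#' weighting_factor(c("age_81_plus", "spouse_none", "living_alone",
#'                    "disabled"), "life_assistance")
weighting_factor <- function(who, module,
                             coefficients = care_coefficients(),
                             alpha_sig = 0.05) {
  check_dimension(module)
  check_coefficients(coefficients)
  preds <- if (is.character(who)) {
    who
  } else {
    profile_predictors(who)[[1L]]
  }
  pool <- coefficients |>
    filter(.data$dimension == module, !.data$is_constant,
           !.data$is_reference)
  unknown <- setdiff(preds, c(.predictor_map$predictor,
                              .reference_predictors))
  if (length(unknown) > 0L) {
    abort(paste0("unknown predictor categor(ies): ",
                 paste(unknown, collapse = ", ")))
  }
  contributing <- pool |>
    filter(.data$p < alpha_sig, .data$predictor %in% preds) |>
    select("predictor", "B")
  tibble(module = module, beta = sum(contributing$B),
         n_contributing = nrow(contributing),
         contributing = list(contributing))
}

#' Build per-person service bundles
#'
#' For every respondent and every module: the activation coefficient from
#' the dimension score against the module threshold, and the weighting
#' factor from the respondent's significant predictor categories. A
#' person's service bundle is the set of activated modules with their
#' weights (a weighted set, not a scalar: weights of unlike modules are not
#' summed). Deterministic and invariant to module order.
#'
#' @param cohort Cohort tibble (profiles + items).
#' @param thresholds Threshold tibble from [compute_thresholds()] (or
#'   [read_thresholds()]).
#' @param coefficients Coefficient table; default [care_coefficients()].
#' @param alpha_sig Significance level for the weighting factors.
#' @param predictor_sets Optional named list (names = respondent ids) of
#'   explicit predictor-id vectors that override profile matching for those
#'   respondents, e.g. to reproduce a published worked example exactly.
#' @return A tibble, one row per respondent x module: `respondent_id`,
#'   `module`, `score`, `threshold`, `alpha`, `beta`, `included`, and a
#'   list-column `contributing`. Class `service_bundles`.
#' @export
#' @examples
#' cohort <- generate_cohort(demographic_config(n = 50, seed = 1))
#' bundles <- build_bundles(cohort, compute_thresholds(cohort))
#' dplyr::filter(bundles, included)
build_bundles <- function(cohort, thresholds,
                          coefficients = care_coefficients(),
                          alpha_sig = 0.05, predictor_sets = NULL) {
  check_cohort(cohort)
  check_profiles(cohort)
  if (!all(care_dimensions() %in% thresholds$module)) {
    abort("`thresholds` must cover all five modules")
  }
  check_coefficients(coefficients)
  for (m in care_dimensions()) {
    if (!m %in% coefficients$dimension) {
      abort(paste0("`coefficients` has no rows for module ", m))
    }
  }
  ids <- cohort$respondent_id %||% seq_len(nrow(cohort))
  scores <- dimension_scores(cohort)
  pred_sets <- profile_predictors(cohort)
  names(pred_sets) <- as.character(ids)
  if (!is.null(predictor_sets)) {
    pred_sets[names(predictor_sets)] <- predictor_sets
  }
  # weighting factors depend only on (predictor set, module): compute each
  # distinct combination once
  sig <- coefficients |>
    filter(!.data$is_constant, !.data$is_reference, .data$p < alpha_sig)
  beta_for <- function(preds, module) {
    rows <- sig |>
      filter(.data$dimension == module, .data$predictor %in% preds)
    list(beta = sum(rows$B), contributing = rows |> select("predictor", "B"))
  }
  out <- scores |>
    left_join(thresholds, by = c(dimension = "module")) |>
    rename(module = "dimension") |>
    mutate(alpha = activation_coefficient(.data$score, .data$threshold))
  key <- paste(vapply(pred_sets[as.character(out$respondent_id)],
                      paste, character(1), collapse = ","),
               out$module, sep = "|")
  uniq <- !duplicated(key)
  wf <- Map(beta_for,
            pred_sets[as.character(out$respondent_id[uniq])],
            out$module[uniq])
  names(wf) <- key[uniq]
  out$beta <- vapply(wf[key], `[[`, numeric(1), "beta")
  out$contributing <- lapply(wf[key], `[[`, "contributing")
  out$included <- out$alpha == 1L
  out$beta[!out$included] <- 0
  out$contributing[!out$included] <- list(sig[0, c("predictor", "B")])
  out <- out |>
    select("respondent_id", "module", "score", "threshold", "alpha",
           "beta", "included", "contributing")
  class(out) <- c("service_bundles", class(out))
  out
}

#' Build a service bundle directly from assessed dimension scores
#'
#' Some assessments provide the five dimension demand scores directly
#' rather than item responses (as published worked examples do). Each score
#' is compared to its module threshold and the weighting factor is computed
#' from the supplied predictor set.
#'
#' @param scores Named numeric vector (names = modules) or tibble with
#'   columns `dimension`/`module` and `score`; must cover all five modules.
#' @param thresholds Threshold tibble ([compute_thresholds()] layout).
#' @param predictors Character vector of the person's predictor ids.
#' @inheritParams build_bundles
#' @param respondent_id Identifier recorded in the result.
#' @return A `service_bundles` tibble with five rows.
#' @export
#' @examples
#' th <- tibble::tibble(module = care_dimensions(),
#'                      threshold = c(3.8, 3.83, 4.0, 4.0, 4.0))
#' bundle_from_scores(c(life_assistance = 4.2, medical_care = 4.2,
#'                      spiritual_cultural = 3.5, rights_protection = 3.5,
#'                      age_friendly = 4.0),
#'                    th, c("age_81_plus", "spouse_none", "living_alone",
#'                          "disabled", "chronic"))
bundle_from_scores <- function(scores, thresholds, predictors,
                               coefficients = care_coefficients(),
                               alpha_sig = 0.05, respondent_id = 1L) {
  if (is.data.frame(scores)) {
    dim_col <- if ("module" %in% names(scores)) "module" else "dimension"
    scores <- setNames(scores$score, scores[[dim_col]])
  }
  if (!all(care_dimensions() %in% names(scores))) {
    abort("`scores` must cover all five modules")
  }
  if (!all(care_dimensions() %in% thresholds$module)) {
    abort("`thresholds` must cover all five modules")
  }
  out <- purrr::map_dfr(care_dimensions(), function(m) {
    th <- thresholds$threshold[thresholds$module == m]
    a <- activation_coefficient(scores[[m]], th)
    wf <- weighting_factor(predictors, m, coefficients, alpha_sig)
    tibble(respondent_id = respondent_id, module = m,
           score = scores[[m]], threshold = th, alpha = a,
           beta = if (a == 1L) wf$beta else 0,
           included = a == 1L,
           contributing = if (a == 1L) wf$contributing else
             list(wf$contributing[[1]][0, ]))
  })
  class(out) <- c("service_bundles", class(out))
  out
}

#' Build the service bundle of a single survey record
#'
#' @param record One-row cohort tibble.
#' @inheritParams build_bundles
#' @param predictors Optional explicit predictor-id vector overriding the
#'   record's profile.
#' @return A `service_bundles` tibble with five rows.
#' @export
build_bundle <- function(record, thresholds,
                         coefficients = care_coefficients(),
                         alpha_sig = 0.05, predictors = NULL) {
  if (nrow(record) != 1L) abort("`record` must be a single row")
  sets <- if (is.null(predictors)) NULL else {
    setNames(list(predictors),
             as.character(record$respondent_id %||% 1L))
  }
  build_bundles(record, thresholds, coefficients, alpha_sig,
                predictor_sets = sets)
}

#' Classify priority tiers
#'
#' Tier-1 priority recipients are those of advanced age (71 years or
#' older), living alone, or disabled - any one criterion suffices; everyone
#' else is standard tier. The triggering attributes are listed per person.
#'
#' @param profiles Data frame with the demographic factor columns.
#' @return A tibble `respondent_id`, `tier` (`"tier1"`/`"standard"`),
#'   `n_triggers` and list-column `triggers`.
#' @export
#' @examples
#' cohort <- generate_cohort(demographic_config(n = 10, seed = 1))
#' classify_tier(cohort)
classify_tier <- function(profiles) {
  check_profiles(profiles)
  ids <- profiles$respondent_id %||% seq_len(nrow(profiles))
  advanced <- as.character(profiles$age_band) %in% c("71-80", ">=81")
  triggers <- lapply(seq_len(nrow(profiles)), function(i) {
    c(if (advanced[i]) "advanced_age",
      if (isTRUE(profiles$living_alone[i])) "living_alone",
      if (isTRUE(profiles$disabled[i])) "disabled")
  })
  n_trig <- lengths(triggers)
  tibble(respondent_id = ids,
         tier = ifelse(n_trig > 0L, "tier1", "standard"),
         n_triggers = n_trig, triggers = triggers)
}

#' Write service bundles to JSON
#'
#' Per respondent: the priority tier (when profiles are supplied) and, per
#' module, the activation coefficient, weighting factor and contributing
#' predictors.
#'
#' @param bundles A `service_bundles` tibble.
#' @param path JSON file path.
#' @param tiers Optional tier tibble from [classify_tier()].
#' @export
write_bundles <- function(bundles, path, tiers = NULL) {
  split_b <- split(bundles, bundles$respondent_id)
  payload <- lapply(split_b, function(b) {
    mods <- lapply(seq_len(nrow(b)), function(j) {
      list(module = b$module[j], score = b$score[j],
           threshold = b$threshold[j], alpha = b$alpha[j],
           beta = b$beta[j],
           contributing = as.list(setNames(b$contributing[[j]]$B,
                                           b$contributing[[j]]$predictor)))
    })
    out <- list(respondent_id = b$respondent_id[1], modules = mods)
    if (!is.null(tiers)) {
      tr <- tiers[tiers$respondent_id == b$respondent_id[1], ]
      if (nrow(tr) == 1L) {
        out$tier <- tr$tier
        out$triggers <- as.list(tr$triggers[[1]])
      }
    }
    out
  })
  jsonlite::write_json(unname(payload), path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}
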
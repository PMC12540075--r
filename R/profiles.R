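# Canonical coding of respondent demographic profiles and the dummy
# (indicator) predictors used by the regression models and the bundle engine.

.profile_levels <- list(
  age_band    = c("60-65", "66-70", "71-80", ">=81"),
  education   = c("low", "high"),
  spouse      = c("yes", "none"),
  children    = c("<=1", ">=2"),
  income_band = c("0-1500", "1501-3000", "3001-4999", ">5000")
)

.logical_factors <- c("living_alone", "disabled", "chronic")

# non-reference dummy predictors: factor, level carried, predictor id
.predictor_map <- tibble::tribble(
  ~factor,        ~level,       ~predictor,
  "age_band",     "66-70",      "age_66_70",
  "age_band",     "71-80",      "age_71_80",
  "age_band",     ">=81",       "age_81_plus",
  "education",    "high",       "education_high",
  "spouse",       "none",       "spouse_none",
  "children",     ">=2",        "children_2plus",
  "living_alone", "TRUE",       "living_alone",
  "disabled",     "TRUE",       "disabled",
  "chronic",      "TRUE",       "chronic",
  "income_band",  "1501-3000",  "income_1501_3000",
  "income_band",  "3001-4999",  "income_3001_4999",
  "income_band",  ">5000",      "income_5000_plus"
)

#' Demographic factors and their dummy coding
#'
#' All demographic factors are coded against fixed reference categories:
#' age 60-65, education low (junior high school or below), with spouse,
#' at most one child, not living alone, fully independent (not disabled),
#' no chronic disease, income 0-1500 yuan/month. `predictor_map()` lists the
#' non-reference dummy predictors; `profile_factors()` the factor names.
#'
#' @return `predictor_map()`: a tibble with columns `factor`, `level`,
#'   `predictor`. `profile_factors()`: character vector of the eight factor
#'   column names.
#' @export
#' @examples
#' predictor_map()
predictor_map <- function() .predictor_map

#' @rdname predictor_map
#' @export
profile_factors <- function() c(names(.profile_levels)[1:4], .logical_factors,
                                "income_band")

#' Dummy predictors possessed by respondent profiles
#'
#' Maps each profile row to the set of non-reference predictor categories it
#' carries (e.g. a disabled respondent aged 83 who lives alone carries
#' `age_81_plus`, `living_alone`, `disabled`, plus whatever the remaining
#' factors contribute). Reference categories contribute nothing.
#'
#' @param profiles A data frame with the demographic columns listed by
#'   [profile_factors()].
#' @return A list (one element per row) of character vectors of predictor ids.
#' @export
#' @examples
#' cohort <- generate_cohort(demographic_config(n = 3, seed = 1))
#' profile_predictors(cohort)
profile_predictors <- function(profiles) {
  check_profiles(profiles)
  lapply(seq_len(nrow(profiles)), function(i) {
    row <- profiles[i, ]
    carried <- vapply(seq_len(nrow(.predictor_map)), function(j) {
      f <- .predictor_map$factor[j]
      lv <- .predictor_map$level[j]
      as.character(row[[f]]) == lv
    }, logical(1))
    .predictor_map$predictor[carried]
  })
}

check_profiles <- function(profiles) {
  if (!is.data.frame(profiles) || nrow(profiles) == 0L) {
    abort("`profiles` must be a non-empty data frame")
  }
  missing <- setdiff(profile_factors(), names(profiles))
  if (length(missing) > 0L) {
    abort(paste0("profiles are missing factor columns: ",
                 paste(missing, collapse = ", ")))
  }
  for (f in names(.profile_levels)) {
    bad <- setdiff(unique(as.character(profiles[[f]])), .profile_levels[[f]])
    if (length(bad) > 0L) {
      abort(paste0("invalid level(s) for ", f, ": ",
                   paste(bad, collapse = ", ")))
    }
  }
  for (f in .logical_factors) {
    if (!is.logical(profiles[[f]]) && !all(profiles[[f]] %in% c(0, 1))) {
      abort(paste0("`", f, "` must be logical (or 0/1)"))
    }
  }
  invisible(profiles)
}

as_profile_factors <- function(df) {
  for (f in names(.profile_levels)) {
    df[[f]] <- factor(as.character(df[[f]]), levels = .profile_levels[[f]])
  }
  for (f in .logical_factors) df[[f]] <- as.logical(df[[f]])
  df
}
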
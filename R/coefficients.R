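#' Packaged demand-regression coefficient table
#'
#' The reference coefficient set of the modular care model: per demand
#' dimension, the Enter-method dummy-coded multiple-regression output
#' (unstandardized B, standard error, standardized Beta, t, p, tolerance,
#' VIF) estimated from a provincial survey of 331 community-dwelling older
#' adults. Reference categories appear as rows with `is_reference = TRUE`
#' and `B = 0`; the model constant of each dimension is the row with
#' `is_constant = TRUE`. This table is both the default weighting input of
#' the bundle engine and the ground-truth effect set of the synthetic cohort
#' generator.
#'
#' @param path Optional path to an alternative coefficient CSV in the same
#'   layout; defaults to the packaged table.
#' @return A tibble with columns `dimension`, `factor`, `predictor`, `B`,
#'   `se`, `beta`, `t`, `p`, `tolerance`, `vif`, `is_reference`,
#'   `is_constant`.
#' @seealso [weighting_factor()], [generator_truth()]
#' @export
#' @examples
#' care_coefficients() |> dplyr::filter(dimension == "medical_care")
care_coefficients <- function(path = NULL) {
  path <- path %||% system.file("extdata", "demand_coefficients.csv",
                                package = "carebundles", mustWork = TRUE)
  tab <- readr::read_csv(path, show_col_types = FALSE, progress = FALSE)
  check_coefficients(tab)
  tab
}

check_coefficients <- function(tab) {
  need <- c("dimension", "factor", "predictor", "B", "p",
            "is_reference", "is_constant")
  missing <- setdiff(need, names(tab))
  if (length(missing) > 0L) {
    abort(paste0("coefficient table is missing columns: ",
                 paste(missing, collapse = ", ")))
  }
  check_dimension(unique(tab$dimension))
  if (any(tab$B[tab$is_reference] != 0)) {
    abort("reference rows must carry B = 0")
  }
  invisible(tab)
}

#' Read or write a coefficient table
#'
#' Coefficient tables move between the regression step and the bundle engine
#' as CSV or JSON; the format is chosen from the file extension.
#'
#' @param coefficients A coefficient tibble as returned by
#'   [care_coefficients()] or [coefficient_table()].
#' @param path File path ending in `.csv` or `.json`.
#' @return `read_coefficients()` returns the tibble; `write_coefficients()`
#'   returns `path` invisibly.
#' @export
write_coefficients <- function(coefficients, path) {
  check_coefficients(coefficients)
  if (grepl("\\.json$", path)) {
    jsonlite::write_json(coefficients, path, dataframe = "rows",
                         auto_unbox = TRUE, digits = NA, na = "null")
  } else {
    readr::write_csv(coefficients, path, progress = FALSE)
  }
  invisible(path)
}

#' @rdname write_coefficients
#' @export
read_coefficients <- function(path) {
  tab <- if (grepl("\\.json$", path)) {
    as_tibble(jsonlite::fromJSON(path))
  } else {
    readr::read_csv(path, show_col_types = FALSE, progress = FALSE)
  }
  check_coefficients(tab)
  tab
}
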
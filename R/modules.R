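# Registry of the five service modules / demand dimensions and the fixed
# item-to-dimension layout of the 19-item demand instrument.

.dimensions <- c("life_assistance", "medical_care", "spiritual_cultural",
                 "rights_protection", "age_friendly")

.dimension_display <- c(
  life_assistance    = "Life assistance",
  medical_care       = "Medical care",
  spiritual_cultural = "Spiritual/Cultural engagement",
  rights_protection  = "Rights protection",
  age_friendly       = "Age-friendly modifications"
)

# items 1-5 / 6-11 / 12-14 / 15-17 / 18-19 (5/6/3/3/2)
.item_dimension <- rep(.dimensions, times = c(5L, 6L, 3L, 3L, 2L))

.module_components <- list(
  life_assistance = c("Hygiene care", "Catering services",
                      "Emergency maintenance", "Entrusted agency services"),
  medical_care = c("Health management", "Preventive healthcare",
                   "Diagnosis & treatment", "Emergency rescue",
                   "Rehabilitation guidance"),
  spiritual_cultural = c("Spiritual comfort", "Leisure activities",
                         "Self-actualization"),
  rights_protection = c("Legal consultation/aid", "Policy service promotion",
                        "Conflict mediation"),
  age_friendly = c("Indoor modifications", "Public environment modifications")
)

#' The five demand dimensions / service modules
#'
#' The demand instrument measures five dimensions of community home-based
#' older adult care; each dimension maps one-to-one onto a core service
#' module of the modular care model. `care_dimensions()` returns the
#' canonical identifiers (in instrument order); `care_modules()` returns the
#' module registry with display names and core component services.
#'
#' @return `care_dimensions()`: character vector of length 5.
#'   `care_modules()`: a tibble with columns `module`, `display_name`,
#'   `n_items` and a list-column `components` of the module's core services.
#' @export
#' @examples
#' care_dimensions()
#' care_modules()
care_dimensions <- function() .dimensions

#' @rdname care_dimensions
#' @export
care_modules <- function() {
  tibble(
    module = .dimensions,
    display_name = unname(.dimension_display[.dimensions]),
    n_items = as.integer(table(factor(.item_dimension, levels = .dimensions))),
    components = unname(.module_components[.dimensions])
  )
}

#' Item-to-dimension layout of the demand instrument
#'
#' The instrument has 19 five-point Likert items grouped 5/6/3/3/2 into the
#' five demand dimensions. Items are stored in cohort tables as columns
#' `item_01` ... `item_19`.
#'
#' @return A tibble with columns `item` (column name), `index` and
#'   `dimension`.
#' @export
#' @examples
#' item_dimension_map()
item_dimension_map <- function() {
  tibble(
    item = item_columns(),
    index = 1:19,
    dimension = .item_dimension
  )
}

item_columns <- function() sprintf("item_%02d", 1:19)

dimension_item_columns <- function(dimension) {
  item_columns()[.item_dimension == dimension]
}

check_dimension <- function(dimension) {
  bad <- setdiff(dimension, .dimensions)
  if (length(bad) > 0L) {
    abort(paste0("unknown dimension(s): ", paste(bad, collapse = ", "),
                 "; expected one of ", paste(.dimensions, collapse = ", ")))
  }
  invisible(dimension)
}
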
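# Demand-Service Matching Index (DSMI) monitoring: index computation, the
# low-match recombination trigger, and the periodic re-bundling cycle.

#' Compute the Demand-Service Matching Index
#'
#' `DSMI = (actual coverage / expected coverage) * satisfaction`. All three
#' operands are fractions: actual coverage is delivered over planned service
#' units across the activated modules, expected coverage is the planned
#' demand coverage in (0, 1], and satisfaction is the mean 5-point
#' satisfaction divided by 5. The index is not clamped above 1
#' (over-delivery with high satisfaction can exceed 1); only the low side
#' matters for the trigger. Values at or below `threshold` flag the
#' observation for module recombination.
#'
#' @param delivery Data frame with columns `actual_coverage`,
#'   `expected_coverage`, `satisfaction` (and optionally `respondent_id`,
#'   `period`).
#' @param threshold Trigger threshold, default 0.8.
#' @return The input tibble plus columns `dsmi` and `triggered`.
#' @export
#' @examples
#' compute_dsmi(tibble::tibble(actual_coverage = c(0.9, 0.72),
#'                             expected_coverage = c(0.9, 0.9),
#'                             satisfaction = c(1, 0.9)))
compute_dsmi <- function(delivery, threshold = 0.8) {
  need <- c("actual_coverage", "expected_coverage", "satisfaction")
  missing <- setdiff(need, names(delivery))
  if (length(missing) > 0L) {
    abort(paste0("delivery records are missing: ",
                 paste(missing, collapse = ", ")))
  }
  if (any(delivery$expected_coverage <= 0)) {
    abort("`expected_coverage` must be > 0")
  }
  rng <- c(delivery$actual_coverage, delivery$expected_coverage,
           delivery$satisfaction)
  if (any(rng < 0 | rng > 1)) {
    abort("coverage and satisfaction must be fractions in [0, 1]")
  }
  as_tibble(delivery) |>
    mutate(dsmi = .data$actual_coverage / .data$expected_coverage *
             .data$satisfaction,
           triggered = evaluate_trigger(.data$dsmi, threshold))
}

#' Recombination trigger rule
#'
#' Module recombination is triggered when the DSMI falls at or below the
#' threshold (the boundary itself triggers).
#'
#' @param dsmi DSMI value(s).
#' @param threshold Default 0.8.
#' @return Logical vector.
#' @export
#' @examples
#' evaluate_trigger(c(0.80, 0.81)) # TRUE FALSE
evaluate_trigger <- function(dsmi, threshold = 0.8) {
  dsmi <= threshold
}

#' Run a monitoring cycle over a delivery stream
#'
#' Processes one person's delivery records period by period (at most
#' `max_iter` periods): each period's DSMI is computed and, on trigger, the
#' `rebundle` hook is invoked to revise the activated modules or their
#' weights (e.g. re-running [build_bundles()] on refreshed scores and
#' thresholds). The decision is `keep` when no period triggered and
#' `recombine` otherwise; if the period cap is reached while the last
#' period still triggers, the decision is flagged unresolved.
#'
#' @param bundle A `service_bundles` tibble for the monitored person.
#' @param delivery Delivery stream data frame (see [compute_dsmi()]),
#'   processed in row/period order.
#' @param rebundle `NULL`, or `function(bundle, delivery_row)` returning the
#'   revised bundle.
#' @param threshold Trigger threshold, default 0.8.
#' @param max_iter Maximum periods to process (>= 1).
#' @return A list of class `monitor_result`: `history` (per-period tibble
#'   with `dsmi`, `triggered`, `recombined`), `decision`
#'   (`"keep"`/`"recombine"`), `iterations`, `unresolved`, and the final
#'   `bundle`.
#' @export
#' @examples
#' stream <- tibble::tibble(period = 1:3,
#'                          actual_coverage = c(0.9, 0.7, 0.95),
#'                          expected_coverage = 0.9, satisfaction = 0.9)
#' run_monitor_cycle(NULL, stream)
run_monitor_cycle <- function(bundle, delivery, rebundle = NULL,
                              threshold = 0.8, max_iter = 10L) {
  if (max_iter < 1L) abort("`max_iter` must be >= 1")
  n <- min(nrow(delivery), max_iter)
  history <- compute_dsmi(delivery[seq_len(n), , drop = FALSE], threshold)
  history$recombined <- FALSE
  n_recomb <- 0L
  for (i in seq_len(n)) {
    if (history$triggered[i] && !is.null(rebundle)) {
      bundle <- rebundle(bundle, history[i, ])
      history$recombined[i] <- TRUE
      n_recomb <- n_recomb + 1L
    }
  }
  structure(
    list(history = history,
         decision = if (any(history$triggered)) "recombine" else "keep",
         iterations = n, n_recombinations = n_recomb,
         unresolved = n == max_iter && history$triggered[n],
         bundle = bundle),
    class = "monitor_result"
  )
}

#' @export
print.monitor_result <- function(x, ...) {
  cat("<monitor_result>", x$decision, "after", x$iterations, "period(s),",
      x$n_recombinations, "recombination(s)",
      if (x$unresolved) "[unresolved at max_iter]" else "", "\n")
  print(x$history)
  invisible(x)
}

#' Read or write service-delivery streams and DSMI histories
#'
#' Delivery streams are CSV with columns `respondent_id`, `period`,
#' `actual_coverage`, `expected_coverage`, `satisfaction`. DSMI histories
#' add `dsmi` and `triggered`.
#'
#' @param delivery,history Data frames.
#' @param path CSV file path.
#' @export
read_delivery <- function(path) {
  readr::read_csv(path, show_col_types = FALSE, progress = FALSE)
}

#' @rdname read_delivery
#' @export
write_delivery <- function(delivery, path) {
  readr::write_csv(delivery, path, progress = FALSE)
  invisible(path)
}

#' @rdname read_delivery
#' @export
write_dsmi_history <- function(history, path) {
  readr::write_csv(history, path, progress = FALSE)
  invisible(path)
}
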
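# ggplot2 displays for demand summaries, fitted models and DSMI monitoring.

#' Plot the cohort demand profile
#'
#' Median and interquartile range of each dimension's demand scores, on the
#' 1-5 instrument scale.
#'
#' @param summary Output of [summarize_dimensions()].
#' @return A ggplot object.
#' @export
#' @examples
#' cohort <- generate_cohort(demographic_config(n = 200, seed = 1))
#' plot_demand_profile(summarize_dimensions(cohort))
plot_demand_profile <- function(summary) {
  disp <- .dimension_display[summary$dimension]
  ggplot(summary, aes(x = stats::reorder(disp, .data$median),
                      y = .data$median)) +
    geom_pointrange(aes(ymin = .data$p25, ymax = .data$p75)) +
    coord_flip(ylim = c(1, 5)) +
    labs(x = NULL, y = "Demand score (median, IQR)",
         title = "Demand profile by service dimension") +
    theme_minimal()
}

#' Coefficient plot of a demand fit
#'
#' Forest-style display of the unstandardized coefficients with approximate
#' 95% intervals (B +/- 1.96 SE); reference categories are shown at zero.
#'
#' @param object A `demand_fit`.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.demand_fit <- function(object, ...) {
  td <- tidy(object) |> filter(!.data$is_constant)
  ggplot(td, aes(x = .data$B, y = .data$predictor,
                 shape = .data$is_reference)) +
    geom_vline(xintercept = 0, linetype = 2, colour = "grey60") +
    geom_pointrange(aes(xmin = .data$B - 1.96 * .data$se,
                        xmax = .data$B + 1.96 * .data$se)) +
    scale_shape_manual(values = c(`FALSE` = 16, `TRUE` = 1),
                       guide = "none") +
    labs(title = paste("Demand model:",
                       .dimension_display[object$dimension]),
         x = "Unstandardized coefficient B", y = NULL) +
    theme_minimal()
}

#' Plot a DSMI monitoring history
#'
#' DSMI per period with the recombination threshold; triggered periods are
#' highlighted.
#'
#' @param history DSMI history tibble (from [compute_dsmi()] or
#'   [run_monitor_cycle()]`$history`).
#' @param threshold Trigger threshold drawn as a reference line.
#' @return A ggplot object.
#' @export
plot_dsmi <- function(history, threshold = 0.8) {
  period <- history$period %||% seq_len(nrow(history))
  df <- mutate(as_tibble(history), period = period)
  ggplot(df, aes(x = .data$period, y = .data$dsmi)) +
    geom_hline(yintercept = threshold, linetype = 2, colour = "red") +
    geom_line() +
    geom_point(aes(colour = .data$triggered), size = 2) +
    scale_colour_manual(values = c(`FALSE` = "black", `TRUE` = "red"),
                        name = "Recombination\ntriggered") +
    labs(x = "Monitoring period", y = "DSMI",
         title = "Demand-service matching over time") +
    theme_minimal()
}
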
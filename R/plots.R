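#' Plot a discontinuity cutoff sweep
#'
#' Discontinuity coefficient with one-SE error bars for every candidate
#' cutoff; the vertical line marks the first reform-affected birth cohort
#' and the highlighted point the argmax cutoff.
#'
#' @param object A `wayfindr_rdd_sweep`.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot wayfindr_rdd_sweep
#' @export
autoplot.wayfindr_rdd_sweep <- function(object, ...) {
  d <- tidy(object)
  ggplot2::ggplot(d, ggplot2::aes(x = .data$cutoff, y = .data$estimate)) +
    ggplot2::geom_vline(xintercept = attr(object, "center_year"),
                        linetype = "dashed", colour = "grey50") +
    ggplot2::geom_hline(yintercept = 0, colour = "grey80") +
    ggplot2::geom_errorbar(
      ggplot2::aes(ymin = .data$estimate - .data$std.error,
                   ymax = .data$estimate + .data$std.error),
      width = 0.2
    ) +
    ggplot2::geom_point(ggplot2::aes(colour = .data$best), size = 2) +
    ggplot2::scale_colour_manual(values = c(`TRUE` = "firebrick",
                                            `FALSE` = "black"),
                                 guide = "none") +
    ggplot2::labs(x = "Candidate cutoff (birth year)",
                  y = "Discontinuity coefficient",
                  title = "Regression-discontinuity cutoff sweep") +
    ggplot2::theme_minimal()
}

#' Plot the pre/post regression lines at the cutoff
#'
#' Mean outcome by birth year with the two free regression lines fitted on
#' either side of the cutoff, visualizing the extrapolated gap.
#'
#' @param object A `wayfindr_gap`.
#' @param data The window cohort the gap was computed on (tibble with
#'   `birth_year` and the outcome).
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot wayfindr_gap
#' @export
autoplot.wayfindr_gap <- function(object, data, ...) {
  outcome <- object$outcome
  means <- data |>
    group_by(.data$birth_year) |>
    summarise(m = mean(.data[[outcome]]), .groups = "drop")
  pred <- function(model, years) {
    tibble(birth_year = years,
           m = predict(model, newdata = tibble(birth_year = years)))
  }
  years_pre <- seq(min(data$birth_year), object$cutoff)
  years_post <- seq(object$cutoff, max(data$birth_year))
  ggplot2::ggplot(means, ggplot2::aes(x = .data$birth_year, y = .data$m)) +
    ggplot2::geom_point() +
    ggplot2::geom_vline(xintercept = object$cutoff, linetype = "dashed",
                        colour = "grey50") +
    ggplot2::geom_line(data = pred(object$models$pre, years_pre),
                       colour = "steelblue") +
    ggplot2::geom_line(data = pred(object$models$post, years_post),
                       colour = "firebrick") +
    ggplot2::labs(x = "Birth year", y = sprintf("Mean %s", outcome),
                  title = sprintf("Gap at %d: %.3f (%.2f IQ points)",
                                  object$cutoff, object$delta,
                                  object$iq_points)) +
    ggplot2::theme_minimal()
}

#' Forest plot of per-group education slopes
#'
#' @param object A `wayfindr_slopes`.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot wayfindr_slopes
#' @export
autoplot.wayfindr_slopes <- function(object, ...) {
  d <- tidy(object) |> arrange(.data$estimate)
  d$group <- factor(d$group, levels = d$group)
  ggplot2::ggplot(d, ggplot2::aes(x = .data$estimate, y = .data$group)) +
    ggplot2::geom_vline(xintercept = 0, colour = "grey80") +
    ggplot2::geom_errorbarh(
      ggplot2::aes(xmin = .data$estimate - .data$std.error,
                   xmax = .data$estimate + .data$std.error),
      height = 0.2
    ) +
    ggplot2::geom_point() +
    ggplot2::labs(x = "Education slope (tertiary advantage)",
                  y = object$group_var,
                  title = "Education effect by group (fixed + BLUP)") +
    ggplot2::theme_minimal()
}

#' Plot the education effect size across age windows
#'
#' @param g_windows Output of [g_by_age_window()].
#' @return A ggplot object.
#' @export
plot_g_by_age <- function(g_windows) {
  ggplot2::ggplot(g_windows,
                  ggplot2::aes(x = .data$window_center, y = .data$g)) +
    ggplot2::geom_hline(yintercept = 0, colour = "grey80") +
    ggplot2::geom_ribbon(ggplot2::aes(ymin = .data$ci_low,
                                      ymax = .data$ci_high),
                         fill = "steelblue", alpha = 0.2) +
    ggplot2::geom_line(colour = "steelblue") +
    ggplot2::geom_point() +
    ggplot2::labs(x = "Age (window center, years)",
                  y = "Hedge's g (tertiary − secondary and lower)",
                  title = "Education effect size across age") +
    ggplot2::theme_minimal()
}
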
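#' Sharp regression-discontinuity fit at one cutoff
#'
#' Ordinary least squares of the outcome on birth year and a discontinuity
#' dummy: `outcome ~ 1 + (birth_year - c) + 1[birth_year >= c]`. Centering
#' birth year at the cutoff makes the dummy coefficient the size of the
#' jump at the cutoff (the uncentered form differs only in the intercept).
#' Participants born exactly in the cutoff year belong to the post side.
#'
#' @param data Tibble with `birth_year` and the outcome, already restricted
#'   to the analysis window around the reform.
#' @param cutoff Candidate cutoff year c.
#' @param outcome Name of the outcome column (default `"wf"`).
#' @return An object of class `wayfindr_rdd`: list with `cutoff`,
#'   `estimate` (the dummy coefficient), `se`, `statistic` (t), `p_value`,
#'   `n`, and the fitted `lm` in `model`.
#' @examples
#' d <- tibble::tibble(birth_year = rep(1952:1962, each = 20))
#' d$wf <- 0.02 * (d$birth_year - 1957) + 0.3 * (d$birth_year >= 1957)
#' fit_rdd(d, cutoff = 1957)
#' @export
fit_rdd <- function(data, cutoff, outcome = "wf") {
  check_columns(data, c("birth_year", outcome), "`data`")
  pre <- sum(data$birth_year < cutoff)
  post <- sum(data$birth_year >= cutoff)
  if (pre == 0 || post == 0) {
    abort(sprintf("cutoff %s leaves all data on one side", cutoff),
          class = "wayfindr_invalid_argument")
  }
  d <- tibble(
    y = data[[outcome]],
    year_c = data$birth_year - cutoff,
    post = as.numeric(data$birth_year >= cutoff)
  )
  fit <- lm(y ~ year_c + post, data = d)
  sm <- summary(fit)$coefficients
  structure(
    list(
      cutoff = cutoff,
      estimate = unname(coef(fit)["post"]),
      se = unname(sm["post", "Std. Error"]),
      statistic = unname(sm["post", "t value"]),
      p_value = unname(sm["post", "Pr(>|t|)"]),
      n = nrow(d),
      outcome = outcome,
      model = fit
    ),
    class = "wayfindr_rdd"
  )
}

#' @export
print.wayfindr_rdd <- function(x, ...) {
  cat(sprintf(
    "RDD at c = %s (%s, n = %d): jump = %.4f (SE %.4f), t = %.2f, p = %.3g\n",
    x$cutoff, x$outcome, x$n, x$estimate, x$se, x$statistic, x$p_value
  ))
  invisible(x)
}

#' Sweep regression-discontinuity cutoffs around the reform year
#'
#' Fits one sharp RDD per integer candidate cutoff in
#' `center_year +/- halfwidth`, on the cohort restricted to birth years
#' within `center_year +/- window_halfwidth`. The data window is wider than
#' the cutoff grid (twice as wide by default) so that even the extreme
#' candidate cutoffs have birth cohorts on both sides. If the reform has a
#' causal effect, the discontinuity coefficient should peak at the first
#' affected birth cohort; placing the cutoff a year off misattributes part
#' of the jump to the trend and attenuates it.
#'
#' @param data Cohort tibble with `birth_year` and the outcome.
#' @param center_year Birth year of the first potentially affected cohort
#'   (default 1957, the UK 1972 reform).
#' @param halfwidth Half-width of the cutoff grid, in years (default 5:
#'   an 11-cutoff grid over a 10-year span).
#' @param window_halfwidth Half-width of the birth-year data window
#'   (default `2 * halfwidth`).
#' @param outcome Name of the outcome column (default `"wf"`).
#' @return An object of class `wayfindr_rdd_sweep`: tibble with one row per
#'   cutoff (`cutoff`, `estimate`, `se`, `statistic`, `p_value`, `n`), with
#'   attributes `best_cutoff` (argmax of the coefficient; ties broken
#'   toward `center_year` with a warning), `center_year` and `outcome`.
#' @export
sweep_cutoffs <- function(data, center_year = 1957L, halfwidth = 5L,
                          window_halfwidth = 2L * halfwidth,
                          outcome = "wf") {
  check_columns(data, c("birth_year", outcome), "`data`")
  window <- filter(
    data,
    .data$birth_year >= center_year - window_halfwidth,
    .data$birth_year <= center_year + window_halfwidth
  )
  cutoffs <- seq(center_year - halfwidth, center_year + halfwidth)
  fits <- purrr::map(cutoffs, function(cc) {
    f <- fit_rdd(window, cutoff = cc, outcome = outcome)
    tibble(cutoff = cc, estimate = f$estimate, se = f$se,
           statistic = f$statistic, p_value = f$p_value, n = f$n)
  })
  res <- bind_rows(fits)
  best <- res$cutoff[res$estimate == max(res$estimate)]
  if (length(best) > 1) {
    warn(sprintf("tied maximal discontinuity at cutoffs %s; choosing the one nearest %d",
                 paste(best, collapse = ", "), center_year))
    best <- best[which.min(abs(best - center_year))]
  }
  attr(res, "best_cutoff") <- best
  attr(res, "center_year") <- center_year
  attr(res, "outcome") <- outcome
  class(res) <- c("wayfindr_rdd_sweep", class(res))
  res
}

#' Pre/post regression gap at the cutoff
#'
#' Fits two free regression lines of the outcome on birth year — one on
#' participants born before the cutoff, one on those born in or after it —
#' and evaluates both at the cutoff. The gap `delta = post - pre` is the
#' discontinuity as seen by the two-line (separate-slopes) description; the
#' single-slope model of [fit_rdd()] is the formal test. The gap is also
#' rescaled to IQ-point units: `delta / SD(outcome) * 15`, i.e. the jump
#' expressed on a standard IQ scale (mean 100, SD 15). By default the SD
#' is computed on the window cohort passed in; supply `sd_outcome` to use
#' a whole-cohort SD instead.
#'
#' @param data Window cohort tibble with `birth_year` and the outcome.
#' @param cutoff Cutoff year.
#' @param outcome Name of the outcome column (default `"wf"`).
#' @param sd_outcome Optional SD used for the IQ rescaling; default
#'   `sd(data[[outcome]])`.
#' @return An object of class `wayfindr_gap`: list with `delta`,
#'   `pre_value`, `post_value`, their 95% CIs (`pre_ci`, `post_ci`),
#'   `iq_points`, `sd_outcome`, `n_pre`, `n_post`, `cutoff`.
#' @export
pre_post_gap <- function(data, cutoff, outcome = "wf", sd_outcome = NULL) {
  check_columns(data, c("birth_year", outcome), "`data`")
  pre <- filter(data, .data$birth_year < cutoff)
  post <- filter(data, .data$birth_year >= cutoff)
  if (nrow(pre) < 3 || nrow(post) < 3 ||
      n_distinct(pre$birth_year) < 2 || n_distinct(post$birth_year) < 2) {
    abort("each side of the cutoff needs at least 3 participants over at least 2 birth years",
          class = "wayfindr_invalid_argument")
  }
  line_at_cutoff <- function(d) {
    fit <- lm(stats::reformulate("birth_year", response = outcome), data = d)
    pr <- predict(fit, newdata = tibble(birth_year = cutoff), se.fit = TRUE)
    z <- qnorm(0.975)
    list(value = unname(pr$fit), ci = unname(pr$fit + c(-z, z) * pr$se.fit),
         model = fit)
  }
  lo <- line_at_cutoff(pre)
  hi <- line_at_cutoff(post)
  sd_out <- sd_outcome %||% sd(data[[outcome]])
  delta <- hi$value - lo$value
  structure(
    list(
      cutoff = cutoff,
      pre_value = lo$value, pre_ci = lo$ci,
      post_value = hi$value, post_ci = hi$ci,
      delta = delta,
      sd_outcome = sd_out,
      iq_points = iq_rescale(delta, sd_out),
      n_pre = nrow(pre), n_post = nrow(post),
      outcome = outcome,
      models = list(pre = lo$model, post = hi$model)
    ),
    class = "wayfindr_gap"
  )
}

#' @export
print.wayfindr_gap <- function(x, ...) {
  cat(sprintf(
    paste0("Pre/post gap at %s (%s): pre %.3f [%.3f, %.3f], ",
           "post %.3f [%.3f, %.3f]\n  delta = %.4f  (%.2f IQ points at SD %.3f); ",
           "n = %d + %d\n"),
    x$cutoff, x$outcome, x$pre_value, x$pre_ci[1], x$pre_ci[2],
    x$post_value, x$post_ci[1], x$post_ci[2],
    x$delta, x$iq_points, x$sd_outcome, x$n_pre, x$n_post
  ))
  invisible(x)
}

#' Rescale an outcome gap to IQ-point units
#'
#' Divides a gap by the outcome's standard deviation and multiplies by 15,
#' expressing the effect on the standard IQ scale (mean 100, SD 15). Linear
#' in the gap and inversely proportional to the SD.
#'
#' @param delta Gap in outcome units.
#' @param sd_outcome Standard deviation of the outcome (> 0).
#' @param iq_sd SD of the reference IQ scale (default 15).
#' @return The gap in IQ points.
#' @examples
#' iq_rescale(0.06, 1.125)  # 0.8
#' @export
iq_rescale <- function(delta, sd_outcome, iq_sd = 15) {
  if (any(sd_outcome <= 0)) {
    abort("`sd_outcome` must be positive", class = "wayfindr_invalid_argument")
  }
  delta / sd_outcome * iq_sd
}

#' Placebo discontinuity sweep on training performance
#'
#' Repeats the cutoff sweep with the motor-control training score as the
#' outcome. Education should not affect pure motor skill, so a discontinuity
#' appearing here would indicate a spurious cohort artifact rather than a
#' causal education effect.
#'
#' @param data Cohort tibble with `birth_year` and the training score.
#' @param center_year,halfwidth,window_halfwidth As in [sweep_cutoffs()].
#' @param outcome Name of the training-score column (default `"tp"`).
#' @return A `wayfindr_rdd_sweep` with an extra attribute `summary`:
#'   one-row tibble with the maximal coefficient and its `statistic` and
#'   `p_value`.
#' @export
placebo_rdd <- function(data, center_year = 1957L, halfwidth = 5L,
                        window_halfwidth = 2L * halfwidth,
                        outcome = "tp") {
  check_columns(data, c("birth_year", outcome), "`data`")
  if (nrow(data) == 0 || all(is.na(data[[outcome]]))) {
    abort("no training scores available for the placebo analysis",
          class = "wayfindr_data_error")
  }
  res <- sweep_cutoffs(data, center_year = center_year,
                       halfwidth = halfwidth,
                       window_halfwidth = window_halfwidth,
                       outcome = outcome)
  i <- which.max(res$estimate)
  attr(res, "summary") <- tibble(
    max_estimate = res$estimate[i], cutoff = res$cutoff[i],
    statistic = res$statistic[i], p_value = res$p_value[i]
  )
  res
}
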
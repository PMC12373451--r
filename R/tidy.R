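#' Tidy a single regression-discontinuity fit
#'
#' @param x A `wayfindr_rdd` object.
#' @param ... Unused.
#' @return A one-row tibble with broom-style columns `term`, `estimate`,
#'   `std.error`, `statistic`, `p.value`, plus `cutoff` and `n`.
#' @method tidy wayfindr_rdd
#' @export
tidy.wayfindr_rdd <- function(x, ...) {
  tibble(
    term = "discontinuity",
    estimate = x$estimate,
    std.error = x$se,
    statistic = x$statistic,
    p.value = x$p_value,
    cutoff = x$cutoff,
    n = x$n
  )
}

#' @rdname tidy.wayfindr_rdd
#' @method glance wayfindr_rdd
#' @export
glance.wayfindr_rdd <- function(x, ...) {
  sm <- summary(x$model)
  tibble(
    cutoff = x$cutoff,
    n = x$n,
    r.squared = sm$r.squared,
    sigma = sm$sigma,
    outcome = x$outcome
  )
}

#' Tidy a cutoff sweep
#'
#' @param x A `wayfindr_rdd_sweep` object.
#' @param ... Unused.
#' @return A tibble with one row per candidate cutoff (`cutoff`, `estimate`,
#'   `std.error`, `statistic`, `p.value`, `n`, `best` flag).
#' @method tidy wayfindr_rdd_sweep
#' @export
tidy.wayfindr_rdd_sweep <- function(x, ...) {
  tibble(
    cutoff = x$cutoff,
    estimate = x$estimate,
    std.error = x$se,
    statistic = x$statistic,
    p.value = x$p_value,
    n = x$n,
    best = x$cutoff == attr(x, "best_cutoff")
  )
}

#' @rdname tidy.wayfindr_rdd_sweep
#' @method glance wayfindr_rdd_sweep
#' @export
glance.wayfindr_rdd_sweep <- function(x, ...) {
  i <- which(x$cutoff == attr(x, "best_cutoff"))
  tibble(
    best_cutoff = attr(x, "best_cutoff"),
    center_year = attr(x, "center_year"),
    max_estimate = x$estimate[i],
    statistic = x$statistic[i],
    p.value = x$p_value[i],
    outcome = attr(x, "outcome")
  )
}

#' Tidy a random-slope education model
#'
#' @param x A `wayfindr_slopes` object.
#' @param effects `"random"` (default: per-group total education slopes,
#'   fixed + BLUP) or `"fixed"`.
#' @param ... Unused.
#' @return A tibble of estimates with `std.error`.
#' @method tidy wayfindr_slopes
#' @export
tidy.wayfindr_slopes <- function(x, effects = c("random", "fixed"), ...) {
  effects <- match.arg(effects)
  if (effects == "fixed") {
    return(rename(x$fixed, estimate = "estimate", std.error = "se"))
  }
  out <- x$slopes
  names(out) <- c("group", "estimate", "std.error")
  out
}

#' @rdname tidy.wayfindr_slopes
#' @method glance wayfindr_slopes
#' @export
glance.wayfindr_slopes <- function(x, ...) {
  tibble(
    slope_sd = x$slope_sd,
    singular = x$singular,
    logLik = as.numeric(stats::logLik(x$model)),
    AIC = stats::AIC(x$model),
    n = stats::nobs(x$model),
    n_groups = nrow(x$slopes)
  )
}

#' Tidy a pre/post gap estimate
#'
#' @param x A `wayfindr_gap` object.
#' @param ... Unused.
#' @return A tibble with rows `pre`, `post` and `delta`; the `delta` row
#'   carries the IQ-point rescaling in `iq_points`.
#' @method tidy wayfindr_gap
#' @export
tidy.wayfindr_gap <- function(x, ...) {
  tibble(
    side = c("pre", "post", "delta"),
    estimate = c(x$pre_value, x$post_value, x$delta),
    conf.low = c(x$pre_ci[1], x$post_ci[1], NA),
    conf.high = c(x$pre_ci[2], x$post_ci[2], NA),
    n = c(x$n_pre, x$n_post, x$n_pre + x$n_post),
    iq_points = c(NA, NA, x$iq_points)
  )
}

#' Tidy an F-test table
#'
#' @param x A `wayfindr_anova` object.
#' @param ... Unused.
#' @return The term table with broom-style names (`term`, `statistic`,
#'   `df`, `df.residual`, `p.value`).
#' @method tidy wayfindr_anova
#' @export
tidy.wayfindr_anova <- function(x, ...) {
  tibble(
    term = x$term,
    statistic = x$statistic,
    df = x$df,
    df.residual = x$df_residual,
    p.value = x$p_value
  )
}
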
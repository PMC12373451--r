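#' Hedge's g with confidence interval
#'
#' Bias-corrected standardized mean difference between two groups,
#' `g = J * (mean(a) - mean(b)) / s_pooled` with small-sample correction
#' `J = 1 - 3 / (4 (n1 + n2 - 2) - 1)`. The default confidence interval is
#' the normal approximation with
#' `SE^2 = (n1 + n2) / (n1 n2) + g^2 / (2 (n1 + n2 - 2))`; an exact
#' noncentral-t interval is available behind `ci_method`.
#'
#' Positive g means the first group's mean exceeds the second's; in the
#' package's analyses the first group is the tertiary-education class, so
#' positive g is a tertiary advantage.
#'
#' @param group_a,group_b Numeric outcome vectors (each length >= 2).
#' @param conf_level Confidence level (default 0.95).
#' @param ci_method `"normal"` (default) or `"noncentral_t"`.
#' @return A one-row tibble of class `wayfindr_effect`: `g`, `se`, `ci_low`,
#'   `ci_high`, `n1`, `n2`.
#' @examples
#' hedges_g(rnorm(50, 0.3), rnorm(50))
#' @export
hedges_g <- function(group_a, group_b, conf_level = 0.95,
                     ci_method = c("normal", "noncentral_t")) {
  ci_method <- match.arg(ci_method)
  a <- group_a[is.finite(group_a)]
  b <- group_b[is.finite(group_b)]
  n1 <- as.numeric(length(a))
  n2 <- as.numeric(length(b))
  if (n1 < 2 || n2 < 2) {
    abort("both groups need at least 2 finite observations",
          class = "wayfindr_invalid_argument")
  }
  df <- n1 + n2 - 2
  s_pooled <- sqrt(((n1 - 1) * var(a) + (n2 - 1) * var(b)) / df)
  if (s_pooled == 0) {
    abort("pooled standard deviation is zero: effect size undefined",
          class = "wayfindr_degenerate_input")
  }
  j <- 1 - 3 / (4 * df - 1)
  g <- j * (mean(a) - mean(b)) / s_pooled
  se <- sqrt((n1 + n2) / (n1 * n2) + g^2 / (2 * df))

  if (ci_method == "normal") {
    z <- qnorm(1 - (1 - conf_level) / 2)
    ci <- c(g - z * se, g + z * se)
  } else {
    # exact CI: invert the noncentral-t distribution of the t statistic
    t_obs <- (mean(a) - mean(b)) / (s_pooled * sqrt(1 / n1 + 1 / n2))
    scale <- sqrt(1 / n1 + 1 / n2)
    alpha <- (1 - conf_level) / 2
    ncp_bound <- function(p) {
      # pt() with large noncentrality emits precision warnings far beyond
      # the accuracy the interval needs
      f <- function(ncp) suppressWarnings(pt(t_obs, df, ncp = ncp)) - p
      lo <- t_obs - 10 * (1 + abs(t_obs))
      hi <- t_obs + 10 * (1 + abs(t_obs))
      stats::uniroot(f, c(lo, hi), extendInt = "downX")$root
    }
    ci <- sort(j * scale * c(ncp_bound(1 - alpha), ncp_bound(alpha)))
  }

  structure(
    tibble(g = g, se = se, ci_low = ci[1], ci_high = ci[2],
           n1 = n1, n2 = n2),
    class = c("wayfindr_effect", class(tibble())))
}

#' Education effect size in age windows
#'
#' Partitions age into consecutive left-closed windows `[a, a + width)`
#' anchored at the cohort minimum age, and computes Hedge's g for tertiary
#' versus secondary-and-lower education within each window. Windows where
#' either class has fewer than 2 members are omitted (with a message).
#' A rising profile of g over the window centers indicates an education
#' effect that grows with age.
#'
#' @param data Cohort tibble with `age`, `education2` and the outcome.
#' @param outcome Name of the outcome column (default `"wf"`).
#' @param window_width Window width in years (default 5).
#' @param ... Passed to [hedges_g()].
#' @return A tibble with one row per retained window: `window_center`,
#'   `window_low`, `g`, `se`, `ci_low`, `ci_high`, `n1`, `n2`.
#' @export
g_by_age_window <- function(data, outcome = "wf", window_width = 5, ...) {
  check_columns(data, c("age", "education2", outcome), "`data`")
  a0 <- min(data$age)
  data <- mutate(
    data,
    .window = a0 + window_width * floor((.data$age - a0) / window_width)
  )
  windows <- sort(unique(data$.window))
  rows <- purrr::map(windows, function(w) {
    d <- filter(data, .data$.window == w)
    ter <- d[[outcome]][d$education2 == "tertiary"]
    sec <- d[[outcome]][d$education2 == "secondary_and_lower"]
    if (length(ter) < 2 || length(sec) < 2) {
      return(NULL)
    }
    eff <- hedges_g(ter, sec, ...)
    bind_cols(tibble(window_center = w + window_width / 2, window_low = w),
              eff)
  })
  dropped <- sum(purrr::map_lgl(rows, is.null))
  if (dropped > 0) {
    inform(sprintf(
      "g_by_age_window: omitted %d window(s) with fewer than 2 per class",
      dropped
    ))
  }
  bind_rows(rows)
}

anova_to_tibble <- function(tab, df_res) {
  terms <- rownames(tab)
  keep <- !terms %in% c("Residuals", "(Intercept)")
  tibble(
    term = terms[keep],
    statistic = tab[keep, "F value"],
    df = tab[keep, "Df"],
    df_residual = df_res,
    p_value = tab[keep, "Pr(>F)"]
  )
}

#' ANOVA of the factorial age/gender/education model
#'
#' Fits the ordinary least-squares model `wf ~ age * gender * education2`
#' (continuous age, binary gender and merged education, all interactions)
#' and summarizes each term with an F test. Type II sums of squares are the
#' default — each main effect is tested after the other main effects,
#' without depending on term order; classical sequential (Type I) tests are
#' available for comparison.
#'
#' @param data Cohort tibble with `age`, `gender`, `education2` and the
#'   outcome.
#' @param outcome Name of the outcome column (default `"wf"`).
#' @param rhs One-sided formula for the model right-hand side; default
#'   `~ age * gender * education2`.
#' @param type `"II"` (default) or `"I"` sums of squares.
#' @return A tibble of class `wayfindr_anova`: `term`, `statistic` (F),
#'   `df`, `df_residual`, `p_value`, with the fitted `lm` in attribute
#'   `model`. A zero-variance outcome yields NaN statistics and a warning.
#' @export
anova_main_effects <- function(data, outcome = "wf",
                               rhs = ~ age * gender * education2,
                               type = c("II", "I")) {
  type <- match.arg(type)
  vars <- all.vars(rhs)
  check_columns(data, c(vars, outcome), "`data`")
  f <- stats::reformulate(attr(stats::terms(rhs), "term.labels"),
                          response = outcome)
  fit <- lm(f, data = data)
  if (any(is.na(coef(fit)))) {
    abort("model matrix is rank deficient: singular fit",
          class = "wayfindr_singular_fit")
  }
  if (var(data[[outcome]]) == 0) {
    warn("outcome has zero variance: F statistics are undefined")
    labels <- attr(stats::terms(f), "term.labels")
    res <- tibble(term = labels, statistic = NaN,
                  df = NA_real_, df_residual = fit$df.residual,
                  p_value = NaN)
    attr(res, "model") <- fit
    class(res) <- c("wayfindr_anova", class(res))
    return(res)
  }
  tab <- if (type == "II") {
    as.data.frame(car::Anova(fit, type = 2))
  } else {
    out <- as.data.frame(stats::anova(fit))
    names(out)[names(out) == "F value"] <- "F value"
    out
  }
  names(tab)[names(tab) == "F value"] <- "F value"
  res <- anova_to_tibble(as.matrix(tab[, c("Df", "F value", "Pr(>F)")]),
                         df_res = fit$df.residual)
  attr(res, "model") <- fit
  class(res) <- c("wayfindr_anova", class(res))
  res
}

#' Fixed-effects education-by-country interaction model
#'
#' The "classic" fixed-effects counterpart of the random-slope model:
#' ordinary least squares of the outcome on age, gender, country
#' (categorical) and the education-by-country interaction, summarized with
#' Type II F tests. A significant interaction term indicates that the
#' education effect differs across countries.
#'
#' @param data Cohort tibble with `age`, `gender`, `education2`, `country`
#'   and the outcome; at least 2 countries.
#' @param outcome Name of the outcome column (default `"wf"`).
#' @return A tibble of class `wayfindr_anova` (see [anova_main_effects()]);
#'   the per-country education effects implied by the fixed model are in
#'   attribute `country_effects` (tibble `country`, `slope`, `se`).
#' @export
fixed_interaction_model <- function(data, outcome = "wf") {
  check_columns(data, c("age", "gender", "education2", "country", outcome),
                "`data`")
  if (n_distinct(data$country) < 2) {
    abort("need at least 2 countries for the interaction model",
          class = "wayfindr_invalid_argument")
  }
  data <- mutate(data, country = factor(.data$country))
  f <- stats::reformulate("age + gender + education2 * country",
                          response = outcome)
  fit <- lm(f, data = data)
  tab <- as.data.frame(car::Anova(fit, type = 2))
  res <- anova_to_tibble(as.matrix(tab[, c("Df", "F value", "Pr(>F)")]),
                         df_res = fit$df.residual)

  # per-country education slope implied by the fixed model: base education
  # coefficient plus the country's interaction contrast
  cts <- levels(data$country)
  beta <- coef(fit)
  V <- vcov(fit)
  base <- "education2tertiary"
  eff <- purrr::map_dfr(cts, function(ct) {
    inter <- paste0("education2tertiary:country", ct)
    idx <- c(base, if (inter %in% names(beta)) inter)
    w <- setNames(rep(1, length(idx)), idx)
    est <- sum(beta[idx])
    se <- sqrt(drop(t(w) %*% V[idx, idx, drop = FALSE] %*% w))
    tibble(country = ct, slope = est, se = se)
  })
  attr(res, "model") <- fit
  attr(res, "country_effects") <- eff
  class(res) <- c("wayfindr_anova", class(res))
  res
}

#' Correlate group-level effect estimates with a group indicator
#'
#' Pearson correlation between per-group education slopes (e.g. by country
#' or by level) and an external group-level indicator (e.g. GDP per capita,
#' or level difficulty), with the two-sided p-value from the t transform on
#' n - 2 degrees of freedom.
#'
#' @param slopes Tibble with a group column and a `slope` column (e.g. the
#'   `slopes` element of [fit_education_slopes()]).
#' @param indicator Tibble with the same group column and a `value` column.
#' @param by Name of the group column shared by both tables (default
#'   `"group"`).
#' @return A one-row tibble: `r`, `p_value`, `n` (matched groups).
#' @export
correlate_slopes_with_indicator <- function(slopes, indicator, by = "group") {
  check_columns(slopes, c(by, "slope"), "`slopes`")
  check_columns(indicator, c(by, "value"), "`indicator`")
  merged <- inner_join(slopes, indicator, by = by)
  if (nrow(merged) < 3) {
    abort("need at least 3 matched groups",
          class = "wayfindr_invalid_argument")
  }
  if (var(merged$value) == 0 || var(merged$slope) == 0) {
    abort("constant slopes or indicator: correlation undefined",
          class = "wayfindr_degenerate_input")
  }
  ct <- stats::cor.test(merged$slope, merged$value, method = "pearson")
  tibble(r = unname(ct$estimate), p_value = ct$p.value, n = nrow(merged))
}
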
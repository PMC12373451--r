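#' Random-slope mixed model for the education effect
#'
#' Fits a linear mixed model of the outcome on fixed age, gender and
#' education effects, with a random intercept and a random education slope
#' per group (country or level): in shorthand,
#' `outcome ~ age + gender + education + (1 + education | group)`.
#' Estimation is by maximum likelihood (not REML), with an unstructured
#' 2x2 random-effect covariance. The per-group education effect reported is
#' the fixed education coefficient plus the group's predicted (BLUP) slope
#' deviation; its standard error combines the fixed coefficient's sampling
#' variance with the conditional variance of the BLUP (an approximation
#' that ignores their covariance).
#'
#' @param data Tibble with the outcome, `education2`, the grouping column,
#'   and the fixed covariates.
#' @param outcome Name of the outcome column (default `"wf"`).
#' @param group Name of the grouping column (e.g. `"country"` or
#'   `"level_id"`).
#' @param covariates Character vector of fixed covariates (default
#'   `c("age", "gender")`).
#' @return An object of class `wayfindr_slopes`: a list with `slopes`
#'   (tibble `group`, `slope`, `se`), `fixed` (tibble of fixed effects),
#'   `slope_sd` (estimated SD of the random education slopes), `singular`
#'   (logical) and the fitted `merMod` in `model`.
#' @examples
#' \donttest{
#' d <- simulate_cohort(generator_config(n_participants = 2000, seed = 5))
#' sc <- score_cohort(
#'   dplyr::mutate(d$participants, education2 = merge_education(education4)),
#'   d$trajectories, d$levels
#' )
#' fit_education_slopes(sc, group = "country")
#' }
#' @export
fit_education_slopes <- function(data, outcome = "wf", group = "country",
                                 covariates = c("age", "gender")) {
  check_columns(data, c(outcome, "education2", group, covariates), "`data`")
  data$.group <- factor(data[[group]])
  if (nlevels(data$.group) < 3) {
    abort("need at least 3 groups for a random-slope model",
          class = "wayfindr_invalid_argument")
  }
  both <- data |>
    group_by(.data$.group) |>
    summarise(ok = n_distinct(.data$education2) == 2, .groups = "drop")
  if (!all(both$ok)) {
    abort(
      sprintf("both education classes must be present in every group (missing in: %s)",
              paste(both$.group[!both$ok], collapse = ", ")),
      class = "wayfindr_invalid_argument"
    )
  }

  f <- stats::reformulate(
    c(covariates, "education2", "(1 + education2 | .group)"),
    response = outcome
  )
  fit <- withCallingHandlers(
    lme4::lmer(f, data = data, REML = FALSE,
               control = lme4::lmerControl(calc.derivs = FALSE)),
    message = function(m) invokeRestart("muffleMessage")
  )
  if (lme4::isSingular(fit)) {
    warn("random-effect covariance is singular; fit retained")
  }
  conv <- fit@optinfo$conv$lme4
  if (!is.null(conv$code) && conv$code < 0) {
    abort(
      paste0("mixed model failed to converge: ",
             paste(unlist(conv$messages), collapse = "; ")),
      class = "wayfindr_fit_error"
    )
  }

  fe <- lme4::fixef(fit)
  fe_se <- sqrt(diag(as.matrix(vcov(fit))))
  edu_term <- "education2tertiary"
  re <- lme4::ranef(fit, condVar = TRUE)$.group
  pv <- attr(re, "postVar")  # 2x2 conditional covariance per group
  slope_dev <- re[[edu_term]]
  slope_condvar <- pv[2, 2, ]

  slopes <- tibble(
    group = rownames(re),
    slope = unname(fe[edu_term] + slope_dev),
    se = sqrt(fe_se[edu_term]^2 + slope_condvar)
  )
  names(slopes)[1] <- group

  vc <- as.data.frame(lme4::VarCorr(fit))
  slope_sd <- vc$sdcor[vc$grp == ".group" & vc$var1 == edu_term &
                         is.na(vc$var2)]

  structure(
    list(
      slopes = slopes,
      fixed = tibble(term = names(fe), estimate = unname(fe),
                     se = fe_se),
      slope_sd = slope_sd,
      singular = lme4::isSingular(fit),
      group_var = group,
      outcome = outcome,
      model = fit
    ),
    class = "wayfindr_slopes"
  )
}

#' @export
print.wayfindr_slopes <- function(x, ...) {
  cat(sprintf(
    "Random-slope education model (ML): %s ~ ... + (1 + education2 | %s)\n",
    x$outcome, x$group_var
  ))
  cat(sprintf("Random slope SD: %.4f%s\n", x$slope_sd,
              if (x$singular) "  [singular fit]" else ""))
  print(x$slopes, ...)
  invisible(x)
}

#' Per-level outcomes for the difficulty analysis
#'
#' Builds the long table used to model the education effect by level:
#' one row per participant and wayfinding level, with outcome the negated
#' tutorial-normalized trajectory length (so larger = better, and a
#' positive education slope is a tertiary advantage). The per-level scale
#' is deliberately not standardized: harder levels stretch trajectories
#' more, and that scale difference is exactly the difficulty modulation
#' the level-clustered model measures.
#'
#' @param participants Participant tibble (with demographics).
#' @param trajectories Trajectory tibble.
#' @param levels Level catalog.
#' @return A long tibble: demographics plus `level_id` and `outcome`.
#' @export
level_outcomes <- function(participants, trajectories, levels) {
  tutorial_ids <- levels$level_id[levels$is_tutorial]
  wf_ids <- levels$level_id[levels$is_wayfinding]
  tut <- trajectories |>
    filter(.data$level_id %in% tutorial_ids) |>
    group_by(.data$participant_id) |>
    summarise(tutorial_sum = sum(.data$trajectory_length), n_tut = n(),
              .groups = "drop") |>
    filter(.data$n_tut == 2)
  trajectories |>
    filter(.data$level_id %in% wf_ids) |>
    inner_join(tut, by = "participant_id") |>
    mutate(outcome = -.data$trajectory_length / .data$tutorial_sum) |>
    inner_join(participants, by = "participant_id") |>
    select(-"tutorial_sum", -"n_tut", -"trajectory_length")
}
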
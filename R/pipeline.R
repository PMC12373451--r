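#' Assemble a pipeline run configuration
#'
#' @param seed Master seed; every random stage derives its own stream from
#'   it, so a config fully determines the run.
#' @param generator A [generator_config()] (its seed is overridden by
#'   `seed`).
#' @param criteria An [inclusion_criteria()].
#' @param wayfinding_ids Levels entering the performance composite.
#' @param analyses Named list of toggles: `effects`, `country_slopes`,
#'   `difficulty`, `rdd`.
#' @param rdd_center,rdd_halfwidth,rdd_country Discontinuity analysis
#'   settings: first affected birth cohort, sweep half-width, and the
#'   country the reform applies to.
#' @param out_dir Optional output directory for CSV/JSON artifacts.
#' @return A list of class `wayfindr_run_config`.
#' @export
run_config <- function(seed,
                       generator = generator_config(seed = seed),
                       criteria = inclusion_criteria(),
                       wayfinding_ids = c(6L, 7L, 8L, 11L),
                       analyses = list(effects = TRUE, country_slopes = TRUE,
                                       difficulty = FALSE, rdd = TRUE),
                       rdd_center = 1957L,
                       rdd_halfwidth = 5L,
                       rdd_country = "GB",
                       out_dir = NULL) {
  generator$seed <- as.integer(seed)
  structure(
    list(seed = as.integer(seed), generator = generator,
         criteria = criteria, wayfinding_ids = wayfinding_ids,
         analyses = analyses, rdd_center = rdd_center,
         rdd_halfwidth = rdd_halfwidth, rdd_country = rdd_country,
         out_dir = out_dir),
    class = "wayfindr_run_config"
  )
}

#' Run the full analysis pipeline
#'
#' Executes simulate -> filter -> score -> effects -> discontinuity as
#' toggled in the config, writing tables (and a JSON report) to
#' `config$out_dir` when set. The returned report carries stage counts,
#' the main estimates and seed provenance; an identical config yields an
#' identical report.
#'
#' @param config A [run_config()].
#' @param data Optional pre-loaded list (`participants`, `trajectories`,
#'   `levels`) to analyze instead of simulating.
#' @return A list of class `wayfindr_report` with elements `provenance`,
#'   `filter`, `scores`, `effects`, `rdd` (those not toggled are absent),
#'   plus the scored cohort in `cohort`.
#' @examples
#' \donttest{
#' rep <- run_pipeline(run_config(seed = 1,
#'   generator = generator_config(n_participants = 2000),
#'   criteria = inclusion_criteria(min_country_n = 50)))
#' rep$effects$anova
#' }
#' @export
run_pipeline <- function(config, data = NULL) {
  stopifnot(inherits(config, "wayfindr_run_config"))
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      abort(sprintf("pipeline stage '%s' failed: %s", name,
                    conditionMessage(e)),
            class = "wayfindr_pipeline_error")
    })
  }

  data <- data %||% stage("simulate", simulate_cohort(config$generator))

  filtered <- stage("filter", apply_inclusion(
    data$participants, data$trajectories, data$levels, config$criteria
  ))
  inform(sprintf(
    "filter: %s",
    paste(sprintf("%s=%d", filtered$report$stages$stage,
                  filtered$report$stages$n), collapse = " -> ")
  ))

  scored <- stage("score", score_cohort(
    filtered$cohort, data$trajectories, data$levels,
    wayfinding_ids = config$wayfinding_ids
  ))

  report <- list(
    provenance = list(
      package = "wayfindr",
      version = as.character(utils::packageVersion("wayfindr")),
      seed = config$seed,
      n_simulated = nrow(data$participants)
    ),
    filter = list(
      stages = filtered$report$stages,
      countries = filtered$report$countries
    ),
    scores = list(
      n_scored = nrow(scored),
      sd_wf = sd(scored$wf),
      cor_age_wf = cor(scored$age, scored$wf),
      cor_wf_tp = cor(scored$wf, scored$tp)
    )
  )

  if (isTRUE(config$analyses$effects)) {
    report$effects <- stage("effects", {
      ter <- scored$wf[scored$education2 == "tertiary"]
      sec <- scored$wf[scored$education2 == "secondary_and_lower"]
      males <- scored$wf[scored$gender == "male"]
      females <- scored$wf[scored$gender == "female"]
      list(
        anova = anova_main_effects(scored),
        g_education = hedges_g(ter, sec),
        g_gender = hedges_g(males, females),
        g_by_age = g_by_age_window(scored)
      )
    })
  }

  if (isTRUE(config$analyses$country_slopes) &&
      n_distinct(scored$country) >= 3) {
    report$country_slopes <- stage("country_slopes", {
      fit <- fit_education_slopes(scored, group = "country")
      list(slopes = fit$slopes, slope_sd = fit$slope_sd,
           fixed = fit$fixed,
           interaction = fixed_interaction_model(scored))
    })
  }

  if (isTRUE(config$analyses$difficulty)) {
    report$difficulty <- stage("difficulty", {
      long <- level_outcomes(scored, data$trajectories, data$levels)
      fit <- fit_education_slopes(long, outcome = "outcome",
                                  group = "level_id")
      diff <- difficulty_table(
        semi_join(data$trajectories, scored, by = "participant_id"),
        data$levels
      )
      slopes <- fit$slopes
      names(slopes)[1] <- "group"
      indicator <- tibble(group = as.character(diff$level_id),
                          value = diff$difficulty)
      list(
        slopes = fit$slopes, difficulty = diff,
        correlation = correlate_slopes_with_indicator(slopes, indicator)
      )
    })
  }

  if (isTRUE(config$analyses$rdd)) {
    report$rdd <- stage("rdd", {
      uk <- filter(scored, .data$country == config$rdd_country)
      window <- filter(
        uk,
        abs(.data$birth_year - config$rdd_center) <= config$rdd_halfwidth
      )
      if (nrow(window) < 50) {
        inform("rdd: fewer than 50 in-window participants; skipping")
        NULL
      } else {
        sweep <- sweep_cutoffs(uk, center_year = config$rdd_center,
                               halfwidth = config$rdd_halfwidth)
        gap <- pre_post_gap(window, cutoff = config$rdd_center)
        placebo <- placebo_rdd(uk, center_year = config$rdd_center,
                               halfwidth = config$rdd_halfwidth)
        list(sweep = sweep, gap = gap, placebo = placebo)
      }
    })
  }

  report$cohort <- scored
  class(report) <- "wayfindr_report"

  if (!is.null(config$out_dir)) {
    write_report(report, data, config$out_dir)
  }
  report
}

# Serialize pipeline artifacts: CSV tables plus a JSON summary.
write_report <- function(report, data, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  write_cohort_tables(data, dir)
  readr::write_csv(
    select(report$cohort, "participant_id", "wf"),
    file.path(dir, "wf_scores.csv")
  )
  readr::write_csv(
    select(report$cohort, "participant_id", "tp"),
    file.path(dir, "training_scores.csv")
  )
  if (!is.null(report$effects)) {
    readr::write_csv(report$effects$anova, file.path(dir, "anova.csv"))
    readr::write_csv(report$effects$g_by_age, file.path(dir, "g_by_age.csv"))
  }
  if (!is.null(report$country_slopes)) {
    readr::write_csv(report$country_slopes$slopes,
                     file.path(dir, "country_slopes.csv"))
  }
  if (!is.null(report$difficulty)) {
    readr::write_csv(report$difficulty$slopes,
                     file.path(dir, "level_slopes.csv"))
    readr::write_csv(report$difficulty$difficulty,
                     file.path(dir, "difficulty.csv"))
  }
  if (!is.null(report$rdd)) {
    readr::write_csv(tidy(report$rdd$sweep), file.path(dir, "rdd_sweep.csv"))
    jsonlite::write_json(
      list(
        cutoff = report$rdd$gap$cutoff,
        pre = report$rdd$gap$pre_value, post = report$rdd$gap$post_value,
        delta = report$rdd$gap$delta, iq_points = report$rdd$gap$iq_points,
        sd_outcome = report$rdd$gap$sd_outcome
      ),
      file.path(dir, "gap.json"), auto_unbox = TRUE, digits = NA
    )
  }
  jsonlite::write_json(
    summarize_report(report), file.path(dir, "report.json"),
    auto_unbox = TRUE, digits = NA
  )
  invisible(dir)
}

#' Flatten a pipeline report into plain lists for JSON
#'
#' @param report A `wayfindr_report`.
#' @return A nested list of scalars and data frames, JSON-serializable.
#' @export
summarize_report <- function(report) {
  out <- list(
    provenance = report$provenance,
    filter_stages = as.data.frame(report$filter$stages),
    scores = report$scores
  )
  if (!is.null(report$effects)) {
    out$effects <- list(
      anova = as.data.frame(report$effects$anova),
      g_education = as.list(report$effects$g_education),
      g_gender = as.list(report$effects$g_gender)
    )
  }
  if (!is.null(report$country_slopes)) {
    out$country_slopes <- list(
      slopes = as.data.frame(report$country_slopes$slopes),
      slope_sd = report$country_slopes$slope_sd
    )
  }
  if (!is.null(report$rdd)) {
    out$rdd <- list(
      best_cutoff = attr(report$rdd$sweep, "best_cutoff"),
      delta = report$rdd$gap$delta,
      iq_points = report$rdd$gap$iq_points,
      placebo_max = as.list(attr(report$rdd$placebo, "summary"))
    )
  }
  out
}

#' @export
print.wayfindr_report <- function(x, ...) {
  cat("wayfindr pipeline report (seed", x$provenance$seed, ")\n")
  cat("  cohort:", x$scores$n_scored, "scored participants;",
      sprintf("cor(age, wf) = %.3f; sd(wf) = %.3f\n",
              x$scores$cor_age_wf, x$scores$sd_wf))
  if (!is.null(x$effects)) {
    cat(sprintf("  education g = %.3f [%.3f, %.3f]; gender g = %.3f\n",
                x$effects$g_education$g, x$effects$g_education$ci_low,
                x$effects$g_education$ci_high, x$effects$g_gender$g))
  }
  if (!is.null(x$rdd)) {
    cat(sprintf("  rdd: argmax cutoff %d, delta = %.4f (%.2f IQ points)\n",
                attr(x$rdd$sweep, "best_cutoff"), x$rdd$gap$delta,
                x$rdd$gap$iq_points))
  }
  invisible(x)
}
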
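#' Generator configuration for the reform simulation study
#'
#' A single-country (GB) cohort spanning ages 49–69 at collection, i.e.
#' birth years 1947–1967: exactly the ±10-year data window around the 1957
#' first-affected cohort used by the discontinuity analysis. Country
#' heterogeneity is switched off so the only structure near the cutoff is
#' the reform itself (plus the age trend).
#'
#' @param n_participants Cohort size (default 40,000, the in-window sample
#'   size of the analysis this design emulates).
#' @param seed Integer seed.
#' @param complier_skill_gain Latent-skill gain per complier; 0 gives a
#'   null (no-reform) cohort.
#' @param complier_fraction Fraction of would-be early leavers affected.
#' @param first_affected_birth_year First reform-bound cohort.
#' @return A [generator_config()].
#' @export
reform_study_config <- function(n_participants = 40000L, seed = 1L,
                                complier_skill_gain = 0,
                                complier_fraction = 0.3,
                                first_affected_birth_year = 1957L) {
  reform <- if (complier_skill_gain != 0) {
    reform_spec(first_affected_birth_year,
                complier_fraction = complier_fraction,
                complier_skill_gain = complier_skill_gain,
                country = "GB")
  }
  generator_config(
    n_participants = n_participants,
    countries = tibble(country = "GB", weight = 1, slope_offset = 0,
                       intercept = 0),
    age_range = c(49L, 69L),
    country_slope_sd = 0,
    reform = reform,
    seed = seed
  )
}

#' Score a generated cohort end to end
#'
#' Convenience for simulation studies: generates a cohort from a config,
#' merges education and computes the wayfinding and training scores,
#' skipping the inclusion filter (generated cohorts are complete by
#' construction).
#'
#' @param config A [generator_config()].
#' @param n_wayfinding Number of wayfinding levels.
#' @return The scored participant tibble (with `education2`, `wf`, `tp`).
#' @export
simulate_scored_cohort <- function(config, n_wayfinding = 9L) {
  d <- simulate_cohort(config, n_wayfinding = n_wayfinding)
  p <- mutate(d$participants, education2 = merge_education(.data$education4))
  suppressMessages(score_cohort(p, d$trajectories, d$levels))
}

#' Calibrate the complier gain for a target mean discontinuity
#'
#' Chooses the per-complier latent-skill gain so that the mean jump in
#' wayfinding performance at the reform cutoff equals `target_sd_step`
#' standard deviations of WF. The mean jump is
#' `share_secondary * complier_fraction * gain` (in latent units), and the
#' latent-to-WF scale and the SDs are measured empirically on a null
#' calibration cohort drawn with a fixed internal seed.
#'
#' @param target_sd_step Target jump in SD(WF) units (e.g. 0.05).
#' @param complier_fraction Complier fraction used in the study.
#' @param n_participants Calibration cohort size.
#' @param seed Seed for the calibration cohort.
#' @return The complier skill gain (latent units).
#' @export
calibrate_complier_gain <- function(target_sd_step = 0.05,
                                    complier_fraction = 0.3,
                                    n_participants = 40000L,
                                    seed = 1999L) {
  cal <- simulate_scored_cohort(
    reform_study_config(n_participants = n_participants, seed = seed)
  )
  scale_wf <- sd(cal$wf) / sd(cal$latent_skill)  # WF units per latent unit
  share <- mean(cal$education2 == "secondary_and_lower")
  target_latent <- target_sd_step * sd(cal$wf) / scale_wf
  target_latent / (share * complier_fraction)
}
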
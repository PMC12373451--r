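#' Merge four education labels into the two analysis classes
#'
#' Collapses `university` and `college` into `tertiary` (the meaning of
#' "college" varies across countries, so the two cannot be separated
#' cross-nationally) and `high-school` and `no formal` into
#' `secondary_and_lower` (the no-formal group is too small and too
#' selection-prone to analyze alone).
#'
#' @param education4 Character or factor vector of 4-class education labels:
#'   `"university"`, `"college"`, `"high-school"`, `"no formal"`.
#' @return A factor with levels `secondary_and_lower`, `tertiary` (reference
#'   level `secondary_and_lower`, so regression coefficients for this factor
#'   are the tertiary advantage).
#' @examples
#' merge_education(c("university", "no formal"))
#' @export
merge_education <- function(education4) {
  x <- as.character(education4)
  known <- x %in% education4_levels() | is.na(x)
  if (!all(known)) {
    abort(
      sprintf("unknown education label(s): %s",
              paste(unique(x[!known]), collapse = ", ")),
      class = "wayfindr_invalid_value"
    )
  }
  factor(
    if_else(x %in% c("university", "college"), "tertiary",
            "secondary_and_lower"),
    levels = c("secondary_and_lower", "tertiary")
  )
}

#' Inclusion criteria for the analysis cohort
#'
#' @param min_levels_completed Minimum number of distinct completed levels.
#' @param min_wayfinding_completed Minimum number of completed wayfinding
#'   levels among them.
#' @param max_age Maximum age retained (inclusive: "above `max_age`" is
#'   removed, participants aged exactly `max_age` stay).
#' @param min_country_n Minimum retained players per country.
#' @param max_education_imbalance Maximum ratio between the larger and the
#'   smaller merged education class within a country; strictly larger ratios
#'   exclude the country.
#' @return A list of class `wayfindr_criteria`.
#' @export
inclusion_criteria <- function(min_levels_completed = 11L,
                               min_wayfinding_completed = 4L,
                               max_age = 70,
                               min_country_n = 500L,
                               max_education_imbalance = 10) {
  thresholds <- c(min_levels_completed, min_wayfinding_completed, max_age,
                  max_education_imbalance)
  if (any(thresholds <= 0) || min_country_n < 0) {
    abort("all inclusion thresholds must be positive",
          class = "wayfindr_invalid_argument")
  }
  structure(
    list(
      min_levels_completed = min_levels_completed,
      min_wayfinding_completed = min_wayfinding_completed,
      max_age = max_age,
      min_country_n = min_country_n,
      max_education_imbalance = max_education_imbalance
    ),
    class = "wayfindr_criteria"
  )
}

#' Per-country sample size and education-class balance
#'
#' For each country computes the retained sample size and the imbalance
#' ratio between the two merged education classes,
#' `max(class counts) / min(class counts)` (infinite when a class is empty),
#' and flags the countries eligible for cross-country analysis.
#'
#' @param cohort Participant tibble carrying `country` and `education2`.
#' @param min_country_n Minimum players per eligible country.
#' @param max_imbalance Maximum tolerated imbalance ratio (strictly larger
#'   excludes).
#' @return A tibble with one row per country: `country`, `n`, `n_tertiary`,
#'   `n_secondary`, `imbalance`, `eligible`.
#' @export
country_eligibility <- function(cohort, min_country_n = 500L,
                                max_imbalance = 10) {
  check_columns(cohort, c("country", "education2"), "`cohort`")
  cohort |>
    group_by(.data$country) |>
    summarise(
      n = n(),
      n_tertiary = sum(.data$education2 == "tertiary"),
      n_secondary = sum(.data$education2 == "secondary_and_lower"),
      .groups = "drop"
    ) |>
    mutate(
      imbalance = if_else(
        pmin(.data$n_tertiary, .data$n_secondary) == 0,
        Inf,
        pmax(.data$n_tertiary, .data$n_secondary) /
          pmin(.data$n_tertiary, .data$n_secondary)
      ),
      eligible = .data$n >= min_country_n & .data$imbalance <= max_imbalance
    ) |>
    arrange(dplyr::desc(.data$n))
}

#' Apply the study inclusion criteria
#'
#' Filters participants in the narrative order of the study design: first
#' completeness (enough levels played, all demographics entered), then the
#' age cap (selection bias makes over-age volunteers unrepresentative), then
#' country-level sample size and education balance. Country eligibility is
#' evaluated once, on the already age- and completeness-filtered set, without
#' iterating to a fixed point. Adds the merged `education2` column and
#' returns an audit report of row counts per stage.
#'
#' @param participants Participant tibble (needs `participant_id`, `age`,
#'   `gender`, `education4`, `country`).
#' @param trajectories Trajectory tibble (`participant_id`, `level_id`,
#'   `trajectory_length`).
#' @param levels Level catalog (for the wayfinding flags).
#' @param criteria An [inclusion_criteria()].
#' @return A list with `cohort` (retained participants, plus `education2`)
#'   and `report` (list: `stages`, a tibble of stage names and row counts;
#'   `countries`, the per-country eligibility table the country filter used).
#' @examples
#' d <- simulate_cohort(generator_config(n_participants = 300, seed = 2))
#' res <- apply_inclusion(d$participants, d$trajectories, d$levels,
#'                        inclusion_criteria(min_country_n = 10))
#' res$report$stages
#' @export
apply_inclusion <- function(participants, trajectories, levels,
                            criteria = inclusion_criteria()) {
  check_columns(participants,
                c("participant_id", "age", "gender", "education4", "country"),
                "`participants`")
  check_columns(trajectories,
                c("participant_id", "level_id", "trajectory_length"),
                "`trajectories`")
  check_columns(levels, c("level_id", "is_wayfinding"), "`levels`")
  stopifnot(inherits(criteria, "wayfindr_criteria"))

  wf_ids <- levels$level_id[levels$is_wayfinding]
  completion <- trajectories |>
    distinct(.data$participant_id, .data$level_id) |>
    group_by(.data$participant_id) |>
    summarise(
      n_levels = n(),
      n_wayfinding = sum(.data$level_id %in% wf_ids),
      .groups = "drop"
    )

  demo_ok <- complete.cases(
    participants[, c("age", "gender", "education4", "country")]
  )
  stage0 <- participants
  stage1 <- stage0[demo_ok, , drop = FALSE] |>
    inner_join(completion, by = "participant_id") |>
    filter(
      .data$n_levels >= criteria$min_levels_completed,
      .data$n_wayfinding >= criteria$min_wayfinding_completed
    ) |>
    select(-"n_levels", -"n_wayfinding")

  stage2 <- filter(stage1, .data$age <= criteria$max_age)

  stage2 <- mutate(stage2, education2 = merge_education(.data$education4))
  countries <- country_eligibility(
    stage2,
    min_country_n = criteria$min_country_n,
    max_imbalance = criteria$max_education_imbalance
  )
  keep <- countries$country[countries$eligible]
  stage3 <- filter(stage2, .data$country %in% keep)

  list(
    cohort = as_tibble(stage3),
    report = list(
      stages = tibble(
        stage = c("initial", "completeness_demographics", "age", "country"),
        n = c(nrow(stage0), nrow(stage1), nrow(stage2), nrow(stage3))
      ),
      countries = countries
    )
  )
}
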
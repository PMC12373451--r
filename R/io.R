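#' Read and validate the three cohort tables
#'
#' Loads `participants.csv`, `trajectories.csv` and `levels.csv` (UTF-8,
#' header row, RFC 4180) and validates their schemas: required columns
#' present, trajectory lengths positive and numeric, no duplicated
#' (participant, level) pair. Errors name the offending column, key or row.
#'
#' @param participants_path,trajectories_path,levels_path File paths.
#' @return A list of tibbles `participants`, `trajectories`, `levels`.
#' @export
read_cohort_tables <- function(participants_path, trajectories_path,
                               levels_path) {
  participants <- readr::read_csv(participants_path,
                                  show_col_types = FALSE)
  trajectories <- readr::read_csv(trajectories_path, show_col_types = FALSE)
  levels <- readr::read_csv(levels_path, show_col_types = FALSE)

  check_columns(participants,
                c("participant_id", "age", "gender", "education4",
                  "country", "birth_year"),
                basename(participants_path))
  check_columns(trajectories,
                c("participant_id", "level_id", "trajectory_length"),
                basename(trajectories_path))
  check_columns(levels,
                c("level_id", "is_tutorial", "is_wayfinding", "min_length",
                  "difficulty_param"),
                basename(levels_path))

  if (!is.numeric(trajectories$trajectory_length)) {
    abort("trajectory_length must be numeric",
          class = "wayfindr_schema_error")
  }
  bad <- which(!is.finite(trajectories$trajectory_length) |
                 trajectories$trajectory_length <= 0)
  if (length(bad) > 0) {
    abort(
      sprintf("non-positive trajectory_length at row(s): %s",
              paste(head(bad, 5), collapse = ", ")),
      class = "wayfindr_schema_error"
    )
  }
  dup <- trajectories |>
    count(.data$participant_id, .data$level_id) |>
    filter(n > 1)
  if (nrow(dup) > 0) {
    abort(
      sprintf("duplicated (participant, level) pair(s): %s",
              paste(head(paste0(dup$participant_id, "/", dup$level_id), 5),
                    collapse = ", ")),
      class = "wayfindr_schema_error"
    )
  }

  pt <- mutate(participants,
               gender = factor(.data$gender, levels = c("female", "male")),
               education4 = factor(.data$education4,
                                   levels = education4_levels()))
  list(participants = pt, trajectories = trajectories, levels = levels)
}

#' Write the three cohort tables as CSV
#'
#' Generator-only columns (`latent_skill`, `motor_skill`, `complier`) are
#' not written: on disk the tables look like observed study data.
#'
#' @param cohort List with `participants`, `trajectories`, `levels` (as from
#'   [simulate_cohort()]).
#' @param dir Output directory (created if needed).
#' @return Invisibly, the paths written.
#' @export
write_cohort_tables <- function(cohort, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  paths <- file.path(dir, c("participants.csv", "trajectories.csv",
                            "levels.csv"))
  observed <- select(cohort$participants,
                     -dplyr::any_of(c("latent_skill", "motor_skill",
                                      "complier")))
  readr::write_csv(observed, paths[1])
  readr::write_csv(cohort$trajectories, paths[2])
  readr::write_csv(cohort$levels, paths[3])
  invisible(paths)
}

#' Read a pipeline run configuration from YAML
#'
#' Flat keys override [generator_config()] and [inclusion_criteria()]
#' defaults under the `generator:` and `criteria:` mappings; `seed` may be
#' given in the file or as an argument (the argument wins). A `reform:`
#' mapping inside `generator:` is converted to a [reform_spec()].
#'
#' @param path YAML file path.
#' @param seed Optional seed overriding the file's.
#' @return A run configuration list as from [run_config()].
#' @export
read_run_config <- function(path, seed = NULL) {
  raw <- yaml::read_yaml(path)
  seed <- seed %||% raw$seed
  if (is.null(seed)) {
    abort("a seed is required (in the YAML file or as an argument)",
          class = "wayfindr_invalid_argument")
  }
  gen_args <- raw$generator %||% list()
  if (!is.null(gen_args$reform)) {
    gen_args$reform <- do.call(reform_spec, gen_args$reform)
  }
  if (!is.null(gen_args$age_range)) {
    gen_args$age_range <- as.integer(unlist(gen_args$age_range))
  }
  gen_args$seed <- seed
  crit_args <- raw$criteria %||% list()
  run_config(
    seed = seed,
    generator = do.call(generator_config, gen_args),
    criteria = do.call(inclusion_criteria, crit_args),
    wayfinding_ids = unlist(raw$wayfinding_ids %||% c(6L, 7L, 8L, 11L)),
    analyses = modifyList(
      list(effects = TRUE, country_slopes = TRUE, difficulty = FALSE,
           rdd = TRUE),
      raw$analyses %||% list()
    ),
    rdd_center = raw$rdd_center %||% 1957L,
    rdd_halfwidth = raw$rdd_halfwidth %||% 5L,
    rdd_country = raw$rdd_country %||% "GB",
    out_dir = raw$out_dir
  )
}
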
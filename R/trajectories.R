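#' Simulate per-level trajectory lengths
#'
#' Generates one trajectory length (pixels) per participant and level.
#' Tutorial levels demand only motor control:
#' `length = min_length * motor_skill`. Wayfinding levels inflate the minimal
#' path by an amount that shrinks with latent skill and grows with level
#' difficulty:
#'
#' \deqn{length = min\_length \cdot motor \cdot
#'   (1 + difficulty \cdot \mathrm{softplus}(shift - skill + \varepsilon))}
#'
#' with \eqn{\varepsilon \sim N(0, level\_noise\_sd^2)} per observation. The
#' softplus keeps the inflation strictly positive (lengths never fall below
#' `min_length`) and strictly decreasing in skill, so higher latent skill
#' gives stochastically shorter wayfinding trajectories; the positive shift
#' keeps the link near-linear over the bulk of the skill distribution.
#'
#' @param participants Participant tibble from [sample_population()] (needs
#'   `participant_id`, `latent_skill`, `motor_skill`).
#' @param levels Level catalog from [level_catalog()].
#' @param link_shift Positive shift inside the softplus link.
#' @param level_noise_sd SD of the per-observation noise inside the link.
#' @param seed Integer seed for the level noise.
#' @return A tibble with columns `participant_id`, `level_id`,
#'   `trajectory_length`.
#' @export
simulate_trajectories <- function(participants, levels,
                                  link_shift = 5, level_noise_sd = 0.1,
                                  seed = 1L) {
  check_columns(participants, c("participant_id", "latent_skill", "motor_skill"),
                "`participants`")
  check_columns(levels,
                c("level_id", "is_tutorial", "is_wayfinding",
                  "min_length", "difficulty_param"),
                "`levels`")
  if (nrow(participants) == 0 || nrow(levels) == 0) {
    abort("`participants` and `levels` must be non-empty",
          class = "wayfindr_invalid_argument")
  }

  set.seed(derive_seed(seed, "trajectories"))
  long <- tidyr::crossing(
    select(participants, "participant_id", "latent_skill", "motor_skill"),
    select(levels, "level_id", "is_tutorial", "min_length", "difficulty_param")
  )
  eps <- rnorm(nrow(long), 0, level_noise_sd)
  inflation <- if_else(
    long$is_tutorial,
    0,
    long$difficulty_param * softplus(link_shift - long$latent_skill + eps)
  )
  long |>
    mutate(trajectory_length = .data$min_length * .data$motor_skill *
             (1 + inflation)) |>
    select("participant_id", "level_id", "trajectory_length") |>
    arrange(.data$participant_id, .data$level_id)
}

#' Generate a complete synthetic cohort
#'
#' Convenience wrapper: builds a level catalog, samples the population and
#' simulates all trajectory lengths from one configuration, so a full
#' analysis-ready dataset is a deterministic function of the config.
#'
#' @param config A [generator_config()].
#' @param n_wayfinding Number of wayfinding levels (default 9, so every
#'   participant has the 11 levels — 2 tutorial + 9 wayfinding — that the
#'   standard inclusion rule requires).
#' @return A list with tibbles `participants`, `trajectories`, `levels`.
#' @examples
#' cohort <- simulate_cohort(generator_config(n_participants = 200, seed = 3))
#' nrow(cohort$trajectories)
#' @export
simulate_cohort <- function(config, n_wayfinding = 9L) {
  stopifnot(inherits(config, "wayfindr_config"))
  levels <- level_catalog(n_wayfinding, seed = config$seed)
  participants <- sample_population(config)
  trajectories <- simulate_trajectories(
    participants, levels,
    link_shift = config$link_shift,
    level_noise_sd = config$level_noise_sd,
    seed = config$seed
  )
  list(participants = participants, trajectories = trajectories,
       levels = levels)
}
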
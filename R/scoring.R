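#' Tutorial-normalized trajectory lengths
#'
#' Divides each participant's wayfinding trajectory lengths by the sum of
#' their two tutorial trajectory lengths. The tutorials demand only motor
#' control, so the ratio removes device/video-gaming skill from the
#' wayfinding measure. Participants missing a tutorial level or any of the
#' requested wayfinding levels are dropped (with an informative message
#' counting them).
#'
#' @param trajectories Trajectory tibble (`participant_id`, `level_id`,
#'   `trajectory_length`).
#' @param levels Level catalog with `is_tutorial` flags.
#' @param wayfinding_ids Wayfinding levels forming the matrix columns
#'   (default the first four: 6, 7, 8, 11).
#' @return A tibble: `participant_id` plus one column `L<id>` per wayfinding
#'   level, all entries positive and finite.
#' @export
normalize_lengths <- function(trajectories, levels,
                              wayfinding_ids = c(6L, 7L, 8L, 11L)) {
  check_columns(trajectories,
                c("participant_id", "level_id", "trajectory_length"),
                "`trajectories`")
  check_columns(levels, c("level_id", "is_tutorial"), "`levels`")
  tutorial_ids <- levels$level_id[levels$is_tutorial]
  if (length(tutorial_ids) != 2) {
    abort("the level catalog must contain exactly 2 tutorial levels",
          class = "wayfindr_invalid_argument")
  }

  tut <- trajectories |>
    filter(.data$level_id %in% tutorial_ids) |>
    group_by(.data$participant_id) |>
    summarise(tutorial_sum = sum(.data$trajectory_length),
              n_tut = n(), .groups = "drop") |>
    filter(.data$n_tut == 2)
  if (any(tut$tutorial_sum <= 0)) {
    abort("tutorial trajectory lengths must sum to a positive value",
          class = "wayfindr_data_error")
  }

  wide <- trajectories |>
    filter(.data$level_id %in% wayfinding_ids) |>
    inner_join(tut, by = "participant_id") |>
    mutate(norm = .data$trajectory_length / .data$tutorial_sum,
           col = paste0("L", .data$level_id)) |>
    select("participant_id", "col", "norm") |>
    tidyr::pivot_wider(names_from = "col", values_from = "norm")

  cols <- paste0("L", wayfinding_ids)
  missing_cols <- setdiff(cols, names(wide))
  for (mc in missing_cols) wide[[mc]] <- NA_real_
  complete <- complete.cases(wide[, cols])
  n_dropped <- nrow(distinct(trajectories, .data$participant_id)) -
    sum(complete)
  if (n_dropped > 0) {
    inform(sprintf(
      "normalize_lengths: dropped %d participant(s) missing a tutorial or wayfinding level",
      n_dropped
    ))
  }
  wide[complete, c("participant_id", cols)]
}

#' Wayfinding-performance composite (first principal component)
#'
#' Computes the wayfinding performance score WF as the first principal
#' component of the column-standardized normalized-length matrix.
#' Standardizing the columns puts levels of different sizes on the same
#' scale, so no level over-contributes merely because it is larger; the
#' first component is the linear combination of the per-level ratios with
#' maximal variance, and remains interpretable as an overall trajectory
#' in-/efficiency score. The sign is fixed so that WF correlates negatively
#' with the mean normalized length — higher WF means shorter trajectories,
#' i.e. better wayfinding. In the degenerate case of exactly zero
#' correlation the orientation with a positive first loading is used.
#'
#' @param norm_matrix Output of [normalize_lengths()].
#' @return A tibble (`participant_id`, `wf`) with attributes `loadings`
#'   (named PC1 loading vector), `sdev` (PC standard deviations) and
#'   `prop_var` (share of variance explained by PC1).
#' @export
compute_wf <- function(norm_matrix) {
  check_columns(norm_matrix, "participant_id", "`norm_matrix`")
  x <- as.matrix(norm_matrix[, setdiff(names(norm_matrix), "participant_id")])
  if (nrow(x) < 3 || ncol(x) < 2) {
    abort("need at least 3 participants and 2 levels for the composite",
          class = "wayfindr_invalid_argument")
  }
  col_var <- apply(x, 2, var)
  if (any(!is.finite(col_var)) || any(col_var == 0)) {
    abort("constant or non-finite normalized-length column: composite undefined",
          class = "wayfindr_degenerate_input")
  }

  pca <- prcomp(x, center = TRUE, scale. = TRUE)
  wf <- pca$x[, 1]
  loading <- pca$rotation[, 1]
  orientation <- cor(wf, rowMeans(x))
  flip <- if (is.na(orientation) || orientation == 0) {
    loading[1] < 0
  } else {
    orientation > 0
  }
  if (flip) {
    wf <- -wf
    loading <- -loading
  }

  out <- tibble(participant_id = norm_matrix$participant_id, wf = unname(wf))
  attr(out, "loadings") <- loading
  attr(out, "sdev") <- pca$sdev
  attr(out, "prop_var") <- pca$sdev[1]^2 / sum(pca$sdev^2)
  out
}

#' Training (motor-control) performance score
#'
#' Control outcome built from the two tutorial levels only: each tutorial
#' length is divided by the shortest trajectory observed at that level in
#' the cohort, and the two ratios are summed. The score reflects motor and
#' device skill, not wayfinding, and serves as the placebo outcome in the
#' discontinuity analysis. Its minimum is 2 (a participant holding the
#' cohort record at both tutorials).
#'
#' @param trajectories Trajectory tibble for the analysis cohort.
#' @param levels Level catalog with `is_tutorial` flags.
#' @return A tibble (`participant_id`, `tp`), `tp >= 2` for participants
#'   with both tutorial levels; participants missing one are dropped.
#' @export
training_performance <- function(trajectories, levels) {
  check_columns(trajectories,
                c("participant_id", "level_id", "trajectory_length"),
                "`trajectories`")
  tutorial_ids <- levels$level_id[levels$is_tutorial]
  tut <- filter(trajectories, .data$level_id %in% tutorial_ids)
  if (nrow(tut) == 0) {
    abort("no tutorial trajectories found", class = "wayfindr_data_error")
  }
  if (any(tut$trajectory_length <= 0)) {
    abort("trajectory lengths must be positive", class = "wayfindr_data_error")
  }
  tut |>
    group_by(.data$level_id) |>
    mutate(ratio = .data$trajectory_length / min(.data$trajectory_length)) |>
    group_by(.data$participant_id) |>
    summarise(tp = sum(.data$ratio), n_tut = n(), .groups = "drop") |>
    filter(.data$n_tut == length(tutorial_ids)) |>
    select("participant_id", "tp")
}

#' Level difficulty from a vector of trajectory lengths
#'
#' Difficulty of a level is the excess of the median trajectory length over
#' the shortest one, normalized by the shortest:
#' \eqn{(\mathrm{median}(TL) - \min(TL)) / \min(TL)}. In a large cohort the
#' shortest trajectory is near-optimal, so the statistic measures how far
#' the typical player strays from the optimal path, on a scale-free ratio
#' that does not inflate with level size.
#'
#' @param lengths_at_level Positive trajectory lengths of all players at one
#'   level.
#' @return A single non-negative number; 0 iff the median equals the minimum.
#' @examples
#' level_difficulty(c(10, 15, 20))
#' @export
level_difficulty <- function(lengths_at_level) {
  if (length(lengths_at_level) < 1 || any(!is.finite(lengths_at_level)) ||
      any(lengths_at_level <= 0)) {
    abort("trajectory lengths must be positive and finite",
          class = "wayfindr_data_error")
  }
  m <- min(lengths_at_level)
  (median(lengths_at_level) - m) / m
}

#' Difficulty table for all wayfinding levels
#'
#' @param trajectories Trajectory tibble for the analysis cohort.
#' @param levels Level catalog; difficulty is computed for wayfinding levels.
#' @return A tibble (`level_id`, `difficulty`, `n`).
#' @export
difficulty_table <- function(trajectories, levels) {
  wf_ids <- levels$level_id[levels$is_wayfinding]
  trajectories |>
    filter(.data$level_id %in% wf_ids) |>
    group_by(.data$level_id) |>
    summarise(difficulty = level_difficulty(.data$trajectory_length),
              n = n(), .groups = "drop")
}

#' Score an analysis cohort
#'
#' Joins the wayfinding-performance composite and the training-performance
#' control score onto a filtered cohort table.
#'
#' @param cohort Filtered participant tibble (from [apply_inclusion()]).
#' @param trajectories Trajectory tibble.
#' @param levels Level catalog.
#' @param wayfinding_ids Levels entering the composite.
#' @return The cohort tibble with `wf` and `tp` columns added; participants
#'   that could not be scored are dropped.
#' @export
score_cohort <- function(cohort, trajectories, levels,
                         wayfinding_ids = c(6L, 7L, 8L, 11L)) {
  traj <- semi_join(trajectories, cohort, by = "participant_id")
  nm <- normalize_lengths(traj, levels, wayfinding_ids)
  wf <- compute_wf(nm)
  tp <- training_performance(traj, levels)
  cohort |>
    inner_join(wf, by = "participant_id") |>
    inner_join(tp, by = "participant_id")
}
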
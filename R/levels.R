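#' Build a level catalog for the navigation game
#'
#' Creates the table of game levels used by the trajectory simulator: two
#' tutorial levels (pure motor control, no wayfinding demand) followed by
#' `n_wayfinding` wayfinding levels whose difficulty increases with level
#' number, as in sequential-unlock game designs where later levels are harder.
#' The first four wayfinding levels always carry ids 6, 7, 8 and 11, the level
#' set that the default wayfinding-performance composite is computed on.
#'
#' @param n_wayfinding Number of wayfinding levels, at least 4.
#' @param seed Integer seed controlling the randomized level geometry.
#' @return A tibble with one row per level and columns `level_id`,
#'   `is_tutorial`, `is_wayfinding`, `min_length` (shortest possible
#'   trajectory, in pixels) and `difficulty_param` (dimensionless, 0 for
#'   tutorials, non-decreasing in `level_id` for wayfinding levels).
#' @examples
#' level_catalog(9, seed = 1)
#' @export
level_catalog <- function(n_wayfinding, seed = 1L) {
  if (!is.numeric(n_wayfinding) || length(n_wayfinding) != 1 ||
      n_wayfinding < 4 || n_wayfinding != round(n_wayfinding)) {
    abort(
      "`n_wayfinding` must be a single integer >= 4 (the composite needs levels 6, 7, 8 and 11)",
      class = "wayfindr_invalid_argument"
    )
  }
  n_wayfinding <- as.integer(n_wayfinding)

  rng <- local({
    set.seed(derive_seed(seed, "levels"))
    list(
      tut_min = runif(2, 100, 300),
      wf_min = runif(n_wayfinding, 300, 2000),
      # non-decreasing difficulty: cumulative sum of non-negative increments
      wf_diff = 0.12 + cumsum(runif(n_wayfinding, 0, 0.06))
    )
  })

  wf_ids <- c(6L, 7L, 8L, 11L)
  if (n_wayfinding > 4) {
    wf_ids <- c(wf_ids, seq(12L, length.out = n_wayfinding - 4L))
  }

  tibble(
    level_id = c(1L, 2L, wf_ids),
    is_tutorial = c(TRUE, TRUE, rep(FALSE, n_wayfinding)),
    is_wayfinding = c(FALSE, FALSE, rep(TRUE, n_wayfinding)),
    min_length = c(rng$tut_min, rng$wf_min),
    difficulty_param = c(0, 0, rng$wf_diff)
  )
}
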
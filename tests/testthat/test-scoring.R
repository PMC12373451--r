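toy_traj <- function(rows) {
  tibble::tibble(
    participant_id = rows$id, level_id = rows$level,
    trajectory_length = rows$len
  )
}

test_that("normalization divides by the tutorial sum and is scale invariant", {
  rows <- tibble::tibble(
    id = "P1",
    level = c(1L, 2L, 6L, 7L, 8L, 11L),
    len = c(10, 20, 30, 60, 90, 120)
  )
  nm <- normalize_lengths(toy_traj(rows), toy_levels())
  expect_equal(nm$L6, 1.0)
  expect_equal(nm$L7, 2.0)

  doubled <- dplyr::mutate(toy_traj(rows), trajectory_length = 2 * trajectory_length)
  nm2 <- normalize_lengths(doubled, toy_levels())
  expect_equal(as.data.frame(nm2), as.data.frame(nm))
})

test_that("participants missing a required level are dropped, others kept", {
  rows <- tidyr::crossing(id = c("P1", "P2", "P3"),
                          level = c(1L, 2L, 6L, 7L, 8L, 11L)) |>
    dplyr::mutate(len = 50) |>
    dplyr::filter(!(id == "P2" & level == 11L))
  expect_message(
    nm <- normalize_lengths(toy_traj(rows), toy_levels()),
    "dropped 1"
  )
  expect_setequal(nm$participant_id, c("P1", "P3"))
})

test_that("composite equals the brute-force eigendecomposition oracle", {
  set.seed(11)
  base <- rnorm(10)
  X <- sapply(1:4, function(j) 1.5 + 0.8 * base + rnorm(10, sd = 0.3))
  nm <- tibble::as_tibble(as.data.frame(X))
  names(nm) <- paste0("L", c(6, 7, 8, 11))
  nm <- dplyr::bind_cols(tibble::tibble(participant_id = sprintf("P%d", 1:10)), nm)
  wf <- compute_wf(nm)
  expect_equal(wf$wf, wf_eigen_oracle(X), tolerance = 1e-8)
  expect_lt(cor(wf$wf, rowMeans(X)), 0)
})

test_that("rank-one composite is the negated standardized column", {
  a <- c(1, 3, 2, 5, 4, 6, 8, 7)
  nm <- tibble::tibble(participant_id = sprintf("P%d", 1:8), L6 = a, L7 = a)
  wf <- compute_wf(nm)
  expect_equal(cor(wf$wf, a), -1)
})

test_that("composite is equivariant under row permutation", {
  set.seed(12)
  X <- matrix(rexp(40, rate = 2) + 0.5, ncol = 4)
  nm <- dplyr::bind_cols(
    tibble::tibble(participant_id = sprintf("P%d", 1:10)),
    tibble::as_tibble(as.data.frame(X)) |> setNames(paste0("L", c(6, 7, 8, 11)))
  )
  wf <- compute_wf(nm)
  perm <- sample(10)
  wf_p <- compute_wf(nm[perm, ])
  expect_equal(wf_p$wf, wf$wf[perm], tolerance = 1e-10)
})

test_that("degenerate matrices are rejected", {
  nm <- tibble::tibble(participant_id = c("a", "b", "c"),
                       L6 = c(1, 1, 1), L7 = c(1, 2, 3))
  expect_error(compute_wf(nm), class = "wayfindr_degenerate_input")
  expect_error(compute_wf(nm[1:2, ]), class = "wayfindr_invalid_argument")
})

test_that("training performance is the sum of per-tutorial ratios", {
  rows <- tibble::tibble(
    id = rep(c("P1", "P2"), each = 2),
    level = rep(c(1L, 2L), 2),
    len = c(10, 20, 12, 30)  # P1 holds both cohort minima
  )
  tp <- training_performance(toy_traj(rows), toy_levels())
  expect_equal(tp$tp[tp$participant_id == "P1"], 2.0)
  expect_equal(tp$tp[tp$participant_id == "P2"], 12 / 10 + 30 / 20)  # 2.7
  expect_error(
    training_performance(
      dplyr::mutate(toy_traj(rows), trajectory_length = -trajectory_length),
      toy_levels()
    ),
    class = "wayfindr_data_error"
  )
})

test_that("difficulty statistic matches hand arithmetic and is scale free", {
  expect_equal(level_difficulty(c(10, 10, 10)), 0.0)
  expect_equal(level_difficulty(c(10, 15, 20)), 0.5)
  x <- c(3, 8, 11, 40)
  expect_equal(level_difficulty(7 * x), level_difficulty(x))
  expect_error(level_difficulty(c(10, 0)), class = "wayfindr_data_error")
  # monotone in the median with the minimum fixed
  expect_gt(level_difficulty(c(10, 30, 50)), level_difficulty(c(10, 20, 50)))
})

test_that("wayfinding and training scores are nearly uncorrelated by design", {
  res <- scored_cohort(generator_config(n_participants = 5000, seed = 21))
  expect_lt(abs(cor(res$scored$wf, res$scored$tp)), 0.15)
  expect_lt(cor(res$scored$age, res$scored$wf), 0)
})
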
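# Shared fixtures: all synthetic, built in code.

single_country <- function(code = "XX") {
  tibble::tibble(country = code, weight = 1, slope_offset = 0, intercept = 0)
}

# A hand-built level catalog with known geometry for scoring tests:
# tutorials 1 (min 10) and 2 (min 20), wayfinding 6/7/8/11.
toy_levels <- function() {
  tibble::tibble(
    level_id = c(1L, 2L, 6L, 7L, 8L, 11L),
    is_tutorial = c(TRUE, TRUE, FALSE, FALSE, FALSE, FALSE),
    is_wayfinding = c(FALSE, FALSE, TRUE, TRUE, TRUE, TRUE),
    min_length = c(10, 20, 100, 200, 150, 300),
    difficulty_param = c(0, 0, 0.3, 0.6, 0.5, 0.9)
  )
}

# Minimal participant rows for the trajectory simulator.
toy_participants <- function(latent = c(0, 2), motor = 1) {
  tibble::tibble(
    participant_id = sprintf("P%02d", seq_along(latent)),
    latent_skill = latent,
    motor_skill = rep(motor, length.out = length(latent))
  )
}

# Generate, merge education and score a cohort in one quiet call.
scored_cohort <- function(config, n_wayfinding = 9L) {
  d <- simulate_cohort(config, n_wayfinding = n_wayfinding)
  p <- dplyr::mutate(d$participants,
                     education2 = merge_education(education4))
  sc <- suppressMessages(score_cohort(p, d$trajectories, d$levels))
  list(scored = sc, data = d)
}

# Independent brute-force oracle for the performance composite: explicit
# eigendecomposition of the correlation matrix, scores by projection of the
# standardized matrix, oriented against the row mean.
wf_eigen_oracle <- function(X) {
  Z <- scale(X)
  v <- eigen(stats::cor(X), symmetric = TRUE)$vectors[, 1]
  s <- drop(Z %*% v)
  if (stats::cor(s, rowMeans(X)) > 0) s <- -s
  s
}

# Independent closed-form evaluation of the bias-corrected standardized
# mean difference and its normal-approximation CI, written as one plain
# arithmetic expression chain (no shared code with the implementation).
hedges_oracle <- function(a, b) {
  n1 <- length(a); n2 <- length(b)
  sp <- sqrt(((n1 - 1) * stats::var(a) + (n2 - 1) * stats::var(b)) /
               (n1 + n2 - 2))
  J <- 1 - 3 / (4 * (n1 + n2 - 2) - 1)
  g <- J * (mean(a) - mean(b)) / sp
  se <- sqrt((n1 + n2) / (n1 * n2) + g^2 / (2 * (n1 + n2 - 2)))
  c(g = g, lo = g - stats::qnorm(0.975) * se, hi = g + stats::qnorm(0.975) * se)
}
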
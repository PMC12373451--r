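piecewise <- function(step = 0.5, slope = 0.1, cutoff = 1957,
                      years = 1947:1967, per_year = 5, intercept = 2) {
  d <- tibble::tibble(birth_year = rep(years, each = per_year))
  d$wf <- intercept + slope * (d$birth_year - cutoff) +
    step * (d$birth_year >= cutoff)
  d
}

test_that("noiseless piecewise-linear data give the exact jump", {
  fit <- fit_rdd(piecewise(step = 0.5), cutoff = 1957)
  expect_equal(fit$estimate, 0.5, tolerance = 1e-10)
  expect_lt(fit$se, 1e-8)
  flat <- fit_rdd(piecewise(step = 0), cutoff = 1957)
  expect_equal(flat$estimate, 0, tolerance = 1e-10)
})

test_that("estimates are invariant under joint translation of years", {
  d <- piecewise(step = 0.3)
  set.seed(61)
  d$wf <- d$wf + rnorm(nrow(d), sd = 0.2)
  f1 <- fit_rdd(d, cutoff = 1957)
  d2 <- dplyr::mutate(d, birth_year = birth_year + 25)
  f2 <- fit_rdd(d2, cutoff = 1957 + 25)
  expect_equal(f1$estimate, f2$estimate, tolerance = 1e-10)
  expect_equal(f1$se, f2$se, tolerance = 1e-10)
  expect_equal(f1$p_value, f2$p_value, tolerance = 1e-10)
})

test_that("one-sided data are rejected", {
  d <- piecewise(years = 1958:1967)
  expect_error(fit_rdd(d, cutoff = 1957),
               class = "wayfindr_invalid_argument")
})

test_that("cutoff sweep localizes a clean step and honors the grid", {
  d <- piecewise(step = 0.4)
  set.seed(62)
  d$wf <- d$wf + rnorm(nrow(d), sd = 0.05)
  sw <- sweep_cutoffs(d, center_year = 1957, halfwidth = 5)
  expect_equal(nrow(sw), 11)
  expect_equal(sw$cutoff, 1952:1962)
  expect_equal(attr(sw, "best_cutoff"), 1957)
  td <- tidy(sw)
  expect_true(td$best[td$cutoff == 1957])
  single <- sweep_cutoffs(d, center_year = 1957, halfwidth = 0,
                          window_halfwidth = 10)
  expect_equal(nrow(single), 1)
  expect_s3_class(autoplot(sw), "ggplot")
})

test_that("two-line gap reproduces continuity and exact steps", {
  cont <- piecewise(step = 0)
  gap0 <- pre_post_gap(cont, cutoff = 1957)
  expect_equal(gap0$delta, 0, tolerance = 1e-10)

  stepd <- piecewise(step = 0.5)
  gap <- pre_post_gap(stepd, cutoff = 1957)
  expect_equal(gap$delta, 0.5, tolerance = 1e-10)
  expect_equal(gap$post_value - gap$pre_value, gap$delta)
  expect_equal(gap$n_pre + gap$n_post, nrow(stepd))
  td <- tidy(gap)
  expect_equal(td$estimate[td$side == "delta"], 0.5, tolerance = 1e-10)
  expect_s3_class(autoplot(gap, stepd), "ggplot")
  expect_error(pre_post_gap(stepd[stepd$birth_year >= 1956, ], 1957),
               class = "wayfindr_invalid_argument")
})

test_that("IQ rescaling is linear in the gap and inverse in the SD", {
  expect_equal(iq_rescale(0.06, 1.125), 0.8)
  expect_equal(iq_rescale(0.12, 1.125), 2 * iq_rescale(0.06, 1.125))
  expect_equal(iq_rescale(0.06, 2.25), iq_rescale(0.06, 1.125) / 2)
  expect_error(iq_rescale(0.1, 0), class = "wayfindr_invalid_argument")
})

test_that("placebo sweep detects a deliberate motor-skill step", {
  set.seed(63)
  d <- tibble::tibble(birth_year = rep(1947:1967, each = 200))
  d$tp <- 2.2 + 0.001 * (d$birth_year - 1957) +
    0.08 * (d$birth_year >= 1957) + rexp(nrow(d), rate = 10)
  pl <- placebo_rdd(d, center_year = 1957, halfwidth = 5)
  sm <- attr(pl, "summary")
  expect_equal(sm$cutoff, 1957)
  expect_lt(sm$p_value, 0.01)
  expect_error(placebo_rdd(d[0, ], 1957, 5), class = "wayfindr_data_error")
})

test_that("rdd accessors are tidy", {
  d <- piecewise(step = 0.2)
  set.seed(64)
  d$wf <- d$wf + rnorm(nrow(d), sd = 0.1)
  fit <- fit_rdd(d, cutoff = 1957)
  td <- tidy(fit)
  expect_equal(td$term, "discontinuity")
  expect_equal(td$estimate, fit$estimate)
  gl <- glance(fit)
  expect_equal(gl$n, nrow(d))
})
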
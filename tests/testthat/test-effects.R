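test_that("standardized mean difference matches the closed-form oracle", {
  a <- c(2, 4); b <- c(1, 3)
  eff <- hedges_g(a, b)
  ora <- hedges_oracle(a, b)
  expect_equal(eff$g, unname(ora["g"]), tolerance = 1e-10)
  expect_equal(eff$ci_low, unname(ora["lo"]), tolerance = 1e-10)
  expect_equal(eff$ci_high, unname(ora["hi"]), tolerance = 1e-10)

  set.seed(31)
  for (i in 1:10) {
    x <- rnorm(sample(5:40, 1), mean = runif(1, -1, 1))
    y <- rnorm(sample(5:40, 1), sd = runif(1, 0.5, 2))
    eff <- hedges_g(x, y)
    ora <- hedges_oracle(x, y)
    expect_equal(eff$g, unname(ora["g"]), tolerance = 1e-10)
    # antisymmetry
    expect_equal(hedges_g(y, x)$g, -eff$g, tolerance = 1e-12)
  }
})

test_that("null and degenerate effect-size inputs behave", {
  x <- c(1, 2, 3, 4)
  eff <- hedges_g(x, x)
  expect_equal(eff$g, 0)
  expect_lt(eff$ci_low, 0)
  expect_gt(eff$ci_high, 0)
  expect_error(hedges_g(c(1, 1), c(1, 1)),
               class = "wayfindr_degenerate_input")
  expect_error(hedges_g(1, c(1, 2)), class = "wayfindr_invalid_argument")
  # the exact noncentral-t interval agrees with the normal one at large n
  set.seed(32)
  x <- rnorm(500, 0.3); y <- rnorm(500)
  e1 <- hedges_g(x, y)
  e2 <- hedges_g(x, y, ci_method = "noncentral_t")
  expect_equal(e1$ci_low, e2$ci_low, tolerance = 0.01)
  expect_equal(e1$ci_high, e2$ci_high, tolerance = 0.01)
})

test_that("age-window profile: single window, anchoring, and rising trend", {
  d <- tibble::tibble(
    age = rep(20:23, each = 10),
    education2 = factor(rep(c("tertiary", "secondary_and_lower"), 20),
                        levels = c("secondary_and_lower", "tertiary")),
    wf = rnorm(40)
  )
  one <- g_by_age_window(d, window_width = 5)
  expect_equal(nrow(one), 1)
  expect_equal(one$window_low, 20)
  expect_equal(one$window_center, 22.5)

  # interaction injected in the generator shows up as a rising g profile
  res <- scored_cohort(generator_config(
    n_participants = 30000, countries = single_country(),
    beta_age_x_education = 0.006, country_slope_sd = 0, seed = 33
  ))
  prof <- g_by_age_window(res$scored)
  trend <- coef(lm(g ~ window_center, data = prof))["window_center"]
  expect_gt(trend, 0)
})

test_that("factorial ANOVA reduces to t-squared in the two-group case", {
  set.seed(34)
  d <- tibble::tibble(
    education2 = factor(rep(c("secondary_and_lower", "tertiary"), each = 30),
                        levels = c("secondary_and_lower", "tertiary")),
    wf = rnorm(60, mean = rep(c(0, 0.5), each = 30))
  )
  an <- anova_main_effects(d, rhs = ~education2)
  tt <- t.test(wf ~ education2, data = d, var.equal = TRUE)
  expect_equal(an$statistic, unname(tt$statistic)^2, tolerance = 1e-10)
  expect_equal(an$p_value, tt$p.value, tolerance = 1e-10)
})

test_that("ANOVA detects an injected age-by-education interaction", {
  res <- scored_cohort(generator_config(
    n_participants = 50000, countries = single_country(),
    beta_age_x_education = 0.006, country_slope_sd = 0, seed = 35
  ))
  an <- anova_main_effects(res$scored)
  expect_setequal(
    an$term,
    c("age", "gender", "education2", "age:gender", "age:education2",
      "gender:education2", "age:gender:education2")
  )
  expect_lt(an$p_value[an$term == "age:education2"], 0.01)
  expect_lt(an$p_value[an$term == "age"], 1e-10)
})

test_that("zero-variance outcome is flagged, not silently summarized", {
  d <- tibble::tibble(
    age = rep(20:29, 4),
    gender = factor(rep(c("female", "male"), 20),
                    levels = c("female", "male")),
    education2 = factor(rep(c("secondary_and_lower", "tertiary"), each = 20),
                        levels = c("secondary_and_lower", "tertiary")),
    wf = 0
  )
  expect_warning(anova_main_effects(d), "zero variance")
})

test_that("fixed interaction model flags cross-country heterogeneity", {
  set.seed(36)
  n <- 4000
  d <- tibble::tibble(
    age = sample(19:70, 2 * n, TRUE),
    gender = factor(sample(c("female", "male"), 2 * n, TRUE),
                    levels = c("female", "male")),
    education2 = factor(sample(c("secondary_and_lower", "tertiary"), 2 * n,
                               TRUE),
                        levels = c("secondary_and_lower", "tertiary")),
    country = rep(c("AA", "BB"), each = n)
  )
  # opposite education effects in the two countries
  slope <- ifelse(d$country == "AA", 0.3, -0.3)
  d$wf <- slope * (d$education2 == "tertiary") + rnorm(2 * n)
  an <- fixed_interaction_model(d)
  expect_lt(an$p_value[an$term == "education2:country"], 1e-6)
  eff <- attr(an, "country_effects")
  expect_equal(eff$slope[eff$country == "AA"], 0.3, tolerance = 0.1)
  expect_equal(eff$slope[eff$country == "BB"], -0.3, tolerance = 0.1)
  expect_error(fixed_interaction_model(dplyr::filter(d, country == "AA")),
               class = "wayfindr_invalid_argument")
})

test_that("slope-indicator correlation: identity, degeneracy, arity", {
  slopes <- tibble::tibble(group = letters[1:5], slope = c(1, 2, 3, 4, 5))
  ident <- tibble::tibble(group = letters[1:5], value = c(1, 2, 3, 4, 5))
  res <- correlate_slopes_with_indicator(slopes, ident)
  expect_equal(res$r, 1)
  expect_lt(res$p_value, 1e-8)
  expect_equal(res$n, 5)
  expect_error(
    correlate_slopes_with_indicator(
      slopes, dplyr::mutate(ident, value = 1)),
    class = "wayfindr_degenerate_input"
  )
  expect_error(
    correlate_slopes_with_indicator(slopes[1:2, ], ident[1:2, ]),
    class = "wayfindr_invalid_argument"
  )
})
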
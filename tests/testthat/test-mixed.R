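test_that("identical groups receive identical education slopes", {
  set.seed(51)
  block <- tibble::tibble(
    age = sample(19:70, 200, TRUE),
    gender = factor(sample(c("female", "male"), 200, TRUE),
                    levels = c("female", "male")),
    education2 = factor(rep(c("secondary_and_lower", "tertiary"), 100),
                        levels = c("secondary_and_lower", "tertiary"))
  )
  block$wf <- 0.2 * (block$education2 == "tertiary") -
    0.02 * block$age + rnorm(200)
  d <- dplyr::bind_rows(
    dplyr::mutate(block, country = "AA"),
    dplyr::mutate(block, country = "BB"),
    dplyr::mutate(block, country = "CC")
  )
  fit <- suppressWarnings(fit_education_slopes(d, group = "country"))
  expect_equal(length(unique(round(fit$slopes$slope, 10))), 1)
})

test_that("injected country slope offsets are recovered in order", {
  cts <- tibble::tibble(country = c("AA", "BB", "CC"), weight = 1 / 3,
                        slope_offset = c(-0.1, 0, 0.1), intercept = 0)
  cfg <- generator_config(n_participants = 30000, countries = cts,
                          country_slope_sd = 0, seed = 52)
  pop <- sample_population(cfg)
  pop$education2 <- merge_education(pop$education4)
  fit <- suppressWarnings(
    fit_education_slopes(pop, outcome = "latent_skill", group = "country")
  )
  sl <- fit$slopes[order(fit$slopes$country), ]
  injected <- 0.10 + c(-0.1, 0, 0.1)
  expect_true(all(abs(sl$slope - injected) < 0.05))
  expect_equal(order(sl$slope), 1:3)
  expect_true(all(sl$se > 0))
})

test_that("group prerequisites are enforced", {
  d <- tibble::tibble(
    age = rep(30, 40), gender = factor(rep(c("female", "male"), 20)),
    education2 = factor(rep("tertiary", 40),
                        levels = c("secondary_and_lower", "tertiary")),
    country = rep(c("AA", "BB", "CC", "DD"), 10), wf = rnorm(40)
  )
  expect_error(fit_education_slopes(d, group = "country"),
               class = "wayfindr_invalid_argument")  # one class only
  d2 <- dplyr::mutate(d, country = rep(c("AA", "BB"), 20))
  expect_error(fit_education_slopes(d2, group = "country"),
               class = "wayfindr_invalid_argument")  # too few groups
})

test_that("per-level outcomes preserve the difficulty scaling", {
  res <- scored_cohort(generator_config(
    n_participants = 3000, countries = single_country(),
    beta_education = 0.6, country_slope_sd = 0, seed = 53
  ))
  long <- level_outcomes(res$scored, res$data$trajectories, res$data$levels)
  expect_true(all(c("level_id", "outcome", "education2") %in% names(long)))
  expect_true(all(long$outcome < 0))

  fit <- suppressWarnings(
    fit_education_slopes(long, outcome = "outcome", group = "level_id")
  )
  slopes <- fit$slopes
  names(slopes)[1] <- "group"
  diff <- difficulty_table(res$data$trajectories, res$data$levels)
  indicator <- tibble::tibble(group = as.character(diff$level_id),
                              value = diff$difficulty)
  cr <- correlate_slopes_with_indicator(slopes, indicator)
  # harder levels separate the education classes more
  expect_gt(cr$r, 0.5)
})

test_that("broom-style accessors expose the fit", {
  cts <- tibble::tibble(country = c("AA", "BB", "CC"), weight = 1 / 3,
                        slope_offset = 0, intercept = 0)
  cfg <- generator_config(n_participants = 3000, countries = cts,
                          country_slope_sd = 0.05, seed = 54)
  pop <- sample_population(cfg)
  pop$education2 <- merge_education(pop$education4)
  fit <- suppressWarnings(
    fit_education_slopes(pop, outcome = "latent_skill", group = "country")
  )
  td <- tidy(fit)
  expect_equal(names(td), c("group", "estimate", "std.error"))
  expect_equal(nrow(td), 3)
  gl <- glance(fit)
  expect_true(all(c("slope_sd", "singular", "AIC", "n_groups") %in% names(gl)))
  expect_s3_class(autoplot(fit), "ggplot")
})
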
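toy_study <- function() {
  participants <- tibble::tibble(
    participant_id = sprintf("P%d", 1:6),
    age = c(75L, 80L, 30L, 40L, 50L, 70L),
    gender = factor(c("male", "female", "male", "female", "male", "female"),
                    levels = c("female", "male")),
    education4 = factor(
      c("university", "college", "high-school",
        "university", "high-school", "college"),
      levels = c("university", "college", "high-school", "no formal")
    ),
    country = c("AA", "AA", "ZZ", "AA", "AA", "AA"),
    birth_year = 2016L - c(75L, 80L, 30L, 40L, 50L, 70L)
  )
  lv <- toy_levels()
  # everyone played all 6 levels except P1, who stopped before level 11
  traj <- tidyr::crossing(participant_id = participants$participant_id,
                          level_id = lv$level_id) |>
    dplyr::filter(!(participant_id == "P1" & level_id == 11L)) |>
    dplyr::mutate(trajectory_length = 100)
  crit <- inclusion_criteria(min_levels_completed = 6,
                             min_wayfinding_completed = 4,
                             max_age = 70, min_country_n = 2,
                             max_education_imbalance = 10)
  list(participants = participants, trajectories = traj, levels = lv,
       criteria = crit)
}

test_that("education merging maps the four labels onto the two classes", {
  expect_equal(as.character(merge_education("university")), "tertiary")
  expect_equal(as.character(merge_education("college")), "tertiary")
  expect_equal(as.character(merge_education("high-school")),
               "secondary_and_lower")
  expect_equal(as.character(merge_education("no formal")),
               "secondary_and_lower")
  expect_equal(levels(merge_education("university")),
               c("secondary_and_lower", "tertiary"))
  expect_error(merge_education("primary"), class = "wayfindr_invalid_value")
})

test_that("inclusion filter stages match the hand-enumerated toy cohort", {
  s <- toy_study()
  res <- apply_inclusion(s$participants, s$trajectories, s$levels, s$criteria)
  # P1 drops at completeness (missing level 11; also over-age), P2 at the
  # age cap, P3 at the country filter (alone in ZZ)
  expect_equal(res$report$stages$n, c(6L, 5L, 4L, 3L))
  expect_setequal(res$cohort$participant_id, c("P4", "P5", "P6"))
  expect_true("education2" %in% names(res$cohort))
})

test_that("disabling thresholds leaves only the completeness filter", {
  s <- toy_study()
  loose <- inclusion_criteria(min_levels_completed = 6,
                              min_wayfinding_completed = 4,
                              max_age = Inf, min_country_n = 0,
                              max_education_imbalance = Inf)
  res <- apply_inclusion(s$participants, s$trajectories, s$levels, loose)
  expect_setequal(res$cohort$participant_id,
                  setdiff(s$participants$participant_id, "P1"))
})

test_that("filtering is idempotent and independent of row order", {
  s <- toy_study()
  res1 <- apply_inclusion(s$participants, s$trajectories, s$levels,
                          s$criteria)
  again <- apply_inclusion(res1$cohort, s$trajectories, s$levels, s$criteria)
  expect_setequal(again$cohort$participant_id, res1$cohort$participant_id)

  perm <- s$participants[c(4, 2, 6, 1, 3, 5), ]
  res2 <- apply_inclusion(perm, s$trajectories, s$levels, s$criteria)
  expect_setequal(res2$cohort$participant_id, res1$cohort$participant_id)
  expect_equal(res2$report$stages$n, res1$report$stages$n)
})

test_that("country thresholds act on the already-filtered cohort", {
  s <- toy_study()
  # BB has 2 players before filtering but only 1 under the age cap,
  # so it must fall below min_country_n = 2
  extra <- s$participants[1:2, ]
  extra$participant_id <- c("P7", "P8")
  extra$age <- c(30L, 80L)
  extra$birth_year <- 2016L - extra$age
  extra$country <- "BB"
  parts <- dplyr::bind_rows(s$participants, extra)
  traj <- dplyr::bind_rows(
    s$trajectories,
    tidyr::crossing(participant_id = c("P7", "P8"),
                    level_id = s$levels$level_id) |>
      dplyr::mutate(trajectory_length = 100)
  )
  res <- apply_inclusion(parts, traj, s$levels, s$criteria)
  expect_false("BB" %in% res$cohort$country)
  bb <- dplyr::filter(res$report$countries, country == "BB")
  expect_equal(bb$n, 1L)
  expect_false(bb$eligible)
})

test_that("country eligibility arithmetic: ratios and degenerate classes", {
  cohort <- tibble::tibble(
    country = rep(c("AA", "BB", "CC"), times = c(500, 300, 40)),
    education2 = factor(
      c(rep("tertiary", 400), rep("secondary_and_lower", 100),
        rep("tertiary", 300),
        rep(c("tertiary", "secondary_and_lower"), 20)),
      levels = c("secondary_and_lower", "tertiary")
    )
  )
  ce <- country_eligibility(cohort, min_country_n = 500, max_imbalance = 10)
  aa <- dplyr::filter(ce, country == "AA")
  expect_equal(aa$imbalance, 4.0)
  expect_true(aa$eligible)
  bb <- dplyr::filter(ce, country == "BB")
  expect_equal(bb$imbalance, Inf)
  expect_false(bb$eligible)
  cc <- dplyr::filter(ce, country == "CC")
  expect_equal(cc$imbalance, 1.0)
  expect_false(cc$eligible)  # balanced but too small
})

test_that("degenerate inputs: empty tables pass through, bad schemas error", {
  s <- toy_study()
  res <- apply_inclusion(s$participants[0, ], s$trajectories[0, ], s$levels,
                         s$criteria)
  expect_equal(nrow(res$cohort), 0)
  expect_equal(res$report$stages$n, rep(0L, 4))
  expect_error(
    apply_inclusion(dplyr::select(s$participants, -age), s$trajectories,
                    s$levels, s$criteria),
    class = "wayfindr_schema_error"
  )
})
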
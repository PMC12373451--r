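# wayfindr

Education is associated with many cognitive abilities, spatial navigation
among them — but the association is confounded by everything that travels
with educational attainment (socioeconomic status, country, cohort).
`wayfindr` packages the full analysis chain used to study this question in
large mobile-game navigation cohorts, from raw per-level trajectory lengths
to a causal regression-discontinuity estimate built on a school-leaving-age
reform, together with a synthetic cohort generator so every stage can be
developed and tested without access to restricted player data.

## What it computes

**Wayfinding performance (WF).** For each player, per-level trajectory
lengths (pixels) are divided by the sum of their two tutorial-level lengths
(tutorials demand only motor control, so the ratio removes video-gaming
skill). WF is the first principal component of the column-standardized
normalized lengths of wayfinding levels 6, 7, 8 and 11, oriented so that
higher WF = shorter trajectories = better navigation.

**Cohort filtering.** The study inclusion rules: ≥ 11 completed levels
(≥ 4 wayfinding), complete demographics, age ≤ 70, countries with ≥ 500
retained players and merged education classes at most 10-fold imbalanced.
Education is merged as {university, college} → tertiary and {high-school,
no formal} → secondary-and-lower.

**Association analyses.** Hedge's g (bias-corrected standardized mean
difference) with 95% CIs, overall and in 5-year age windows; Type II ANOVA
of `WF ~ age * gender * education`; default (JZS) Bayes factors; linear
mixed models with random education slopes by country
(`WF ~ age + gender + education + (1 + education | country)`, ML
estimation) and by level, whose slopes are correlated with country
indicators or with level difficulty
`(median TL − min TL) / min TL`.

**Causal analysis.** Sharp regression discontinuity around the first birth
cohort bound by the 1972 UK reform that raised the school-leaving age from
15 to 16 (first affected cohort born 1957):
`WF ~ 1 + birthyear + 1[birthyear ≥ c]`, with `c` swept over 1952–1962;
the two-line pre/post gap ΔWF at the reform cohort, rescaled to IQ points
(ΔWF / SD(WF) × 15); and a placebo sweep on the motor-control training
score, which education should not affect.

**Synthetic cohorts.** `generator_config()` + `simulate_cohort()` draw
demographically structured populations with an age-related decline in
latent skill, a male advantage, a tertiary-education advantage that grows
with age and with level difficulty, country-level slope heterogeneity, and
an optional reform discontinuity acting on the latent skill of compliers.

## Worked example

```r
library(wayfindr)

# cross-country association analysis on a synthetic cohort
cfg <- run_config(seed = 42,
  generator = generator_config(n_participants = 50000),
  analyses = list(effects = TRUE, country_slopes = TRUE,
                  difficulty = FALSE, rdd = FALSE))
report <- run_pipeline(cfg)
report
#> wayfindr pipeline report (seed 42 )
#>   cohort: 50000 scored participants; cor(age, wf) = -0.353; sd(wf) = 1.994
#>   education g = 0.090 [0.071, 0.109]; gender g = 0.458

tidy(report$effects$anova)[1:3, ]
#>   term       statistic    df df.residual  p.value
#> 1 age            7571.     1       49992 0
#> 2 gender         2997.     1       49992 0
#> 3 education2      107.     1       49992 3.67e-25

dplyr::arrange(report$country_slopes$slopes, slope)
#>   country   slope     se
#> 1 IN      -0.0571 0.0561
#> 2 RO       0.116  0.0664
#> 3 NL       0.189  0.0637
#> # 5 more rows
```

Age dominates (negative correlation ≈ −0.35), males outperform females by
g ≈ 0.46, tertiary education carries a positive but much smaller advantage,
and the education slope varies across countries (near zero in the
lowest-slope country).

```r
# reform discontinuity on a UK-like birth-cohort window
gain <- calibrate_complier_gain(target_sd_step = 0.06 / 1.125, seed = 99)
uk <- simulate_scored_cohort(
  reform_study_config(41754, seed = 42, complier_skill_gain = gain))

sweep <- sweep_cutoffs(uk, center_year = 1957, halfwidth = 5)
glance(sweep)
#>   best_cutoff center_year max_estimate statistic  p.value outcome
#> 1        1957        1957        0.138      3.59 0.000328 wf

pre_post_gap(dplyr::filter(uk, abs(birth_year - 1957) <= 5), cutoff = 1957)
#> Pre/post gap at 1957 (wf): pre -0.094 [-0.185, -0.004], post 0.031 [-0.032, 0.093]
#>   delta = 0.1250  (0.95 IQ points at SD 1.975); n = 9849 + 11937
```

The discontinuity coefficient peaks at the first reform-affected cohort
(1957), and the extrapolated pre/post gap corresponds to roughly one IQ
point per extra school year — the order of magnitude reported by
meta-analyses of schooling effects on cognition. `autoplot(sweep)` and
`autoplot(gap, window_data)` draw the corresponding figures.

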
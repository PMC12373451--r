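---
title: "Methods: wayfinding performance, education effects, and the reform discontinuity"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: wayfinding performance, education effects, and the reform discontinuity}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(wayfindr)
```

`wayfindr` implements an analysis chain for studying how education relates
to spatial wayfinding measured from navigation-game trajectories: a
composite performance score, cohort inclusion rules, effect-size and
mixed-model association analyses, and a regression-discontinuity causal
analysis built on a school-leaving-age reform. This vignette explains each
model, the tunable parameters and why their defaults are what they are,
the numerical conventions, and what the synthetic-data tests do and do not
establish.

## The wayfinding performance composite

The raw measurement is one trajectory length per player and level, in
pixels (the summed point-to-point Euclidean distance of the path; shorter
is better). Two transformations turn lengths into a performance score:

1. **Tutorial normalization.** Each wayfinding length is divided by the sum
   of the player's two tutorial-level lengths. Tutorials require no
   wayfinding — only steering — so the ratio removes motor/device skill.
   In the generator this is exact by construction: the motor-skill factor
   multiplies every level and cancels in the ratio.
2. **First principal component.** WF is the first principal component of
   the normalized lengths of wayfinding levels 6, 7, 8, 11 (the earliest
   four, where sample size is largest; the set is configurable). We compute
   the PCA on *column-standardized* data (the correlation convention):
   levels differ in physical size, and standardization is the guarantee
   that a large level cannot dominate the composite. PC1 scores are used
   as returned by the eigendecomposition, so SD(WF) equals the square root
   of the leading eigenvalue (close to 2 when four columns are strongly
   correlated) — effect sizes reported as Hedge's g or in SD units are
   unaffected by this scale.

**Sign convention.** Raw lengths load positively on PC1 (longer = worse),
so the component is flipped to satisfy `cor(WF, mean normalized length) < 0`:
higher WF = better navigation. If that correlation is exactly zero (a
degenerate matrix), the orientation with a positive first loading is used
as a deterministic tie-break. Constant columns are an error, not a silent
drop. No log-transform is applied to lengths.

The **training performance** control score is the sum over the two
tutorials of `length / (cohort minimum at that level)`; its floor is 2,
attained by a player holding the record at both tutorials. It reflects
motor skill only and serves as the placebo outcome later.

**Level difficulty** is `(median TL − min TL) / min TL` over all players at
a level: the typical player's excess over the (near-optimal) best path,
normalized so larger levels are not counted as harder merely for being
larger. It is scale-invariant and zero only when the median equals the
minimum.

## Inclusion rules

Filtering runs once, in a fixed order: (1) completeness — at least 11
distinct completed levels including 4 wayfinding levels, and full
demographics (no imputation; missingness always excludes); (2) age — players
*above* 70 are removed (70 itself stays), because volunteer self-selection
makes older players unrepresentative; (3) country — computed on the already
filtered set, countries with fewer than 500 retained players or with merged
education classes more than 10-fold imbalanced (ratio strictly > 10, on the
two merged classes) are dropped, with no iteration to a fixed point. The
audit report records the count after each stage and the per-country
eligibility table.

Education is observed in four classes (university, college, high-school,
no formal) and merged to tertiary vs secondary-and-lower for analysis:
"college" is not comparable across countries, and the no-formal class is
too small and selection-prone to stand alone. The 4-class labels are kept
in the tables so the supplementary 4-level analysis remains possible.

## Association analyses

**Hedge's g.** `g = J (m_a − m_b) / s_pooled` with
`J = 1 − 3/(4(n1+n2−2) − 1)`; the default CI is the normal approximation
`g ± 1.96 SE`, `SE² = (n1+n2)/(n1 n2) + g²/(2(n1+n2−2))` — simple,
standard, and exactly testable against a closed form. An exact
noncentral-t interval is available via `ci_method = "noncentral_t"`; the
two agree to ~1% at the sample sizes involved here. Age profiles use
left-closed 5-year windows anchored at the cohort minimum age, labelled by
their midpoint; windows with fewer than 2 players in either class are
omitted with a message.

**ANOVA.** `WF ~ age * gender * education` (continuous age), summarized
with Type II F tests: main effects are tested after the other main
effects, independent of term order, which matches reporting single
main-effect F values from a model that also carries interactions.
Sequential Type I tests are available behind a flag for comparison.
Gender is coded with female as the reference level, so positive
coefficients mean a male advantage; education with secondary-and-lower as
reference, so positive means a tertiary advantage.

**Bayes factors.** The two-sample default (JZS) Bayes factor with a Cauchy
prior of scale √2/2 on the standardized effect, computed by adaptive
quadrature of the g-mixture integral in log space. Published analyses of
this design do not state their BF method, so printed Bayes factors from
such studies are not reproduction targets; the JZS convention is fixed
here and tested against an independent noncentral-t × Cauchy quadrature.

**Random education slopes.** The cross-country model is
`WF ~ age + gender + education + (1 + education | country)`, maximum
likelihood (not REML), unstructured 2×2 random covariance. The reported
per-country effect is the fixed education coefficient plus the country's
BLUP slope deviation; its SE combines the fixed coefficient's sampling
variance with the BLUP conditional variance (ignoring their covariance — a
documented approximation). A singular random-effects estimate warns but
keeps the fit; optimizer non-convergence is an error carrying the
diagnostics. The same per-country effects are also available from the
fixed-effects interaction model `WF ~ age + gender + education * country`
(as base coefficient + interaction contrast), since group-level effect
displays can be built either way.

**Slopes by level.** For the difficulty analysis the grouping is the level,
and the outcome is the per-(participant, level) *negated normalized length*
— deliberately not z-scored per level. Harder levels stretch trajectories
(and their education gradient) more, and that scale difference is exactly
the difficulty modulation the model measures; per-level standardization
would divide it out and flatten every slope to a common signal-to-noise
ratio. Slopes are then correlated (Pearson, t-based p on n−2 df) with the
difficulty statistic.

## The reform discontinuity

The natural experiment is the UK 1972 reform raising the minimum
school-leaving age from 15 to 16; the first birth cohort bound by it was
born 1957. The sharp RDD model is

```
WF ~ 1 + (birthyear − c) + 1[birthyear ≥ c]
```

Centering birth year at the cutoff makes the dummy coefficient the jump at
the cutoff; an uncentered parameterization changes only the intercept, not
the estimate. Players born exactly in the cutoff year are on the post side.
The cutoff `c` sweeps the integer years 1952–1962 (center ± 5); the data
window is center ± 10 birth years, twice the grid half-width, so every
candidate cutoff has cohorts on both sides — consistent with the oldest
in-window participants being in their 69th year at the 2016 collection. If
the reform is causal the coefficient should peak at 1957: misplacing the
cutoff leaks part of the jump into the trend and attenuates it.

The **pre/post gap** fits two *free* regression lines (separate slopes) on
either side of 1957 within the ±5-year window and evaluates both at the
cutoff; ΔWF is their difference, with CIs from each line's prediction SE.
The single-slope `fit_rdd` model remains the formal test; the two-line gap
is the descriptive counterpart. ΔWF is rescaled to IQ points as
`ΔWF / SD(WF) × 15`, with SD(WF) computed on the window cohort by default
(the gap is estimated there; a whole-cohort SD can be supplied).

The **placebo** repeats the sweep with training performance as outcome.
Education should not move motor skill, so a significant placebo
discontinuity would flag a cohort artifact rather than a causal education
effect.

## The synthetic cohort generator

Latent wayfinding skill is

```
s = β_age (age − 40) + β_gender 1[male]
    + (β_edu + β_age×edu (age − 40) + u_country) 1[tertiary]
    + a_country + ε,   ε ~ N(0, σ²)
```

with ages integer-uniform on [19, 70], birth year = 2016 − age (the
collection year; fractional birth dates ignored), education drawn in four
classes with the 42/28/27/3 composition and merged downstream, and
`age_ref = 40` so `β_edu` is the mid-life effect. Trajectory lengths are

```
tutorial:    length = min_length · motor
wayfinding:  length = min_length · motor · (1 + difficulty · softplus(κ − s + ε_level))
```

with `motor` log-normal (lengths stay positive), `ε_level ~ N(0, 0.1²)`
per observation, and κ = 5 a positive shift inside the softplus link. The
link must be strictly positive (lengths never undercut the minimal path)
and decreasing in skill (better navigators take stochastically shorter
paths); any such link is admissible, and the shifted softplus is chosen
because it keeps the link in its near-linear regime over the bulk of the
skill distribution, so a standardized effect injected on the latent scale
survives the length → normalization → PCA chain essentially unchanged (the
package's calibration tests verify recovery of an injected education g
through the full pipeline). As skill → ∞ the inflation still vanishes and
lengths approach the minimum.

Default effect sizes are calibrated analytically to the structure reported
for large navigation-game cohorts: `β_age = −0.027` and `σ = 1` give an
age–WF correlation near −0.36 over ages 19–70; `β_gender = 0.48` gives a
male advantage near g = 0.44; `β_edu = 0.10` with
`β_age×edu = 0.0019` puts the education effect near g = 0.05 at age 20
rising to ≈ 0.14 at 65. (Those published numbers are internally tense —
the overall education g is quoted as high as its oldest age window — so
the defaults prioritize the age profile; the resulting overall g is
≈ 0.07–0.09.) The default country table spans a near-zero-to-modest range
of education-slope offsets (lowest in the IN row, highest in RO/NL),
plus `country_slope_sd = 0.03` of additional random heterogeneity.

A reform is injected by giving a `complier_fraction` (default 0.3) of
would-be early leavers — players without tertiary education, in the reform
country, born in or after the first affected year — an additive latent
gain. The education *label* does not change: the reform moved the leaving
age between two points below the tertiary threshold, so the discontinuity
must be detectable within observed education classes.
`calibrate_complier_gain()` converts a target mean jump in SD(WF) units to
the per-complier latent gain using a fixed-seed null calibration cohort.

One master seed drives everything; per-stage streams are derived
deterministically from it, so a configuration byte-identically determines
all tables and reports.

## Simulation designs used by the tests

The packaged checks run at these problem sizes (chosen to make each
quantity's sampling error small relative to what it demonstrates):
formula-level oracles on fixtures up to 50 × 4 (agreement 1e-8 to 1e-10);
ANOVA size under the null at 400 datasets of n = 2,000 (rejection rate
expected in [0.02, 0.08] at α = 0.05); country-slope recovery of injected
offsets {−0.1, 0, +0.1} at n = 100,000 over 10 seeds, on the latent scale
— WF is an affine rescaling of latent skill with an arbitrary PCA scale,
so "recovery within ±0.03" is only meaningful on the scale the offsets
were injected on, while ordering, sign and the scale-free Hedge's g are
checked on WF itself; and discontinuity studies at n ≈ 40,000 with a
0.05-SD step over 50 seeds. On that last design, note the arithmetic: the
jump estimator's SE is ≈ 0.02 SD, so a 0.05-SD step yields t ≈ 2.5 and the
argmax over an 11-cutoff grid lands on the true year only about two thirds
of the time — single-dataset cutoff localization at such step sizes is
suggestive, not guaranteed, and a larger step or sample localizes sharply.
The null half is stable: absent a reform, |t| > 3 anywhere on the grid is
rare.

## What the synthetic data do and do not show

The generator reproduces the *statistical skeleton* the analyses assume:
monotone age decline, additive gender and education effects on a latent
scale, country heterogeneity of the education slope, difficulty-scaled
trajectory inflation, and a reform acting on compliers' skill. Passing
tests therefore demonstrate that the estimators recover what the model
injects, at realistic sizes and noise. They do not validate the
substantive claims on real players: the generator has uniform ages (real
cohorts skew young), no participation selection (the real over-70 bias is
the *reason* for the age cap, not a feature of the data), no missingness,
linear age trends, Gaussian latent noise, a single reform in one country,
and education independent of country and age apart from the injected
terms. Conclusions about real cohorts require the real tables, loaded via
`read_cohort_tables()` into exactly the same pipeline.

## Known limitations

- The BLUP slope SEs ignore the fixed–random covariance term.
- The JZS Bayes factor is fixed at scale √2/2; other conventions will give
  other numbers.
- The composite requires complete data on the tutorial and composite
  levels; players missing any are dropped (with a count), not imputed.
- `fit_rdd` assumes a common linear trend across the cutoff; the two-line
  gap relaxes the slope but still extrapolates linearly.
- WF's absolute scale is a PCA artifact; only standardized or SD-relative
  quantities should be compared across datasets. By default WF is computed
  once on the full cohort (the discontinuity window inherits those
  scores); refitting the PCA within a subsample is possible but changes
  the scale.
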
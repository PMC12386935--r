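---
title: "Age-stage, two-sex life table methods in agestage"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Age-stage, two-sex life table methods in agestage}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(agestage)
```

## The model

`agestage` implements the age-stage, two-sex life table for insect cohorts
reared individually and censused once per day. The raw data are one row per
individual per day alive: age `x` (day 0 = oviposition), the developmental
stage occupied that day (egg, larval instars, pupa, adult female or adult
male), and the eggs laid that day. Because both sexes and variable
developmental rates are retained, stage overlap between ages is represented
explicitly rather than collapsed to a female-only age classification.

From a cohort of `n` eggs the package computes:

* **Age-stage survival** `s_xj = n_xj / n`, the probability a newborn is alive
  in stage `j` at age `x`; **age-specific survival** `l_x = sum_j s_xj`.
* **Fecundity** `f_xj` (eggs per living adult female at age `x`), `m_x =
  sum_j s_xj f_xj / l_x` and the net maternity `l_x m_x`.
* **Net reproductive rate** `R0 = sum_x l_x m_x`. Because every egg laid is
  attributed to the day it was laid, `R0` equals `(N_f / N) *` (mean lifetime
  fecundity per adult female) *exactly*, an identity the test suite asserts on
  every cohort.
* **Intrinsic rate of increase** `r`, the unique root of the discrete
  Euler–Lotka equation `sum_x exp(-r (x + 1)) l_x m_x = 1`. The `x + 1`
  exponent reflects ages counted from 0 with reproduction credited at the end
  of the day; the convention is pinned by the trivial case `l_0 m_0 = 1  =>
  r = 0`. The left-hand side is strictly decreasing in `r`, so bisection on
  `[-1, 2]` (tolerance 1e-12, at most 200 iterations) finds the root with
  residual below 1e-10. **Finite rate** `lambda = exp(r)`; **mean generation
  time** `T = ln(R0) / r`, reported as missing when `R0 <= 0` or `r = 0`.
* **Life expectancy** `e_xj` and **reproductive value** `v_xj`, computed from
  the empirical daily transition model (below). Two identities anchor them:
  `e_0,EGG` equals the cohort mean total longevity, and `v_0,EGG = lambda`.
  Both are asserted at 1e-9 on every generated cohort.

## The empirical transition model

For every occupied age-stage cell `(x, j)` the cohort itself defines the
daily transition probabilities: the observed fractions of its occupants that
are, one day later, still in `j`, in a later stage `j'` (skipping only
supernumerary instars or the alternative adult stage), or dead. Rows sum to
one exactly, and propagating the full cohort mass forward through the model
reproduces `s_xj` exactly — so life expectancy, reproductive value and the
population projection are all mutually consistent with the observed
schedules.

`e_xj` is defined by propagating unit mass forward from `(x, j)` and summing
the surviving mass over all later ages (the current day included, so
`e_xj >= 1`). The implementation uses the equivalent backward recursion
`e_xj = 1 + sum_y P(x, j -> y) e_{x+1,y}`; the forward formulation is kept in
the test suite as an independent oracle, and the two agree to 1e-9 cell by
cell. `v_xj` follows the same pattern with the discounted future reproduction
`exp(-r (i + 1)) f_iy` accumulated along the way. A formulation found in parts
of the literature divides by `s_xj` while starting the forward propagation at
`s_xj`; the two factors cancel, and the cancelled form is what is implemented.

## Population projection

`project_population()` iterates the transition model as an expected-value
recursion from an initial egg pile (default 10 eggs, 120 days): mass in
`(x, j)` splits per the model into `(x+1, ·)` or death, and the eggs laid by
adult females on day `t` enter the `(0, EGG)` cell on day `t + 1`. Fractional
individuals are intentional; a stochastic individual-based mode
(`stochastic = TRUE`) exists for cross-validation only. Mass balance —
alive(t+1) = alive(t) − deaths + births — holds to floating-point precision
at every step.

The projection's asymptotic growth rate equals the cohort's `r` (the renewal
equation of the recursion *is* the Euler–Lotka equation), but convergence
happens through damped generation cycles whose decay rate scales roughly with
`sigma^2 / T^3`, where `sigma` is the spread of reproduction and `T` the
generation time. Two practical consequences, both visible in the tests:

* For cohorts like the fall-armyworm presets (`T` near 32 d, reproduction
  concentrated in a 1–2 week burst) the cycle has *not* decayed by day 120;
  the measured log-slope still deviates from `r` by around 1e-2.
* For a fast-turnaround cohort (`T` near 17 d, broad reproduction) the slope
  measured by `projection_growth_rate(window = 2T, period = T)` — an OLS fit
  of `log N(t)` with one cosine/sine pair at the generation period as
  nuisance regressors — is within 1e-3 of `r` by day 120. This is the
  configuration the asymptotic-growth acceptance test uses.

Generations within a projection are delimited by local minima of the daily
egg influx (the egg-wave convention); the test suite checks qualitatively
that a FAW-like cohort completes at least two egg waves in 120 days.

## Bootstrap inference

All parameter uncertainty comes from resampling whole individuals (life
histories) with replacement, preserving within-individual correlation between
development, survival and reproduction. The default is B = 100,000 resamples,
matching common practice for these life tables; tests and examples use
1,000–10,000, which this implementation completes in well under a second via
a crossproduct formulation (per-individual summary matrices multiplied by a
matrix of resample counts; the Euler–Lotka root is found by bisection
vectorised across resamples). Resamples in which a parameter is undefined —
no females, hence no reproduction, hence no `r` — are recorded as missing and
counted, not silently dropped into the estimate.

The paired bootstrap test draws B independent resample pairs from two
cohorts and reports the two-sided percentile p-value with add-one
correction, `p = 2 min(#(d > 0) + 1, #(d < 0) + 1) / (B + 1)`, capped at 1;
the add-one form keeps `p >= 2 / (B + 1)` even when the difference
distribution is entirely one-signed. The tail rule is a package choice (the
common software leaves it unstated). No multiplicity adjustment is applied
across parameters or cohort pairs; with more than two cohorts, adjust the
pairwise p-values as appropriate for the design.

Projection uncertainty (`projection_band()`) refits the transition model and
fecundity schedule on each cohort resample and reprojects; the 2.5/97.5
percentiles of `N(t)` per day form the band, and non-overlap of two cohorts'
bands is the criterion for declaring their growth different.

## Preference assays and the Quade test

Bi-choice feeding data are corrected for evaporation: consumption =
`before * (1 - control_loss_fraction) - after`, floored at zero (with a
warning when the floor binds). Preference per replicate is each choice's
share of the replicate total (consumption or egg batches); zero-total
replicates are excluded with a reported count. Because the source assays are
ambiguous about replicates in which only one choice was consumed, both
inclusion rules are first-class: `all_nonzero` (default) and
`both_consumed`.

`quade_test()` implements the randomized-block test from first principles:
within-block mid-ranks `r_ij`, block ranges ranked with mid-ranks `Q_i`,
`S_ij = Q_i (r_ij - (k+1)/2)`, `A = sum S^2`, `B = sum_j S_j^2 / b`, statistic
`(b-1) B / (A - B)` against `F(k-1, (b-1)(k-1))`. `stats::quade.test` serves
as the independent oracle in the tests (agreement to 1e-12), and an
exhaustive permutation oracle validates the exact mode. Degeneracies are
flagged rather than mis-tested: a constant matrix returns p = 1, and perfect
concordance (`A = B`, which requires identical rank patterns *and* tied block
ranges) falls back to the exact permutation p-value when `(k!)^b` is
enumerable and to the closed form `2 (1/k!)^(b-1)` otherwise. Simulated
type-I error at b = 12, k = 2 sits within [0.03, 0.07] at the 0.05 level
over 5,000 null draws.

## The synthetic cohort generator

No raw rearing records are published for the study system this package was
validated against, so `generate_cohort()` supplies cohorts with the right
*structure*: gamma-distributed stage durations discretised to whole days
(floor 1 day), per-day geometric mortality within pre-adult stages, optional
supernumerary 7th/8th instars, sex assigned at emergence, an adult
pre-oviposition period, and a lifetime egg total spent along a log-normal
shaped daily curve from first oviposition until death. Fertile females draw
their adult longevity conditional on exceeding their APOP, so every fertile
female lays her full total — which is what makes the ground truth exact.

`ground_truth()` computes, by direct numerical integration over the
configured distributions (no simulation), the generator's exact `R0 =
sex_ratio x preadult_survival x fertile_prob x E[eggs]`, its expected
net-maternity schedule, and the `r` solving Euler–Lotka on that schedule. On
a mortality-free cohort of 20,000 individuals the life-table estimate of `r`
matches this truth within 1e-3; at the realistic n = 80 the median absolute
error over 50 replicates is below 0.005 /d, comfortably inside the 0.02 /d
recovery criterion.

Preset choices: `"corn-like"` and `"jobs-tears-like"` emulate the published
envelope of fast- and slow-developing host-plant cohorts (mean pre-adult
duration 25.5–32.5 d; mean fecundity 278–1055 eggs per female; supernumerary
fractions 0 and 0.61; sex ratios and fertility fractions from the printed
counts). Where the tables give only means ± SEs, the gamma family and its
dispersions are modelling choices. `"faw-default"` is the validation preset
(n = 80, sex ratio 0.4, mean fecundity 700, pre-adult survival 0.7 — its
exact computed value is 0.699). Egg durations print as 2 d in some published
cohorts and 3 d in others (batch-level rounding, most likely); the generator
leaves egg duration a per-preset knob rather than resolving this.

What a green test does **not** establish: the generator draws individuals
independently (no container or batch effects), applies no censoring or
handling losses, gives males no role in reproduction (no mating-limitation),
and holds parameters constant within a cohort. Real rearing data violate all
four to some degree; the generator validates the *estimators*, not the
biology.

## Numerical and design choices

* Age convention: age 0 = oviposition day; one census per day; an
  individual's last record is its last day alive and `death_age` is that age
  plus one. Censoring is not supported and is rejected at validation.
* Individuals dying before adulthood carry sex `unknown` and contribute to
  pre-adult schedules only.
* Stage-duration summaries include only individuals that completed the stage
  (adult stages: death completes them), matching the per-row `n` convention
  of published life-table tables.
* Ages with `l_x = 0` terminate all sums; `m_x` is defined 0 there.
* Bisection rather than Newton for Euler–Lotka: monotonicity makes it
  unconditionally safe, and 200 iterations exceed double precision anyway.
* All stochastic entry points take an explicit seed, use one local RNG
  stream, and restore the caller's RNG state; the CLI refuses stochastic
  work without `--seed`.
* Synthetic configs serialise as JSON (`jsonlite`), the structured-text
  format already in the package's dependency set.

## Known limitations

* Bootstrap CIs are percentile intervals; no BCa correction. At n = 80 the
  realised coverage of the 95% interval for `R0` measures ~94%.
* The paired bootstrap test is unadjusted for multiple comparisons and does
  not reproduce letter groupings across more than two cohorts.
* The projection is density-independent and temperature-free.
* The Quade exact mode enumerates `(k!)^b` permutations and is limited to
  small designs (e.g. k = 2, b <= 16); beyond that the F approximation or
  the concordance closed form applies.
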
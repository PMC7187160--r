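---
title: "Methods: multicenter atrophy markers and simulation-based trial power"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: multicenter atrophy markers and simulation-based trial power}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

This vignette documents the statistical model behind **atrophypower**, the
assumptions it makes, the defaults it ships with and why, and what the
package's validation does and does not establish.

## The measurement model

Every analysis in the package rests on one Gaussian two-level nested
random-intercept model for a longitudinal outcome $y_{ict}$ (a regional
brain volume in mL, or a clinical score) of participant $i$ in center $c$
at time $t$ years from baseline:

$$
y_{ict} = x_{ict}^\top \beta + u_c + u_{i(c)} + \varepsilon_{ict},
\qquad
u_c \sim N(0, \sigma^2_{center}),\;
u_{i(c)} \sim N(0, \sigma^2_{subject}),\;
\varepsilon \sim N(0, \sigma^2_{resid}).
$$

Fixed effects $x^\top\beta$ are drawn from a small vocabulary: time, age at
baseline, sex (0 = female, 1 = male), total intracranial volume (TIV, in
liters), diagnostic group (HC / PreHD / HD), a time-by-age interaction,
scanner, voxel size, and a study-by-group interaction for cross-study
comparisons. Random effects are intercepts only — center, and participant
nested in center. There are no random slopes and no non-Gaussian responses;
those are out of scope by design.

Estimation is by REML through `lme4::lmer()`. The package treats `lme4` as
its fitting engine and concentrates on what surrounds it; the test suite
anchors the engine against independent oracles (ordinary least squares when
all random-effect variances are zero, and the closed-form balanced one-way
ANOVA method-of-moments estimators, which REML reproduces exactly when the
between-center estimate is interior). Non-convergence triggers refits with
the bobyqa and Nelder–Mead optimizers; a fit that still fails is returned
flagged, never silently. Boundary variance estimates of exactly zero are
legitimate results and are reported as zero.

Wald inference in `fit_lmm()` uses residual degrees of freedom
$n_{obs} - \mathrm{rank}(X)$ — simple and adequate at the sample sizes of
interest (hundreds of participants, thousands of observations). The trial
treatment test (below) uses a different df; see *Degrees of freedom for the
treatment test*.

## The synthetic cohort generator

Real multicenter HD imaging data are not freely redistributable, so the
package ships a generator whose defaults emulate the structure of the three
large observational cohorts: 20 centers with 265 participants (controls and
premanifest carriers, a handful of manifest cases, five scanner models),
4 centers with 294 participants, and a single center with 65; three annual
visits; baseline demographics (group sizes, age and TIV means and SDs, sex
ratios, CAG repeat distributions with healthy controls truncated below 36
repeats) follow the published baseline tables of those studies. Group
counts are study totals distributed round-robin across centers, which
reproduces totals that are not multiples of the center count.

Volumes are generated exactly under the measurement model: a
healthy-control baseline mean, covariate terms centered at reference
age 45 y and TIV 1.4 L (so the baseline mean is interpretable), additive
group offsets, group-specific atrophy slopes, per-scanner offsets constant
over time, and the three Gaussian variance components. Group offsets and
slopes are free parameters rather than functions of CAG: the link between
CAG repeat length (or disease burden score, $age \times (CAG - 35.5)$) and
atrophy rate is not quantified in a form we could calibrate, and keeping
offsets explicit keeps the generative model identifiable. The burden score
and the TIV decomposition (CSF + cortical gray + deep gray + white matter)
are provided as utilities.

The default region set is deliberately small — pallidum, caudate, putamen,
insula white matter, nonventricular CSF, plus thalamus and middle cingulate
as low-effect distractors — not the full 83-region bilateral atlas (for
which `combine_bilateral()` handles the 156-to-83 left/right reduction).
Region parameters are anatomically plausible values chosen once to
reproduce the qualitative premanifest pattern: standardized effects ~1–1.7
in pallidum/caudate/putamen, smaller in insula white matter, negative
(enlargement) in CSF, and below the 0.5 selection threshold for the
distractors. Clinical markers (TMS/SDMT/SWRT analogues) use the same nested
structure with slope-to-residual-SD ratios an order of magnitude smaller
than the imaging regions, mimicking clinical scales' weak time dependence.

What the generator does **not** emulate: dropout and missing visits (the
analysis includes complete three-visit cases only, and the CSV loader
enforces this), floor/ceiling effects of clinical scales (markers are
unbounded Gaussians, so a synthetic motor score can be negative),
non-Gaussian measurement error, scanner upgrades mid-study (scanner is
constant within participant by construction), and any CAG-driven
progression heterogeneity. Passing tests therefore demonstrate the
statistical machinery under the model's own assumptions — not robustness to
the ways real imaging data violate them.

## Covariate adjustment

The adjusted baseline volume is the model evaluated at $t = 0$: observed
baseline minus the fitted nuisance contributions (age, sex, TIV, scanner,
voxel size), with each nuisance covariate centered at its sample mean over
baseline records. Centering makes adjusted values live on the observed
scale; the reference covariate values are otherwise arbitrary and a
constant shift cancels from every group contrast. Terms involving time
vanish at baseline, and the group contribution is retained — adjustment
must not remove the disease signal. Residuals are conditional (observed
minus fitted including predicted random effects).

## Standardized effect sizes and bootstrap

The cross-study effect size is
$t = (\bar{y}_{HC} - \bar{y}_{PreHD}) / s_{PreHD}$, the adjusted-baseline
mean difference divided by the residual SD in the premanifest group.
Dividing by a *residual* SD (rather than a raw SD) makes the denominator
comparable across studies with different covariate mixes. Whether the
residuals are conditional or marginal is not dictated by the definition;
conditional is the default and `group_residual_sd(type = "marginal")` is
the switch. Atrophied regions give positive $t$, enlarging compartments
negative $t$; magnitudes are read against Cohen's 0.2 / 0.5 / 0.8 anchors.

Confidence intervals are percentile bootstrap over 2,000 resamples, the
simplest method consistent with a bootstrap CI. The resampling unit is the
participant — not the visit — stratified by group with group sizes
preserved: this respects within-participant correlation and keeps the
group design fixed. Resamples where the statistic is undefined (zero
premanifest residual SD) are redrawn and counted. Cross-study weighted
means weight by the total HC + PreHD participants per study; region
selection takes $|t| > 0.5$ with a *strict* inequality and orders by
descending $|t|$, ties broken lexicographically. Effect maps are
normalized by the maximum absolute entry across all studies and regions.
Between-study effect-size differences are tested by a bootstrap difference
test (percentile, two-sided) rather than a parametric test, since the
sampling distribution of a ratio statistic under stratified resampling is
exactly what the bootstrap provides; p values for families of such
contrasts are Bonferroni-adjusted.

## Trial simulation and power

A simulated trial has $N_c$ centers with $N_{ppc}$ participants each,
randomized 1:1 within center, observed at times $0, 1, 2$ years. Untreated
participants decline at the placebo slope (the fitted time coefficient of
a pooled gene-carrier model — fitted *without* the time-by-age term, which
with uncentered age would turn the time coefficient into an age-zero
extrapolation); treated participants decline at
$slope \times (1 - \delta_c)$, where the center-level effect fraction
$\delta_c \sim N(\delta, \tau^2)$ truncated to $[0, 1]$ expresses
between-center treatment heterogeneity (site effects, assessor effects,
population differences). $\delta$ is the *proportional slowing* of
progression — the standard disease-modification reading of "a 20%
treatment effect". $\tau$ defaults to $0.25\,\delta$ in the pipeline; it is
not identifiable from observational data and is exposed as configuration.

Each simulated trial is analyzed with
`y ~ time + arm + arm:time + (1 | center/participant)` and a two-sided
Wald t test of the `arm:time` coefficient at $\alpha = 0.05$. Power is the
rejection fraction over `n_sim` replicates (default 1,000; binomial MC SE
about 1.3 points near 80% power). For speed, the allocation pattern is
drawn once per design point and subsequent replicates are `lme4::refit()`s
with fresh outcomes — participants are exchangeable, so power is
unaffected; replicates whose refit fails are dropped from the denominator,
counted, and the estimate is flagged when more than 10% fail.

### Degrees of freedom for the treatment test

The treatment-by-time coefficient is a *within-participant* contrast: its
information comes from within-participant changes. The denominator df
follows the containment (between/within) rule,
$n_{obs} - n_{participants} - 2$. The simpler residual-df convention used
elsewhere in the package is anticonservative here: near the
subject-variance boundary, REML pairs a within-based standard error with a
variance estimate that is downward-selected exactly in the samples where
the subject variance is estimated positive, and a full-residual df
compounds the effect. With the containment df, the two-visit zero-variance
case reduces *exactly* (for interior fits) to the two-sample t test on
per-participant change scores — the package's analytic anchor. A small
anticonservative remainder (on the order of one or two points of power) is
inherent to plugging REML variance estimates into a Wald test at the
boundary and is visible in the analytic-limit check's tolerance.

### Power curves and thresholds

Design grids follow the two canonical ways to grow a multicenter trial:
vary centers at $N_{ppc} = 20$ (default 6–100 in steps of 2), or vary
per-center enrollment at $N_c = 4$ (default 30–500 in steps of 10), with
totals capped at 2,000 participants. Raw Monte-Carlo power estimates are
retained and an isotonic-regression smoothed copy is used for threshold
search, so MC noise cannot produce a spurious early crossing of the 80%
line. The sample-size threshold is the smallest grid total with smoothed
power strictly above 80%; a curve that never crosses by the cap reports a
missing threshold.

A note on center geometry: under this analysis model (random intercepts
only), between-center treatment heterogeneity affects power mainly through
the concentration of the realized mean effect
$\bar\delta = \mathrm{mean}(\delta_c)$ — many small centers concentrate
$\bar\delta$, few large centers do not — which is a modest, concavity-driven
advantage. A trial analysis that *models* the between-center
treatment-effect variance (a random treatment-by-center slope) would test
the treatment against that variance with roughly $N_c$ degrees of freedom
and make the many-centers advantage dramatic; such an analysis model is
deliberately outside this package's scope, which mirrors the
intercept-only test.

## Numerical and reproducibility choices

* Convergence: lme4 defaults with singular-fit checks silenced (boundary
  fits are expected and valid); optimizer restarts on convergence
  warnings; REML relative tolerances are the optimizer's.
* All randomness flows from explicit seeds; pipeline stages derive
  sub-seeds by a 32-bit FNV-1a hash of (stage, region, grid point) folded
  into the master seed, so adding a region or grid point never perturbs
  another's results. RNG state is saved and restored around every seeded
  computation.
* CSV outputs round continuous values to 6 significant digits so a seeded
  rerun reproduces files byte for byte.
* Degenerate inputs fail loudly: empty tables, missing columns,
  rank-deficient designs (error names the collinear columns),
  single-center tables (center variance pinned to zero with a message),
  participants lacking complete visits (excluded, logged), scanner changes
  within participant (error with row numbers).

## Problem sizes used in validation

The test suite exercises: balanced one-way layouts of 10 centers × 10
participants against closed-form ANOVA; parameter recovery on 20 centers ×
600 participants × 3 visits; effect-size recovery with 200 simulations and
bootstrap coverage with 500 replications of 500 resamples at 100 per
group; test size at the null with 1,000 simulated trials; the analytic
power limit with 2,000 trials at each of five effect sizes; monotonicity
and threshold-cap behavior on small fixed-seed grids; and a matched-total-n
center-geometry comparison with 500 trials per design. These sizes are
chosen so the full suite completes in a few minutes while keeping
Monte-Carlo error well inside each check's tolerance.

## Known limitations

* Variance-component estimates from 20 or fewer centers are intrinsically
  noisy (the between-center estimate carries roughly
  $\sqrt{2/(N_c - 1)}$ relative sampling SD); recovery checks at that
  scale sit near their tolerance by nature, not by defect.
* The Wald treatment test retains slight anticonservativeness at variance
  boundaries, as discussed above.
* Absolute sample-size thresholds depend entirely on the hyperparameters
  fed to the simulator. The synthetic defaults are plausible but not
  calibrated to any real cohort's fitted values, so thresholds computed
  from synthetic data characterize the method, not HD trial planning;
  feed `extract_hyperparameters()` with fits to real data for the latter.
* Bootstrap CIs are percentile (not BCa) and can undercover slightly at
  small n; coverage is validated at n = 100 per group.
* No composite endpoints across regions, no dropout modelling, no
  cost-weighted center/participant trade-off optimization.
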
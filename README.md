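# atrophypower

Power analysis and effect-size estimation for multicenter clinical trials
that use regional brain volumes as outcome measures, motivated by
premanifest Huntington disease (HD).

HD is rare, so trials must recruit across many centers, and structural MRI
volumetry (caudate, pallidum, putamen, white matter, CSF compartments) is
among the most sensitive markers of premanifest disease progression. This
package provides the full analysis chain needed to plan such trials from
observational cohort data:

1. **Synthetic multicenter cohorts** (`generate_cohort()`): longitudinal
   participant-visit tables with healthy-control (HC), premanifest (PreHD)
   and manifest (HD) groups, participants nested in centers nested in
   studies, per-scanner offsets, and demographic distributions patterned on
   the three large observational HD imaging cohorts (a 20-center study of
   265 participants, a 4-center study of 294, and a single-center study of
   65; three annual visits each).
2. **Covariate adjustment** (`fit_lmm()`, `adjust_baseline()`): per-region
   nested random-intercept linear mixed models
   
   y<sub>ict</sub> = β₀ + β₁·t + β₂·age + β₃·sex + β₄·TIV + β₅·group
   + β₆·(t·age) [+ scanner] + u<sub>c</sub> + u<sub>i(c)</sub> + ε<sub>ict</sub>,
   
   with u<sub>c</sub> ~ N(0, σ²_center), u<sub>i(c)</sub> ~ N(0, σ²_subject),
   ε ~ N(0, σ²_resid), fitted by REML (via lme4). The adjusted baseline
   volume is the observed baseline minus the fitted nuisance contributions
   with covariates centered at their sample means. `test_study_group_interaction()`
   Wald-tests study-by-group interactions with Bonferroni adjustment.
3. **Standardized effect sizes** (`standardized_effect_size()`,
   `effect_size_table()`): t = (mean_HC − mean_PreHD) / SD of the PreHD
   residuals, per region and study, with stratified participant-bootstrap
   percentile confidence intervals (2,000 replications by default),
   participant-weighted cross-study means (`weighted_mean_effect()`),
   the |t| > 0.5 medium-effect selection rule (`select_regions()`), and
   max-normalized effect maps (`normalize_effect_map()`).
4. **Trial power by simulation** (`simulate_trial()`, `estimate_power()`,
   `power_curve()`): treatment slows the placebo atrophy slope by a
   fraction δ (δ = 0.2 is a 20% disease-modifying effect), with optional
   between-center heterogeneity δ_c ~ N(δ, τ²) truncated to [0, 1].
   Simulated trials are analyzed with the nested mixed model
   `y ~ time + arm + arm:time + (1 | center/participant)` and a two-tailed
   Wald t test on the treatment-by-time coefficient (α = 0.05). Power is
   mapped over design grids — varying the number of centers (Nc) at fixed
   per-center enrollment (Nppc), or vice versa — up to a 2,000-participant
   cap, and `sample_size_threshold()` finds the smallest total n with
   (isotonic-smoothed) power > 80%.
5. **Orchestration** (`run_pipeline()`): a seeded, logged end-to-end run
   with CSV/JSON outputs; a thin command-line wrapper with the verbs
   `generate`, `fit`, `effects`, `power`, `run` is installed at
   `inst/cli/atrophypower`.

## Worked example

```r
library(atrophypower)

cohort <- generate_cohort(default_cohort_config(), seed = 42)
es <- effect_size_table(cohort, c("caudate", "pallidum", "thalamus"),
                        n_boot = 500, seed = 42)
print(es, digits = 3)
#>     region   study       t ci_low ci_high n_hc n_prehd
#> 1  caudate PREDICT  1.3694  0.904   1.758   56     205
#> 2 pallidum PREDICT  1.7494  1.202   2.290   56     205
#> 3 thalamus PREDICT  0.0323 -0.457   0.477   56     205
#> 4  caudate   TRACK  1.6530  1.218   2.102  106     105
#> 5 pallidum   TRACK  1.7592  1.330   2.419  106     105
#> 6 thalamus   TRACK  0.1722 -0.262   0.647  106     105
#> 7  caudate   IMAGE  1.7906  0.965   3.824   23      22
#> 8 pallidum   IMAGE  1.3724  0.638   2.307   23      22
#> 9 thalamus   IMAGE -0.6024 -1.871   0.399   23      22
```

Pallidum and caudate show large (t well above 0.8) premanifest effects in
every study; the thalamus distractor does not. The participant-weighted
cross-study means drive region selection:

```r
w <- sapply(split(es, es$region), function(s)
  weighted_mean_effect(setNames(s$t, s$study),
                       setNames(s$n_hc + s$n_prehd, s$study)))
select_regions(w)
#> 2 region(s) with |weighted t| > 0.5
#>   pallidum                 +1.721
#>   caudate                  +1.522
```

Trial hyperparameters come from a pooled gene-carrier fit, and power for a
40-center trial with a 40% treatment effect is estimated by simulation:

```r
carriers <- subset(cohort, group %in% c("PreHD", "HD"))
fit <- fit_lmm(carriers, model_spec("caudate", c("time", "age", "sex", "tiv")))
hyper <- extract_hyperparameters(fit, treated_fraction_sd = 0.1)
estimate_power(trial_design(40, 20, delta = 0.4, n_sim = 300), hyper,
               seed = 42)
#> Power 0.317 (MC SE 0.027) at Nc=40 x Nppc=20 (n=800), delta=0.40
```

A trial of 800 participants detects a 40% slowing of caudate atrophy with
only ~32% power under these (deliberately noisy) synthetic
hyperparameters — sample-size thresholds are explored with
`power_curve()` / `sample_size_threshold()`.

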
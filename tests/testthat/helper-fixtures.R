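# Small cohort configurations used across test files.

# One study, controllable geometry and one region named "vol".
tiny_config <- function(n_centers = 4, n_hc = 40, n_prehd = 40, n_hd = 0,
                        region = region_params(
                          10, b_age = -0.02, b_sex = 0.3, b_tiv = 2,
                          offset = c(PreHD = -0.5, HD = -1),
                          slope = c(HC = -0.02, PreHD = -0.08, HD = -0.12),
                          sigma_center = 0.2, sigma_subject = 0.6,
                          sigma_resid = 0.4),
                        markers = list(), visit_times = c(0, 1, 2),
                        scanners = NULL) {
  cohort_config(
    study_block("S1", n_centers, n_hc, n_prehd, n_hd, scanners = scanners),
    regions = list(vol = region), markers = markers,
    visit_times = visit_times)
}

# Region with no covariate effects and no random effects beyond the
# residual: the generator reduces to group mean + slope * t + noise.
flat_region <- function(offset_prehd = 0, sigma_resid = 1,
                        slope = c(HC = 0, PreHD = 0, HD = 0)) {
  region_params(10, offset = c(PreHD = offset_prehd, HD = 0), slope = slope,
                sigma_center = 0, sigma_subject = 0,
                sigma_resid = sigma_resid)
}

# Per-participant adjusted data with known group means and unit-variance
# noise; `residual` carries the same draws so the bootstrap denominator is
# the PreHD sample SD (see bootstrap_ci()).
fake_adjusted <- function(n_hc, n_prehd, mean_hc = 0.5, mean_prehd = 0,
                          sd = 1) {
  vals <- c(rnorm(n_hc, mean_hc, sd), rnorm(n_prehd, mean_prehd, sd))
  data.frame(participant = seq_len(n_hc + n_prehd),
             group = rep(c("HC", "PreHD"), c(n_hc, n_prehd)),
             adjusted_baseline = vals, residual = vals,
             stringsAsFactors = FALSE)
}

# Hyperparameters of a well-behaved atrophying outcome for trial tests.
test_hyper <- function(tau = 0) {
  trial_hyperparameters(baseline_mean = 7.8, placebo_slope = -0.3,
                        sigma2_center = 0.01, sigma2_subject = 0.3,
                        sigma2_resid = 0.38, tau_treatment = tau)
}
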
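test_that("with zero random-effect variance the LMM collapses to OLS", {
  reg <- region_params(10, b_age = -0.02, b_sex = 0.3, b_tiv = 2,
                       offset = c(PreHD = -0.5), slope = c(PreHD = -0.1),
                       sigma_center = 0, sigma_subject = 0,
                       sigma_resid = 0.5)
  tab <- generate_cohort(tiny_config(n_hc = 60, n_prehd = 60, region = reg),
                         seed = 17)
  fit <- fit_lmm(tab, default_volume_spec("vol"))
  expect_true(fit$converged)
  # REML lands on (or sampling-close to) the zero-variance boundary
  expect_lt(fit$sigma2_center, 1e-6 * fit$sigma2_resid)
  expect_lt(fit$sigma2_subject, 0.25 * fit$sigma2_resid)

  # visits are balanced and identical across participants, so the GLS
  # fixed effects coincide with OLS whenever the center variance is zero
  ols <- stats::lm(vol ~ time + age + sex + tiv + group + time:age,
                   data = fit$frame)
  b_ols <- coef(ols)[fit$beta$term]
  expect_equal(fit$beta$estimate, unname(b_ols), tolerance = 1e-6)
})

test_that("balanced one-way REML equals closed-form ANOVA estimators", {
  set.seed(29)
  n_c <- 10; n_p <- 10
  d <- data.frame(center = factor(rep(seq_len(n_c), each = n_p)))
  d$y <- 5 + rep(rnorm(n_c, 0, 1.5), each = n_p) + rnorm(n_c * n_p, 0, 1)
  fit <- fit_lmm(d, model_spec("y", character(0), random = "center"))

  msw <- sum(tapply(d$y, d$center, function(v) sum((v - mean(v))^2))) /
    (n_c * (n_p - 1))
  grand <- mean(d$y)
  msb <- n_p * sum((tapply(d$y, d$center, mean) - grand)^2) / (n_c - 1)
  expect_gt(msb, msw)  # interior case
  expect_equal(fit$sigma2_resid, msw, tolerance = 1e-4)
  expect_equal(fit$sigma2_center, (msb - msw) / n_p, tolerance = 1e-4)
  expect_equal(fit$beta$estimate[1], grand, tolerance = 1e-6)
})

test_that("known generative parameters are recovered within their SEs", {
  reg <- region_params(10, b_age = -0.02, b_sex = 0.3, b_tiv = 2,
                       offset = c(PreHD = -0.4),
                       slope = c(HC = -0.08, PreHD = -0.08),
                       sigma_center = 0.3, sigma_subject = 0.6,
                       sigma_resid = 0.4)
  tab <- generate_cohort(tiny_config(n_centers = 10, n_hc = 100,
                                     n_prehd = 100, region = reg),
                         seed = 37)
  fit <- fit_lmm(tab, default_volume_spec("vol"))
  b <- fit$beta
  truth <- c(time = -0.08, age = -0.02, sex = 0.3, tiv = 2,
             groupPreHD = -0.4, `time:age` = 0)
  for (tm in names(truth)) {
    row <- b[b$term == tm, ]
    expect_lt(abs(row$estimate - truth[[tm]]), 3 * row$se)
  }
})

test_that("adding a constant to the outcome shifts only the intercept", {
  tab <- generate_cohort(tiny_config(n_hc = 30, n_prehd = 30), seed = 41)
  fit1 <- fit_lmm(tab, default_volume_spec("vol"))
  tab$vol <- tab$vol + 100
  fit2 <- fit_lmm(tab, default_volume_spec("vol"))
  expect_equal(fit2$beta$estimate[1], fit1$beta$estimate[1] + 100,
               tolerance = 1e-6)
  expect_equal(fit2$beta$estimate[-1], fit1$beta$estimate[-1],
               tolerance = 1e-6)
  expect_equal(fit2$sigma2_resid, fit1$sigma2_resid, tolerance = 1e-6)
})

test_that("a single-center table drops the center variance with a message", {
  tab <- generate_cohort(tiny_config(n_centers = 1, n_hc = 25, n_prehd = 25),
                         seed = 43)
  expect_message(fit <- fit_lmm(tab, default_volume_spec("vol")),
                 "single center")
  expect_identical(fit$sigma2_center, 0)
  expect_gt(fit$sigma2_subject, 0)
})

test_that("rank-deficient designs raise an error naming the column", {
  tab <- generate_cohort(tiny_config(n_hc = 20, n_prehd = 20), seed = 47)
  tab$age <- 50  # constant covariate, collinear with the intercept
  expect_error(fit_lmm(tab, default_volume_spec("vol")),
               "rank-deficient.*age")
})

test_that("adjustment without nuisance terms returns observed baselines", {
  tab <- generate_cohort(tiny_config(n_hc = 20, n_prehd = 20), seed = 53)
  fit <- fit_lmm(tab, model_spec("vol", c("time", "group")))
  adj <- adjust_baseline(fit)
  base <- tab[tab$time == 0, ]
  expect_equal(adj$adjusted_baseline,
               base$vol[match(adj$participant, base$participant)])
})

test_that("adjustment removes exactly the fitted TIV contribution", {
  tab <- generate_cohort(tiny_config(n_hc = 40, n_prehd = 40), seed = 59)
  # two participants made identical except for TIV
  base_ids <- unique(tab$participant)[1:2]
  i1 <- tab$participant == base_ids[1]
  i2 <- tab$participant == base_ids[2]
  for (col in c("age", "sex", "group", "center", "scanner"))
    tab[[col]][i2] <- tab[[col]][i1]
  tab$tiv[i2] <- tab$tiv[i1] + 0.25
  tab$vol[i2] <- tab$vol[i1]
  fit <- fit_lmm(tab, default_volume_spec("vol"))
  b_tiv <- fit$beta$estimate[fit$beta$term == "tiv"]
  adj <- adjust_baseline(fit)
  a1 <- adj$adjusted_baseline[adj$participant == base_ids[1]]
  a2 <- adj$adjusted_baseline[adj$participant == base_ids[2]]
  # identical observed volumes, TIV differing by 0.25: adjusted values
  # differ by exactly -b_tiv * 0.25
  expect_equal(a2 - a1, -b_tiv * 0.25, tolerance = 1e-10)
})

test_that("adjusted group mean difference tracks the group coefficient", {
  tab <- generate_cohort(tiny_config(n_centers = 8, n_hc = 120,
                                     n_prehd = 120), seed = 61)
  fit <- fit_lmm(tab, default_volume_spec("vol"))
  adj <- adjust_baseline(fit)
  diff_adj <- mean(adj$adjusted_baseline[adj$group == "PreHD"]) -
    mean(adj$adjusted_baseline[adj$group == "HC"])
  b_group <- fit$beta$estimate[fit$beta$term == "groupPreHD"]
  se_group <- fit$beta$se[fit$beta$term == "groupPreHD"]
  expect_lt(abs(diff_adj - b_group), 3 * se_group)
})

test_that("study-by-group interaction testing needs two studies", {
  tab <- generate_cohort(tiny_config(n_hc = 20, n_prehd = 20), seed = 67)
  out <- test_study_group_interaction(tab, default_volume_spec("vol"))
  expect_equal(nrow(out), 0)
})

test_that("an injected between-study group shift is detected", {
  reg <- region_params(10, offset = c(PreHD = -0.5),
                       slope = c(HC = -0.05, PreHD = -0.05),
                       sigma_center = 0.1, sigma_subject = 0.5,
                       sigma_resid = 0.4)
  cfg <- cohort_config(
    list(study_block("A", 4, 80, 80), study_block("B", 4, 80, 80)),
    regions = list(vol = reg))
  tab <- generate_cohort(cfg, seed = 71)
  # shift study B's PreHD offset by 3 residual SDs
  shift <- tab$study == "B" & tab$group == "PreHD"
  tab$vol[shift] <- tab$vol[shift] - 3 * 0.4
  out <- test_study_group_interaction(tab, default_volume_spec("vol"))
  row <- out[out$group == "PreHD", ]
  expect_equal(nrow(row), 1)
  expect_lt(row$p_adj, 0.05)
  expect_equal(abs(row$estimate), 1.2, tolerance = 0.35)
})

test_that("interaction rejection rate under the null is near alpha", {
  reg <- region_params(10, offset = c(PreHD = -0.5),
                       slope = c(HC = -0.05, PreHD = -0.05),
                       sigma_center = 0.1, sigma_subject = 0.5,
                       sigma_resid = 0.4)
  cfg <- cohort_config(
    list(study_block("A", 3, 40, 40), study_block("B", 3, 40, 40)),
    regions = list(vol = reg))
  n_rep <- 40
  rej <- logical(n_rep)
  for (r in seq_len(n_rep)) {
    tab <- generate_cohort(cfg, seed = 1000 + r)
    out <- test_study_group_interaction(tab, default_volume_spec("vol"))
    rej[r] <- out$p[out$group == "PreHD"] < 0.05
  }
  # unadjusted single-contrast rate should sit near 0.05
  expect_lt(abs(mean(rej) - 0.05), 3 * sqrt(0.05 * 0.95 / n_rep))
})

test_that("hyperparameter extraction maps the fitted model fields", {
  tab <- generate_cohort(tiny_config(n_hc = 30, n_prehd = 30), seed = 79)
  fit <- fit_lmm(tab, default_volume_spec("vol"))
  hy <- extract_hyperparameters(fit, treated_fraction_sd = 0.1)
  expect_s3_class(hy, "trial_hyperparameters")
  expect_equal(hy$baseline_mean,
               fit$beta$estimate[fit$beta$term == "(Intercept)"])
  expect_equal(hy$placebo_slope, fit$beta$estimate[fit$beta$term == "time"])
  expect_equal(hy$sigma2_subject, fit$sigma2_subject)
  expect_equal(hy$tau_treatment, 0.1)

  bad <- fit
  bad$converged <- FALSE
  expect_error(extract_hyperparameters(bad), "non-converged")
  nofit <- fit_lmm(tab, model_spec("vol", c("age", "sex", "group")))
  expect_error(extract_hyperparameters(nofit), "time")
})

test_that("hyperparameters round-trip through a simulated trial refit", {
  hy <- test_hyper()
  d <- trial_design(20, 60, delta = 0, n_sim = 1)
  tr <- simulate_trial(d, hy, seed = 83)
  tr$vol <- tr$y
  fit <- fit_lmm(tr, model_spec("vol", "time"))
  back <- extract_hyperparameters(fit)
  expect_equal(back$baseline_mean, hy$baseline_mean, tolerance = 0.05)
  expect_equal(back$placebo_slope, hy$placebo_slope, tolerance = 0.05)
  expect_equal(back$sigma2_subject, hy$sigma2_subject, tolerance = 0.2)
  expect_equal(back$sigma2_resid, hy$sigma2_resid, tolerance = 0.1)
})

test_that("fitted models export to JSON with all summary fields", {
  tab <- generate_cohort(tiny_config(n_hc = 15, n_prehd = 15), seed = 89)
  fit <- fit_lmm(tab, default_volume_spec("vol"))
  parsed <- jsonlite::fromJSON(fit_to_json(fit))
  expect_equal(parsed$n_obs, fit$n_obs)
  expect_equal(parsed$sigma2_resid, fit$sigma2_resid, tolerance = 1e-8)
  expect_true(all(c("term", "estimate", "se", "p") %in% names(parsed$beta)))
})
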
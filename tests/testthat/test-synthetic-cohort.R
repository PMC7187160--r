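test_that("generated cohorts have the nested longitudinal structure", {
  cfg <- tiny_config(n_centers = 3, n_hc = 10, n_prehd = 11, n_hd = 5)
  tab <- generate_cohort(cfg, seed = 7)

  expect_s3_class(tab, "cohort_table")
  visits <- tapply(tab$time, tab$participant, function(tt) sort(tt))
  expect_true(all(vapply(visits, identical, logical(1L), y = c(0, 1, 2))))
  expect_true(all(tapply(tab$scanner, tab$participant,
                         function(s) length(unique(s))) == 1))
  expect_true(all(tab$group %in% c("HC", "PreHD", "HD")))
  expect_true(all(tab$vol > 0))
  expect_true(all(tab$sex %in% c(0, 1)))
  # group totals are preserved by the round-robin center allocation
  base <- tab[tab$visit == 1, ]
  expect_equal(unname(table(base$group)[c("HC", "PreHD", "HD")]),
               c(10, 11, 5), ignore_attr = TRUE)
  # HC CAG stays in the non-pathogenic range
  expect_true(all(tab$cag[tab$group == "HC"] < 36))
  expect_true(all(tab$cag[tab$group != "HC"] >= 36))
})

test_that("regeneration with the same seed is bit-identical", {
  cfg <- tiny_config()
  expect_identical(generate_cohort(cfg, seed = 123),
                   generate_cohort(cfg, seed = 123))
  t2 <- generate_cohort(cfg, seed = 124)
  expect_false(identical(generate_cohort(cfg, seed = 123)$vol, t2$vol))
})

test_that("with all random-effect SDs zero the generator is deterministic", {
  reg <- region_params(10, b_age = -0.02, b_sex = 0.3, b_tiv = 2,
                       offset = c(PreHD = -0.5), slope = c(PreHD = -0.1),
                       sigma_center = 0, sigma_subject = 0, sigma_resid = 0)
  cfg <- tiny_config(region = reg)
  tab <- generate_cohort(cfg, seed = 5)
  expected <- 10 - 0.02 * (tab$age - 45) + 0.3 * tab$sex +
    2 * (tab$tiv - 1.4) - 0.5 * (tab$group == "PreHD") -
    0.1 * (tab$group == "PreHD") * tab$time
  expect_equal(tab$vol, expected, tolerance = 1e-12)
})

test_that("identical group distributions give a near-zero effect size", {
  cfg <- tiny_config(n_centers = 2, n_hc = 500, n_prehd = 500,
                     region = flat_region(offset_prehd = 0))
  tab <- generate_cohort(cfg, seed = 11)
  base <- tab[tab$visit == 1, ]
  t_hat <- standardized_effect_size(base$vol[base$group == "HC"],
                                    base$vol[base$group == "PreHD"],
                                    sd(base$vol[base$group == "PreHD"]))
  # 3 MC standard errors of a null standardized mean difference
  expect_lt(abs(t_hat), 3 * sqrt(1 / 500 + 1 / 500))
})

test_that("a half-residual-SD offset yields an effect size near 0.5", {
  cfg <- tiny_config(n_centers = 2, n_hc = 2000, n_prehd = 2000,
                     region = flat_region(offset_prehd = -0.5 * 2,
                                          sigma_resid = 2))
  tab <- generate_cohort(cfg, seed = 13)
  base <- tab[tab$visit == 1, ]
  t_hat <- standardized_effect_size(base$vol[base$group == "HC"],
                                    base$vol[base$group == "PreHD"],
                                    sd(base$vol[base$group == "PreHD"]))
  # 3 MC standard errors of a standardized mean difference at n = 2,000
  expect_lt(abs(t_hat - 0.5), 3 * sqrt(2 / 2000 + 0.5^2 / 4000))
})

test_that("default demographics track the published baseline table", {
  tab <- generate_cohort(default_cohort_config(), seed = 21)
  base <- tab[tab$visit == 1 & tab$study == "TRACK" & tab$group == "PreHD", ]
  expect_equal(nrow(base), 105)
  expect_lt(abs(mean(base$age) - 41.1), 3 * 8.8 / sqrt(105))
  expect_equal(length(unique(tab$participant)), 265 + 294 + 65)
  n_centers <- tapply(tab$center, tab$study,
                      function(x) length(unique(x)))
  expect_equal(unname(c(n_centers[c("PREDICT", "TRACK", "IMAGE")])),
               c(20, 4, 1))
})

test_that("empirical variance decomposition matches the configuration", {
  reg <- region_params(50, offset = c(PreHD = 0), slope = c(PreHD = 0),
                       sigma_center = 2, sigma_subject = 1,
                       sigma_resid = 0.5)
  cfg <- tiny_config(n_centers = 200, n_hc = 1200, n_prehd = 1200,
                     region = reg)
  tab <- generate_cohort(cfg, seed = 31)
  # moment estimators on the balanced nested layout
  resid_hat <- mean(tapply(tab$vol, tab$participant, var))
  part_means <- tapply(tab$vol, tab$participant, mean)
  part_center <- tapply(tab$center, tab$participant, `[`, 1)
  subj_hat <- mean(tapply(part_means, part_center, var)) - resid_hat / 3
  center_hat <- var(tapply(tab$vol, tab$center, mean)) -
    (subj_hat + resid_hat / 3) / 12
  expect_equal(resid_hat, 0.5^2, tolerance = 0.1)
  expect_equal(subj_hat, 1^2, tolerance = 0.15)
  expect_equal(center_hat, 2^2, tolerance = 0.3)
})

test_that("configuration errors are caught", {
  expect_error(region_params(10, sigma_resid = -1), "variance")
  expect_error(study_block("S", 2, 0, 0, 0), "n_hc")
  expect_error(cohort_config(study_block("S", 2, 5, 5),
                             regions = list(vol = flat_region()),
                             visit_times = c(0, 0, 1)),
               "strictly increasing")
  expect_error(cohort_config(study_block("S", 2, 5, 5),
                             regions = list(flat_region())),
               "names")
})

test_that("burden score follows age times CAG excess", {
  expect_equal(compute_burden_score(40, 35.5), 0)
  expect_equal(compute_burden_score(40, 43), 300)
  expect_equal(compute_burden_score(30, 40), 135)
  expect_error(compute_burden_score(-1, 42), "positive")
})

test_that("TIV is the symmetric sum of the four compartments", {
  expect_equal(compute_tiv(0, 0, 0, 0), 0)
  expect_equal(compute_tiv(300, 500, 60, 500), 1360)
  expect_equal(compute_tiv(500, 60, 300, 500), compute_tiv(300, 500, 60, 500))
  expect_error(compute_tiv(-1, 0, 0, 0), ">= 0")
})

test_that("bilateral combination sums pairs and passes midline through", {
  expect_equal(combine_bilateral(c("Left-Caudate" = 3.1,
                                   "Right-Caudate" = 3.3)),
               c(Caudate = 6.4))
  expect_equal(combine_bilateral(c("Brain-Stem" = 20.0)),
               c("Brain-Stem" = 20.0))
  expect_error(combine_bilateral(c("Left-Caudate" = 3.1)), "unpaired")
})

test_that("a 156-region lateralized atlas combines to 83 volumes", {
  pair_names <- sprintf("Region%02d", 1:73)
  midline <- sprintf("Midline%02d", 1:10)
  vols <- c(stats::setNames(runif(73), paste0("Left-", pair_names)),
            stats::setNames(runif(73), paste0("Right-", pair_names)),
            stats::setNames(runif(10), midline))
  expect_length(vols, 156)
  out <- combine_bilateral(vols)
  expect_length(out, 83)
  expect_equal(sum(out), sum(vols))
  expect_equal(out[["Region01"]],
               vols[["Left-Region01"]] + vols[["Right-Region01"]])
})
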
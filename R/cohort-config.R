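GROUPS <- c("HC", "PreHD", "HD")

#' Describe one study in a multicenter cohort configuration
#'
#' A study block fixes the geometry (centers, participants per group) and the
#' demographic distributions of one observational study. Group counts are
#' study totals and are distributed round-robin across centers, which allows
#' totals that are not multiples of the center count (e.g. 105 premanifest
#' participants over 4 centers).
#'
#' @param study_id character label, e.g. `"TRACK"`.
#' @param n_centers number of centers (>= 1).
#' @param n_hc,n_prehd,n_hd total participants per group across all centers.
#' @param scanners character vector of scanner labels; recycled over centers
#'   (default one scanner per center). Each participant keeps the scanner of
#'   their center at all visits.
#' @param age named list per group of `c(mean, sd)` in years at baseline.
#' @param sex_male named numeric per group: fraction of male participants.
#' @param cag named list per group of `c(mean, sd)` CAG repeat lengths.
#'   Healthy-control draws are truncated below 36 repeats (non-pathogenic).
#' @param tiv `c(mean, sd)` of total intracranial volume in liters.
#' @return an object of class `study_block`.
#' @export
study_block <- function(study_id, n_centers, n_hc, n_prehd, n_hd = 0,
                        scanners = NULL,
                        age = list(HC = c(45, 12), PreHD = c(42, 10),
                                   HD = c(48, 10)),
                        sex_male = c(HC = 0.5, PreHD = 0.5, HD = 0.5),
                        cag = list(HC = c(20.3, 3.3), PreHD = c(42.3, 2.6),
                                   HD = c(43.0, 3.1)),
                        tiv = c(1.4, 0.14)) {
  stopifnot(is.character(study_id), length(study_id) == 1L,
            n_centers >= 1, n_hc >= 0, n_prehd >= 0, n_hd >= 0,
            n_hc + n_prehd + n_hd > 0)
  if (is.null(scanners)) scanners <- paste0(study_id, "-scanner", seq_len(n_centers))
  scanners <- rep_len(as.character(scanners), n_centers)
  for (g in GROUPS) {
    if (is.null(age[[g]]) || length(age[[g]]) != 2L)
      stop("age must give c(mean, sd) for group ", g)
    if (age[[g]][2] < 0) stop("age sd must be >= 0 for group ", g)
  }
  if (any(sex_male[GROUPS] < 0 | sex_male[GROUPS] > 1, na.rm = TRUE))
    stop("sex_male fractions must lie in [0, 1]")
  if (tiv[2] < 0) stop("tiv sd must be >= 0")
  structure(list(study_id = study_id, n_centers = as.integer(n_centers),
                 n_group = c(HC = as.integer(n_hc), PreHD = as.integer(n_prehd),
                             HD = as.integer(n_hd)),
                 scanners = scanners, age = age, sex_male = sex_male,
                 cag = cag, tiv = tiv),
            class = "study_block")
}

#' Generative parameters for one regional volume
#'
#' Volumes (mL) are generated as
#' `baseline_mean + b_age*(age - age_ref) + b_sex*sex + b_tiv*(tiv - tiv_ref)
#'  + offset[group] + slope[group]*time + scanner effect + u_center +
#'  u_subject + residual`,
#' with the three random terms mean-zero Gaussians. Covariates are centered
#' at the configuration's reference age/TIV so `baseline_mean` is the typical
#' healthy-control volume.
#'
#' @param baseline_mean healthy-control baseline mean, mL.
#' @param b_age mL per year of baseline age.
#' @param b_sex mL difference male vs female.
#' @param b_tiv mL per liter of intracranial volume.
#' @param offset named numeric, additive group offsets in mL (HC implied 0).
#' @param slope named numeric, atrophy slope per group in mL/year.
#' @param sigma_center,sigma_subject,sigma_resid random-effect and residual
#'   SDs in mL; all must be >= 0.
#' @param sigma_scanner SD of per-scanner additive offsets (mL), constant
#'   over time within scanner.
#' @return an object of class `region_params`.
#' @export
region_params <- function(baseline_mean, b_age = 0, b_sex = 0, b_tiv = 0,
                          offset = c(PreHD = 0, HD = 0),
                          slope = c(HC = 0, PreHD = 0, HD = 0),
                          sigma_center = 0, sigma_subject = 1,
                          sigma_resid = 1, sigma_scanner = 0) {
  if (any(c(sigma_center, sigma_subject, sigma_resid, sigma_scanner) < 0))
    stop("variance components must be >= 0")
  off <- c(HC = 0, PreHD = 0, HD = 0); off[names(offset)] <- offset
  sl <- c(HC = 0, PreHD = 0, HD = 0); sl[names(slope)] <- slope
  structure(list(baseline_mean = baseline_mean, b_age = b_age, b_sex = b_sex,
                 b_tiv = b_tiv, offset = off[GROUPS], slope = sl[GROUPS],
                 sigma_center = sigma_center, sigma_subject = sigma_subject,
                 sigma_resid = sigma_resid, sigma_scanner = sigma_scanner),
            class = "region_params")
}

#' Generative parameters for one clinical marker
#'
#' Same nested random-effect structure as regional volumes, but with no
#' imaging covariates. By construction the defaults keep the slope small
#' relative to the residual SD: clinical scales progress slowly and noisily
#' compared with regional atrophy.
#'
#' @param intercept healthy-control mean score.
#' @param offset named numeric group offsets (HC implied 0).
#' @param slope named numeric score change per year per group.
#' @param sigma_center,sigma_subject,sigma_resid SDs, all >= 0.
#' @return an object of class `clinical_params`.
#' @export
clinical_params <- function(intercept, offset = c(PreHD = 0, HD = 0),
                            slope = c(HC = 0, PreHD = 0, HD = 0),
                            sigma_center = 0, sigma_subject = 1,
                            sigma_resid = 1) {
  if (any(c(sigma_center, sigma_subject, sigma_resid) < 0))
    stop("variance components must be >= 0")
  off <- c(HC = 0, PreHD = 0, HD = 0); off[names(offset)] <- offset
  sl <- c(HC = 0, PreHD = 0, HD = 0); sl[names(slope)] <- slope
  structure(list(intercept = intercept, offset = off[GROUPS],
                 slope = sl[GROUPS], sigma_center = sigma_center,
                 sigma_subject = sigma_subject, sigma_resid = sigma_resid),
            class = "clinical_params")
}

#' Assemble a multicenter cohort configuration
#'
#' @param studies list of [study_block()] objects.
#' @param regions named list of [region_params()], one per regional volume.
#' @param markers named list of [clinical_params()], one per clinical score.
#' @param visit_times strictly increasing visit times in years from baseline
#'   (default three annual visits).
#' @param age_ref,tiv_ref covariate centering points used by the generative
#'   model (years; liters).
#' @return an object of class `cohort_config`.
#' @export
cohort_config <- function(studies, regions, markers = list(),
                          visit_times = c(0, 1, 2),
                          age_ref = 45, tiv_ref = 1.4) {
  if (inherits(studies, "study_block")) studies <- list(studies)
  stopifnot(length(studies) >= 1, length(regions) >= 1,
            !is.null(names(regions)), all(nzchar(names(regions))))
  if (length(markers) && is.null(names(markers)))
    stop("markers must be a named list")
  if (length(visit_times) < 2 || any(diff(visit_times) <= 0))
    stop("visit_times must be strictly increasing with at least 2 visits")
  for (s in studies) if (!inherits(s, "study_block"))
    stop("each study must be built with study_block()")
  for (r in regions) if (!inherits(r, "region_params"))
    stop("each region must be built with region_params()")
  for (m in markers) if (!inherits(m, "clinical_params"))
    stop("each marker must be built with clinical_params()")
  ids <- vapply(studies, `[[`, character(1L), "study_id")
  if (anyDuplicated(ids)) stop("duplicate study_id")
  structure(list(studies = studies, regions = regions, markers = markers,
                 visit_times = visit_times, age_ref = age_ref,
                 tiv_ref = tiv_ref),
            class = "cohort_config")
}

#' Default three-study Huntington disease cohort configuration
#'
#' Emulates the structure of the three large observational HD imaging
#' cohorts: a 20-center study of 265 participants (mostly premanifest and
#' controls, several scanner models), a 4-center study of 294 participants,
#' and a single-center study of 65 participants. Baseline demographics
#' (ages, sex ratios, TIV, CAG repeats) follow the published baseline
#' tables of those studies; regional volume and clinical-marker parameters
#' are plausible values chosen to reproduce the qualitative pattern of
#' premanifest atrophy: large standardized effects in pallidum, caudate and
#' putamen, an enlarging (negative-effect) CSF compartment, and clinical
#' scores that progress weakly relative to their noise.
#'
#' @param n_scale optional multiplier on all group totals (e.g. 0.2 for a
#'   fast smoke-test cohort); counts are rounded up so no group empties.
#' @return a [cohort_config()] object.
#' @export
default_cohort_config <- function(n_scale = 1) {
  sc <- function(n) as.integer(ceiling(n * n_scale))
  predict_scanners <- paste0("PREDICT-scanner", rep(1:5, length.out = 20))
  studies <- list(
    study_block("PREDICT", n_centers = 20, n_hc = sc(56), n_prehd = sc(205),
                n_hd = sc(4), scanners = predict_scanners,
                age = list(HC = c(45.1, 12.1), PreHD = c(41.8, 10.8),
                           HD = c(46.8, 10.7)),
                sex_male = c(HC = 36 / 56, PreHD = 129 / 205, HD = 3 / 4),
                cag = list(HC = c(20.3, 3.3), PreHD = c(42.3, 2.6),
                           HD = c(43.0, 4.2)),
                tiv = c(1.37, 0.134)),
    study_block("TRACK", n_centers = 4, n_hc = sc(106), n_prehd = sc(105),
                n_hd = sc(83),
                age = list(HC = c(46.3, 10.2), PreHD = c(41.1, 8.8),
                           HD = c(49.1, 9.5)),
                sex_male = c(HC = 61 / 106, PreHD = 56 / 105, HD = 44 / 83),
                cag = list(HC = c(20.3, 3.3), PreHD = c(43.0, 2.3),
                           HD = c(43.6, 3.1)),
                tiv = c(1.39, 0.133)),
    study_block("IMAGE", n_centers = 1, n_hc = sc(23), n_prehd = sc(22),
                n_hd = sc(20),
                age = list(HC = c(44.4, 13.9), PreHD = c(43.4, 8.3),
                           HD = c(53.4, 8.8)),
                sex_male = c(HC = 16 / 23, PreHD = 16 / 22, HD = 7 / 20),
                cag = list(HC = c(20.3, 3.3), PreHD = c(42.0, 2.0),
                           HD = c(42.9, 2.4)),
                tiv = c(1.44, 0.144))
  )
  regions <- list(
    # disease-affected regions: group offsets scaled so premanifest
    # standardized effects land near 1.5 (pallidum) down to 0.8 (insula WM)
    pallidum = region_params(3.6, b_age = -0.004, b_sex = 0.08, b_tiv = 1.2,
                             offset = c(PreHD = -0.45, HD = -0.8),
                             slope = c(HC = -0.002, PreHD = -0.04, HD = -0.06),
                             sigma_center = 0.05, sigma_subject = 0.28,
                             sigma_resid = 0.30, sigma_scanner = 0.04),
    caudate = region_params(7.8, b_age = -0.012, b_sex = 0.25, b_tiv = 2.4,
                            offset = c(PreHD = -0.85, HD = -1.6),
                            slope = c(HC = -0.005, PreHD = -0.11, HD = -0.16),
                            sigma_center = 0.10, sigma_subject = 0.55,
                            sigma_resid = 0.62, sigma_scanner = 0.08),
    putamen = region_params(9.8, b_age = -0.02, b_sex = 0.35, b_tiv = 2.8,
                            offset = c(PreHD = -0.95, HD = -1.9),
                            slope = c(HC = -0.006, PreHD = -0.12, HD = -0.18),
                            sigma_center = 0.12, sigma_subject = 0.70,
                            sigma_resid = 0.80, sigma_scanner = 0.10),
    insula_white_matter = region_params(7.0, b_age = -0.008, b_sex = 0.2,
                                        b_tiv = 2.0,
                                        offset = c(PreHD = -0.5, HD = -0.9),
                                        slope = c(HC = -0.003, PreHD = -0.05,
                                                  HD = -0.08),
                                        sigma_center = 0.10,
                                        sigma_subject = 0.50,
                                        sigma_resid = 0.62,
                                        sigma_scanner = 0.08),
    # CSF expands with atrophy: positive offset, hence negative effect size
    nonventricular_csf = region_params(250, b_age = 1.2, b_sex = 8,
                                       b_tiv = 110,
                                       offset = c(PreHD = 16, HD = 30),
                                       slope = c(HC = 0.6, PreHD = 2.4,
                                                 HD = 3.6),
                                       sigma_center = 4, sigma_subject = 18,
                                       sigma_resid = 22, sigma_scanner = 3),
    # distractor regions with negligible disease effect
    thalamus = region_params(14.0, b_age = -0.03, b_sex = 0.5, b_tiv = 4.0,
                             offset = c(PreHD = -0.15, HD = -0.5),
                             slope = c(HC = -0.01, PreHD = -0.03, HD = -0.05),
                             sigma_center = 0.15, sigma_subject = 0.95,
                             sigma_resid = 1.0, sigma_scanner = 0.12),
    middle_cingulate = region_params(4.6, b_age = -0.006, b_sex = 0.12,
                                     b_tiv = 1.4,
                                     offset = c(PreHD = -0.05, HD = -0.2),
                                     slope = c(HC = -0.002, PreHD = -0.01,
                                               HD = -0.02),
                                     sigma_center = 0.06, sigma_subject = 0.4,
                                     sigma_resid = 0.45, sigma_scanner = 0.05)
  )
  markers <- list(
    # weakly time-dependent, noisy progression markers
    tms = clinical_params(2.5, offset = c(PreHD = 1.8, HD = 19),
                          slope = c(HC = 0.05, PreHD = 0.8, HD = 1.6),
                          sigma_center = 0.5, sigma_subject = 2.8,
                          sigma_resid = 3.2),
    sdmt = clinical_params(52, offset = c(PreHD = -3, HD = -16),
                           slope = c(HC = -0.1, PreHD = -0.9, HD = -1.6),
                           sigma_center = 1.5, sigma_subject = 8,
                           sigma_resid = 7),
    swrt = clinical_params(100, offset = c(PreHD = -4, HD = -24),
                           slope = c(HC = -0.2, PreHD = -1.2, HD = -2.4),
                           sigma_center = 3, sigma_subject = 14,
                           sigma_resid = 13)
  )
  cohort_config(studies, regions, markers)
}

#' @export
print.cohort_config <- function(x, ...) {
  cat("Cohort configuration:", length(x$studies), "studies,",
      length(x$regions), "regions,", length(x$markers), "markers\n")
  for (s in x$studies)
    cat(sprintf("  %s: %d centers, HC/PreHD/HD = %d/%d/%d\n", s$study_id,
                s$n_centers, s$n_group["HC"], s$n_group["PreHD"],
                s$n_group["HD"]))
  cat("  visits at", paste(x$visit_times, collapse = ", "), "years\n")
  invisible(x)
}

#' Read or write a cohort configuration as YAML or JSON
#'
#' Field names mirror the constructors [study_block()], [region_params()] and
#' [clinical_params()]. Format is chosen from the file extension
#' (`.yaml`/`.yml` or `.json`).
#'
#' @param path file path.
#' @return for `read_cohort_config`, a [cohort_config()] object.
#' @export
read_cohort_config <- function(path) {
  raw <- if (grepl("\\.json$", path, ignore.case = TRUE)) {
    jsonlite::read_json(path, simplifyVector = TRUE, simplifyDataFrame = FALSE)
  } else {
    yaml::read_yaml(path)
  }
  num2 <- function(x) as.numeric(unlist(x))
  studies <- lapply(raw$studies, function(s) {
    study_block(s$study_id, s$n_centers, s$n_hc, s$n_prehd, s$n_hd %||% 0,
                scanners = s$scanners,
                age = lapply(s$age, num2),
                sex_male = unlist(s$sex_male),
                cag = lapply(s$cag, num2), tiv = num2(s$tiv))
  })
  regions <- lapply(raw$regions, function(r)
    region_params(r$baseline_mean, r$b_age %||% 0, r$b_sex %||% 0,
                  r$b_tiv %||% 0, unlist(r$offset), unlist(r$slope),
                  r$sigma_center %||% 0, r$sigma_subject %||% 1,
                  r$sigma_resid %||% 1, r$sigma_scanner %||% 0))
  markers <- lapply(raw$markers %||% list(), function(m)
    clinical_params(m$intercept, unlist(m$offset), unlist(m$slope),
                    m$sigma_center %||% 0, m$sigma_subject %||% 1,
                    m$sigma_resid %||% 1))
  cohort_config(studies, regions, markers,
                visit_times = num2(raw$visit_times %||% c(0, 1, 2)),
                age_ref = raw$age_ref %||% 45, tiv_ref = raw$tiv_ref %||% 1.4)
}

#' @rdname read_cohort_config
#' @param config a [cohort_config()] object.
#' @export
write_cohort_config <- function(config, path) {
  stopifnot(inherits(config, "cohort_config"))
  as_plain <- function(x) lapply(unclass(x), function(v)
    if (is.null(names(v)) || is.list(v)) v else as.list(v))
  out <- list(
    studies = lapply(config$studies, function(s) {
      p <- as_plain(s); p$n_hc <- s$n_group[["HC"]]
      p$n_prehd <- s$n_group[["PreHD"]]; p$n_hd <- s$n_group[["HD"]]
      p$n_group <- NULL; p
    }),
    regions = lapply(config$regions, as_plain),
    markers = lapply(config$markers, as_plain),
    visit_times = config$visit_times,
    age_ref = config$age_ref, tiv_ref = config$tiv_ref)
  if (grepl("\\.json$", path, ignore.case = TRUE)) {
    jsonlite::write_json(out, path, auto_unbox = TRUE, digits = NA)
  } else {
    yaml::write_yaml(out, path)
  }
  invisible(path)
}
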
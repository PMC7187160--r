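#' Configure an end-to-end pipeline run
#'
#' Exactly one of `input` (a cohort CSV path) or `generator` (a
#' [cohort_config()]) must be given. The master seed drives every stochastic
#' stage through [derive_seed()] sub-seeds, so adding a region or grid point
#' does not perturb the other results.
#'
#' @param input path to a cohort CSV (see [load_cohort_csv()]), or `NULL`.
#' @param generator a [cohort_config()] to generate the cohort, or `NULL`.
#' @param regions region columns to analyze (default: all region columns of
#'   the generator config, or all outcome columns of the CSV).
#' @param n_boot,level,threshold effect-size settings: bootstrap
#'   replications, CI level, and the selection threshold on the weighted
#'   absolute effect size.
#' @param deltas treatment-effect fractions to simulate (default 0.2, 0.4).
#' @param modes power-curve modes to run.
#' @param power_grids optional named list (`vary_centers`,
#'   `vary_per_center`) of integer grids for the varied design quantity.
#' @param alpha significance level for the treatment test.
#' @param n_sim Monte-Carlo replicates per design point.
#' @param tau_factor between-center treatment-effect SD as a fraction of
#'   delta (default 0.25, so `tau = 0.25 * delta`).
#' @param n_cap maximum total participants per curve (default 2,000).
#' @param max_power_regions cap on how many selected regions get power
#'   curves (in descending weighted effect size; default 2).
#' @param outdir output directory (created if needed).
#' @param seed master seed.
#' @param verbose print stage log lines as they happen.
#' @return an object of class `run_config`.
#' @export
run_config <- function(input = NULL, generator = NULL, regions = NULL,
                       n_boot = 2000, level = 0.95, threshold = 0.5,
                       deltas = c(0.2, 0.4),
                       modes = c("vary_centers", "vary_per_center"),
                       power_grids = NULL, alpha = 0.05, n_sim = 1000,
                       tau_factor = 0.25, n_cap = 2000,
                       max_power_regions = 2, outdir = "atrophypower-run",
                       seed = 1L, verbose = TRUE) {
  if (is.null(input) == is.null(generator))
    stop("give exactly one of input (CSV path) or generator (cohort_config)")
  if (!is.null(generator)) stopifnot(inherits(generator, "cohort_config"))
  modes <- match.arg(modes, several.ok = TRUE)
  stopifnot(all(deltas >= 0), all(deltas <= 1), tau_factor >= 0)
  structure(list(input = input, generator = generator, regions = regions,
                 n_boot = n_boot, level = level, threshold = threshold,
                 deltas = deltas, modes = modes, power_grids = power_grids,
                 alpha = alpha, n_sim = n_sim, tau_factor = tau_factor,
                 n_cap = n_cap, max_power_regions = max_power_regions,
                 outdir = outdir, seed = as.integer(seed),
                 verbose = isTRUE(verbose)),
            class = "run_config")
}

#' Run the full analysis pipeline
#'
#' Stages: obtain the cohort (generate or load), fit the per-study
#' adjustment model for every region, compute standardized effect sizes
#' with bootstrap CIs, participant-weighted cross-study means and the
#' medium-effect selection, normalize the effect map, extract trial
#' hyperparameters from a pooled gene-carrier fit per selected region, and
#' map power over the configured design grids with sample-size thresholds.
#' Per-region failures are isolated and recorded rather than aborting the
#' run. All outputs are written to `config$outdir` as CSV/JSON (values
#' rounded to 6 significant digits, so a rerun with the same config and
#' seed reproduces the files byte for byte) together with a line-oriented
#' log and an echo of the resolved configuration.
#'
#' @param config a [run_config()].
#' @return an object of class `run_report`: the in-memory results
#'   (`cohort`, `fits`, `effect_sizes`, `weighted`, `selection`,
#'   `normalized_map`, `power_curves`, `thresholds`, `errors`) plus
#'   `outdir` and `log` (the log lines).
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "run_config"))
  dir.create(config$outdir, recursive = TRUE, showWarnings = FALSE)
  log_lines <- character(0)
  log_stage <- function(...) {
    line <- paste0(format(Sys.time(), "%Y-%m-%dT%H:%M:%S"), " ", ...)
    log_lines <<- c(log_lines, line)
    if (config$verbose) message(line)
  }
  errors <- list()

  # --- cohort ---------------------------------------------------------
  if (!is.null(config$generator)) {
    cohort <- generate_cohort(config$generator,
                              seed = derive_seed(config$seed, "generate"))
    log_stage("stage=generate participants=",
              length(unique(cohort$participant)), " rows=", nrow(cohort))
  } else {
    cohort <- load_cohort_csv(config$input)
    log_stage("stage=load participants=",
              length(unique(cohort$participant)), " rows=", nrow(cohort))
  }
  regions <- config$regions %||%
    (if (!is.null(config$generator)) names(config$generator$regions) else
       outcome_columns(cohort))
  regions <- intersect(regions, names(cohort))

  # --- per-study fits and effect sizes --------------------------------
  fits <- list()
  es_rows <- list()
  for (sid in unique(cohort$study)) {
    sub <- cohort[cohort$study == sid, , drop = FALSE]
    multi_scanner <- length(unique(sub$scanner)) > 1
    for (rg in regions) {
      key <- paste(sid, rg, sep = ":")
      res <- tryCatch({
        fit <- fit_lmm(sub, default_volume_spec(rg, scanner = multi_scanner))
        adj <- adjust_baseline(fit)
        hc <- adj$group == "HC"; pre <- adj$group == "PreHD"
        tval <- standardized_effect_size(adj$adjusted_baseline[hc],
                                         adj$adjusted_baseline[pre],
                                         group_residual_sd(fit, "PreHD"))
        ci <- suppressMessages(bootstrap_ci(
          adj[adj$group %in% c("HC", "PreHD"), , drop = FALSE],
          n_boot = config$n_boot, level = config$level,
          seed = derive_seed(config$seed, "bootstrap", sid, rg)))
        list(fit = fit,
             row = data.frame(region = rg, study = sid, t = tval,
                              ci_low = ci[1], ci_high = ci[2],
                              n_hc = sum(hc), n_prehd = sum(pre),
                              stringsAsFactors = FALSE))
      }, error = function(e) e)
      if (inherits(res, "error")) {
        errors[[key]] <- conditionMessage(res)
        log_stage("stage=fit region=", rg, " study=", sid, " error=",
                  conditionMessage(res))
      } else {
        fits[[key]] <- res$fit
        es_rows[[key]] <- res$row
      }
    }
  }
  effect_sizes <- do.call(rbind, c(es_rows, list(make.row.names = FALSE)))
  log_stage("stage=effects regions=", length(regions), " estimates=",
            nrow(effect_sizes), " exclusions=", length(errors))

  # --- weighted means, selection, normalized map ----------------------
  weighted <- vapply(unique(effect_sizes$region), function(rg) {
    sub <- effect_sizes[effect_sizes$region == rg, , drop = FALSE]
    weighted_mean_effect(stats::setNames(sub$t, sub$study),
                         stats::setNames(sub$n_hc + sub$n_prehd, sub$study))
  }, numeric(1L))
  selection <- select_regions(weighted, threshold = config$threshold)
  normalized_map <- normalize_effect_map(
    effect_sizes[, c("study", "region", "t")])
  log_stage("stage=select selected=", length(selection$selected),
            " threshold=", config$threshold)

  # --- hyperparameters and power --------------------------------------
  carriers <- cohort[cohort$group %in% c("PreHD", "HD"), , drop = FALSE]
  power_regions <- utils::head(selection$selected, config$max_power_regions)
  power_curves <- list()
  thr_rows <- list()
  for (rg in power_regions) {
    # no time:age term here: with uncentered age it would turn the time
    # coefficient into an age-zero extrapolation rather than the cohort's
    # mean progression slope
    hyper <- tryCatch({
      pooled <- fit_lmm(carriers, model_spec(
        rg, c("time", "age", "sex", "tiv")))
      extract_hyperparameters(pooled)
    }, error = function(e) e)
    if (inherits(hyper, "error")) {
      errors[[paste0("hyper:", rg)]] <- conditionMessage(hyper)
      log_stage("stage=hyper region=", rg, " error=",
                conditionMessage(hyper))
      next
    }
    for (delta in config$deltas) {
      hy <- hyper
      hy$tau_treatment <- config$tau_factor * delta
      for (mode in config$modes) {
        key <- paste(rg, delta, mode, sep = ":")
        cv <- tryCatch(
          power_curve(mode, hy, delta = delta, alpha = config$alpha,
                      n_sim = config$n_sim,
                      seed = derive_seed(config$seed, "trial", rg),
                      grid = config$power_grids[[mode]],
                      n_cap = config$n_cap, outcome = rg),
          error = function(e) e)
        if (inherits(cv, "error")) {
          errors[[key]] <- conditionMessage(cv)
          log_stage("stage=power region=", rg, " error=",
                    conditionMessage(cv))
          next
        }
        power_curves[[key]] <- cv
        thr_rows[[key]] <- data.frame(
          outcome = rg, delta = delta, mode = mode,
          threshold_n = cv$threshold_n, stringsAsFactors = FALSE)
        log_stage("stage=power region=", rg, " delta=", delta, " mode=",
                  mode, " points=", nrow(cv$grid), " sims=",
                  config$n_sim * nrow(cv$grid), " threshold=",
                  ifelse(is.na(cv$threshold_n), "none", cv$threshold_n))
      }
    }
  }
  thresholds <- if (length(thr_rows))
    do.call(rbind, c(thr_rows, list(make.row.names = FALSE))) else
      data.frame(outcome = character(), delta = numeric(),
                 mode = character(), threshold_n = integer())

  report <- structure(list(
    cohort = cohort, fits = fits, effect_sizes = effect_sizes,
    weighted = weighted, selection = selection,
    normalized_map = normalized_map, power_curves = power_curves,
    thresholds = thresholds, errors = errors, outdir = config$outdir,
    config = config, log = log_lines), class = "run_report")
  write_run_report(report)
  report
}

sig6 <- function(df) {
  for (cn in names(df)) if (is.numeric(df[[cn]]) && !is.integer(df[[cn]]))
    df[[cn]] <- signif(df[[cn]], 6)
  df
}

write_run_report <- function(report) {
  out <- report$outdir
  cfg <- report$config
  write_cohort_csv(report$cohort, file.path(out, "cohort.csv"))
  fitlist <- lapply(report$fits, function(f)
    jsonlite::fromJSON(fit_to_json(f)))
  jsonlite::write_json(fitlist, file.path(out, "fits.json"),
                       auto_unbox = TRUE, digits = 8)
  write.csv(sig6(report$effect_sizes), file.path(out, "effect_sizes.csv"),
            row.names = FALSE, quote = FALSE)
  jsonlite::write_json(
    list(weighted_t = as.list(signif(report$weighted, 6)),
         threshold = report$selection$threshold,
         selected = report$selection$selected),
    file.path(out, "selection.json"), auto_unbox = TRUE, digits = NA)
  jsonlite::write_json(sig6(report$normalized_map),
                       file.path(out, "normalized_effect_map.json"),
                       digits = NA)
  curves <- lapply(names(report$power_curves), function(k) {
    cv <- report$power_curves[[k]]
    cbind(data.frame(outcome = cv$outcome, delta = cv$delta, mode = cv$mode),
          sig6(cv$grid))
  })
  if (length(curves))
    write.csv(do.call(rbind, curves), file.path(out, "power_curves.csv"),
              row.names = FALSE, quote = FALSE)
  jsonlite::write_json(sig6(report$thresholds),
                       file.path(out, "thresholds.json"), auto_unbox = TRUE,
                       digits = NA, na = "null")
  cfg_echo <- unclass(cfg)
  cfg_echo$generator <- if (!is.null(cfg$generator)) "inline cohort_config"
  jsonlite::write_json(cfg_echo, file.path(out, "config_echo.json"),
                       auto_unbox = TRUE, digits = NA, null = "null")
  writeLines(report$log, file.path(out, "run.log"))
  invisible(out)
}

#' @export
print.run_report <- function(x, ...) {
  cat("Pipeline run ->", x$outdir, "\n")
  cat(" ", length(unique(x$cohort$participant)), "participants,",
      nrow(x$effect_sizes), "effect-size estimates,",
      length(x$selection$selected), "selected regions,",
      length(x$power_curves), "power curves\n")
  if (length(x$errors))
    cat("  errors:", paste(names(x$errors), collapse = ", "), "\n")
  invisible(x)
}
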
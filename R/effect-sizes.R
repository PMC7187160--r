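#' Standardized effect size between control and premanifest groups
#'
#' Defined as the difference in (adjusted) means between the healthy-control
#' and premanifest groups divided by the residual standard deviation in the
#' premanifest group. Atrophied regions therefore give positive values and
#' enlarging compartments (e.g. CSF) negative values; the magnitude is read
#' against Cohen's small/medium/large anchors (0.2 / 0.5 / 0.8).
#'
#' @param hc_adjusted adjusted baseline values of the control group (mL).
#' @param prehd_adjusted adjusted baseline values of the premanifest group.
#' @param prehd_resid_sd residual SD in the premanifest group (> 0), e.g.
#'   from [group_residual_sd()].
#' @return dimensionless effect size.
#' @export
standardized_effect_size <- function(hc_adjusted, prehd_adjusted,
                                     prehd_resid_sd) {
  if (!length(hc_adjusted) || !length(prehd_adjusted))
    stop("both groups must be non-empty")
  if (!is.finite(prehd_resid_sd) || prehd_resid_sd <= 0)
    stop("prehd_resid_sd must be > 0")
  (mean(hc_adjusted) - mean(prehd_adjusted)) / prehd_resid_sd
}

default_es_statistic <- function(adj) {
  hc <- adj$group == "HC"
  pre <- adj$group == "PreHD"
  standardized_effect_size(adj$adjusted_baseline[hc],
                           adj$adjusted_baseline[pre],
                           sd(adj$residual[pre]))
}

#' Bootstrap percentile confidence interval for an effect-size statistic
#'
#' Resamples participants with replacement, stratified by group (controls
#' and premanifest participants are resampled separately with their group
#' sizes preserved), recomputes the statistic on each resample, and returns
#' the percentile interval. Degenerate resamples in which the statistic is
#' undefined (zero premanifest residual SD) are redrawn, with the count
#' reported as the `n_redrawn` attribute.
#'
#' @param adjusted per-participant adjusted data: a `data.frame` with
#'   columns `group`, `adjusted_baseline`, `residual` (as returned by
#'   [adjust_baseline()]).
#' @param statistic function of such a `data.frame` returning a scalar;
#'   default is the standardized HC-vs-PreHD effect size.
#' @param n_boot number of bootstrap replications (>= 100; 2,000 by
#'   default).
#' @param level confidence level (default 0.95).
#' @param seed integer seed; the interval is deterministic given the seed.
#' @return numeric `c(ci_low, ci_high)` with attributes `estimate` (the
#'   point estimate on the original data) and `n_redrawn`.
#' @export
bootstrap_ci <- function(adjusted, statistic = default_es_statistic,
                         n_boot = 2000, level = 0.95, seed = 1L) {
  stopifnot(is.data.frame(adjusted), n_boot >= 100, level > 0, level < 1)
  groups <- split(seq_len(nrow(adjusted)), adjusted$group)
  est <- statistic(adjusted)
  n_redrawn <- 0L
  stats_boot <- numeric(n_boot)
  with_seed(seed, {
    for (b in seq_len(n_boot)) {
      repeat {
        idx <- unlist(lapply(groups, function(ii)
          ii[sample.int(length(ii), length(ii), replace = TRUE)]),
          use.names = FALSE)
        val <- tryCatch(statistic(adjusted[idx, , drop = FALSE]),
                        error = function(e) NA_real_)
        if (is.finite(val)) break
        n_redrawn <- n_redrawn + 1L
        if (n_redrawn > 100 * n_boot)
          stop("bootstrap statistic undefined on virtually all resamples")
      }
      stats_boot[b] <- val
    }
  })
  if (n_redrawn > 0)
    message(n_redrawn, " degenerate bootstrap resample(s) redrawn")
  alpha <- (1 - level) / 2
  ci <- unname(stats::quantile(stats_boot, c(alpha, 1 - alpha), type = 7))
  structure(ci, estimate = est, n_redrawn = n_redrawn)
}

#' Per-region, per-study standardized effect sizes with bootstrap CIs
#'
#' For each study and region: fits the adjustment model within the study
#' (adding a scanner term when the study spans several scanners), computes
#' adjusted baseline volumes, and derives the standardized HC-vs-PreHD
#' effect size with a stratified bootstrap percentile CI.
#'
#' @param table a `cohort_table` covering groups HC and PreHD.
#' @param regions character vector of region column names.
#' @param n_boot,level bootstrap settings (see [bootstrap_ci()]).
#' @param seed master seed; each (study, region) bootstrap gets a derived
#'   sub-seed.
#' @param resid_type `"conditional"` or `"marginal"` residual SD.
#' @return a `data.frame`: `region, study, t, ci_low, ci_high, n_hc,
#'   n_prehd`.
#' @export
effect_size_table <- function(table, regions, n_boot = 2000, level = 0.95,
                              seed = 1L,
                              resid_type = c("conditional", "marginal")) {
  resid_type <- match.arg(resid_type)
  stopifnot(all(regions %in% names(table)))
  rows <- list()
  for (sid in unique(table$study)) {
    sub <- table[table$study == sid, , drop = FALSE]
    multi_scanner <- length(unique(sub$scanner)) > 1
    for (rg in regions) {
      fit <- fit_lmm(sub, default_volume_spec(rg, scanner = multi_scanner))
      adj <- adjust_baseline(fit)
      # effect-size denominator: residual SD in the PreHD group; the
      # bootstrap recomputes it from the resampled participants' residuals
      hc <- adj$group == "HC"; pre <- adj$group == "PreHD"
      if (sum(hc) < 2 || sum(pre) < 2) {
        message("skipping ", rg, " in ", sid, ": fewer than 2 per group")
        next
      }
      tval <- standardized_effect_size(adj$adjusted_baseline[hc],
                                       adj$adjusted_baseline[pre],
                                       group_residual_sd(fit, "PreHD",
                                                         resid_type))
      stat <- if (resid_type == "conditional") default_es_statistic else
        function(a) standardized_effect_size(
          a$adjusted_baseline[a$group == "HC"],
          a$adjusted_baseline[a$group == "PreHD"],
          sd(a$residual[a$group == "PreHD"]))
      ci <- bootstrap_ci(adj[adj$group %in% c("HC", "PreHD"), , drop = FALSE],
                         statistic = stat, n_boot = n_boot, level = level,
                         seed = derive_seed(seed, "bootstrap", sid, rg))
      rows[[length(rows) + 1L]] <- data.frame(
        region = rg, study = sid, t = tval, ci_low = ci[1], ci_high = ci[2],
        n_hc = sum(hc), n_prehd = sum(pre), stringsAsFactors = FALSE)
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Participant-weighted mean effect size across studies
#'
#' Weights are the total number of HC plus PreHD participants contributing
#' to each study's estimate.
#'
#' @param per_study_t named numeric, effect size per study.
#' @param per_study_n named numeric, participant count per study (> 0), with
#'   the same names.
#' @return weighted mean, `sum(n * t) / sum(n)`.
#' @export
weighted_mean_effect <- function(per_study_t, per_study_n) {
  if (is.null(names(per_study_t)) || is.null(names(per_study_n)) ||
      !setequal(names(per_study_t), names(per_study_n)))
    stop("per_study_t and per_study_n must share the same study names")
  n <- per_study_n[names(per_study_t)]
  if (any(n <= 0)) stop("all study counts must be > 0")
  sum(n * per_study_t) / sum(n)
}

#' Select regions by weighted absolute effect size
#'
#' Regions whose participant-weighted absolute mean standardized effect size
#' strictly exceeds the threshold (default 0.5, Cohen's medium-effect
#' anchor), ordered by descending `|t|` with lexicographic tie-breaking.
#'
#' @param weighted_t named numeric, weighted mean effect size per region.
#' @param threshold selection threshold (strict inequality).
#' @return an object of class `region_selection` with fields `weighted_t`,
#'   `threshold`, `selected`.
#' @export
select_regions <- function(weighted_t, threshold = 0.5) {
  stopifnot(is.numeric(weighted_t), length(weighted_t) > 0,
            !is.null(names(weighted_t)))
  keep <- names(weighted_t)[abs(weighted_t) > threshold]
  ord <- keep[order(-abs(weighted_t[keep]), keep)]
  structure(list(weighted_t = weighted_t, threshold = threshold,
                 selected = ord),
            class = "region_selection")
}

#' @export
print.region_selection <- function(x, ...) {
  cat(length(x$selected), "region(s) with |weighted t| >", x$threshold, "\n")
  for (rg in x$selected)
    cat(sprintf("  %-24s %+.3f\n", rg, x$weighted_t[[rg]]))
  invisible(x)
}

#' Normalize an effect-size map to its largest magnitude
#'
#' Divides every (study, region) effect size by the maximum absolute effect
#' size across all studies and regions, mapping the map into [-1, 1] for
#' cross-study visual comparison.
#'
#' @param t_by_study_region `data.frame` with columns `study`, `region`,
#'   `t`, or a numeric matrix (studies x regions).
#' @return same shape, with `t` replaced by its normalized value.
#' @export
normalize_effect_map <- function(t_by_study_region) {
  vals <- if (is.data.frame(t_by_study_region)) t_by_study_region$t else
    t_by_study_region
  m <- max(abs(vals), na.rm = TRUE)
  if (!is.finite(m) || m == 0)
    stop("all effect sizes are zero; nothing to normalize")
  if (is.data.frame(t_by_study_region)) {
    t_by_study_region$t <- t_by_study_region$t / m
  } else {
    t_by_study_region <- t_by_study_region / m
  }
  t_by_study_region
}

#' Bootstrap test for an effect-size difference between two studies
#'
#' Resamples both studies' per-participant adjusted data (stratified by
#' group), forms the bootstrap distribution of the effect-size difference,
#' and returns a two-sided percentile-bootstrap p value (the smallest level
#' at which the percentile interval excludes zero).
#'
#' @param adjusted1,adjusted2 per-participant adjusted data for the two
#'   studies (see [bootstrap_ci()]).
#' @param n_boot replications (default 2,000).
#' @param seed integer seed.
#' @return list with `diff` (point estimate) and `p`.
#' @export
compare_effect_sizes <- function(adjusted1, adjusted2, n_boot = 2000,
                                 seed = 1L) {
  d0 <- default_es_statistic(adjusted1) - default_es_statistic(adjusted2)
  g1 <- split(seq_len(nrow(adjusted1)), adjusted1$group)
  g2 <- split(seq_len(nrow(adjusted2)), adjusted2$group)
  diffs <- numeric(n_boot)
  with_seed(seed, {
    for (b in seq_len(n_boot)) {
      i1 <- unlist(lapply(g1, function(ii)
        ii[sample.int(length(ii), length(ii), replace = TRUE)]),
        use.names = FALSE)
      i2 <- unlist(lapply(g2, function(ii)
        ii[sample.int(length(ii), length(ii), replace = TRUE)]),
        use.names = FALSE)
      diffs[b] <- default_es_statistic(adjusted1[i1, , drop = FALSE]) -
        default_es_statistic(adjusted2[i2, , drop = FALSE])
    }
  })
  p_one <- min(mean(diffs <= 0), mean(diffs >= 0))
  list(diff = d0, p = min(1, 2 * max(p_one, 1 / n_boot)))
}
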
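#' Generate a synthetic multicenter longitudinal cohort
#'
#' Draws a complete participant-visit table with the nested structure the
#' downstream mixed models assume: participants nested in centers nested in
#' studies, every participant observed at every visit time on a single
#' scanner. Regional volumes follow
#' \deqn{y = \mu + \beta_{age}(age - age_{ref}) + \beta_{sex} sex +
#'   \beta_{tiv}(TIV - TIV_{ref}) + offset_{group} + slope_{group} t +
#'   s_{scanner} + u_{center} + u_{subject} + \varepsilon}
#' with \eqn{u_{center} \sim N(0, \sigma^2_{center})},
#' \eqn{u_{subject} \sim N(0, \sigma^2_{subject})} and i.i.d. visit noise
#' \eqn{\varepsilon \sim N(0, \sigma^2_{resid})}. Clinical markers use the
#' same nested structure without the imaging covariates.
#'
#' @param config a [cohort_config()] object.
#' @param seed integer seed; the same seed reproduces the table bit for bit.
#' @return a `data.frame` of class `cohort_table`, one row per
#'   participant-visit, with columns `study, center, participant, visit,
#'   time, age, sex, tiv, group, scanner, cag` followed by one column per
#'   region and per clinical marker. Sex is coded 0 = female, 1 = male.
#' @export
generate_cohort <- function(config, seed = 1L) {
  stopifnot(inherits(config, "cohort_config"))
  with_seed(seed, {
    blocks <- lapply(config$studies, generate_study_block, config = config)
    tab <- do.call(rbind, blocks)
  })
  rownames(tab) <- NULL
  bad <- names(config$regions)[vapply(names(config$regions),
                                      function(r) any(tab[[r]] <= 0),
                                      logical(1L))]
  if (length(bad))
    warning("nonpositive generated volumes in: ", paste(bad, collapse = ", "),
            " (check baseline_mean against the noise SDs)")
  class(tab) <- c("cohort_table", "data.frame")
  tab
}

generate_study_block <- function(study, config) {
  n_tot <- sum(study$n_group)
  # round-robin allocation of each group's total across centers
  center_of <- unlist(lapply(GROUPS, function(g)
    rep_len(seq_len(study$n_centers), study$n_group[[g]])), use.names = FALSE)
  group <- rep(GROUPS, times = study$n_group)
  ord <- order(center_of, match(group, GROUPS))
  center_of <- center_of[ord]; group <- group[ord]

  age <- tiv <- cag <- sex <- numeric(n_tot)
  for (g in GROUPS) {
    idx <- which(group == g)
    if (!length(idx)) next
    age[idx] <- rnorm(length(idx), study$age[[g]][1], study$age[[g]][2])
    sex[idx] <- rbinom(length(idx), 1, study$sex_male[[g]])
    cag[idx] <- if (g == "HC") {
      rtruncnorm(length(idx), study$cag[[g]][1], study$cag[[g]][2],
                 upper = 35.999)
    } else {
      rtruncnorm(length(idx), study$cag[[g]][1], study$cag[[g]][2],
                 lower = 36)
    }
  }
  tiv <- rnorm(n_tot, study$tiv[1], study$tiv[2])
  age <- pmax(age, 18)  # adult cohorts

  times <- config$visit_times
  n_vis <- length(times)
  row_id <- rep(seq_len(n_tot), each = n_vis)
  tab <- data.frame(
    study = study$study_id,
    center = sprintf("%s-C%02d", study$study_id, center_of[row_id]),
    participant = sprintf("%s-C%02d-P%04d", study$study_id, center_of[row_id],
                          row_id),
    visit = rep(seq_len(n_vis), times = n_tot),
    time = rep(times, times = n_tot),
    age = age[row_id], sex = sex[row_id], tiv = tiv[row_id],
    group = group[row_id],
    scanner = study$scanners[center_of[row_id]],
    cag = round(cag[row_id]),
    stringsAsFactors = FALSE)

  scanner_levels <- unique(study$scanners)
  for (rn in names(config$regions)) {
    p <- config$regions[[rn]]
    scan_off <- if (p$sigma_scanner > 0) {
      stats::setNames(rnorm(length(scanner_levels), 0, p$sigma_scanner),
                      scanner_levels)
    } else stats::setNames(numeric(length(scanner_levels)), scanner_levels)
    u_center <- rnorm(study$n_centers, 0, p$sigma_center)
    u_subj <- rnorm(n_tot, 0, p$sigma_subject)
    eps <- rnorm(n_tot * n_vis, 0, p$sigma_resid)
    tab[[rn]] <- p$baseline_mean +
      p$b_age * (tab$age - config$age_ref) + p$b_sex * tab$sex +
      p$b_tiv * (tab$tiv - config$tiv_ref) +
      p$offset[tab$group] + p$slope[tab$group] * tab$time +
      scan_off[tab$scanner] + u_center[center_of[row_id]] + u_subj[row_id] +
      eps
  }
  for (mn in names(config$markers)) {
    p <- config$markers[[mn]]
    u_center <- rnorm(study$n_centers, 0, p$sigma_center)
    u_subj <- rnorm(n_tot, 0, p$sigma_subject)
    eps <- rnorm(n_tot * n_vis, 0, p$sigma_resid)
    tab[[mn]] <- p$intercept + p$offset[tab$group] +
      p$slope[tab$group] * tab$time +
      u_center[center_of[row_id]] + u_subj[row_id] + eps
  }
  tab
}

#' Disease burden score
#'
#' Lifetime-exposure proxy for Huntington disease pathology:
#' `age * (CAG - 35.5)`, with age in years at measurement and CAG the repeat
#' length of the expanded huntingtin allele.
#'
#' @param age age in years (> 0).
#' @param cag CAG repeat length.
#' @return numeric burden score (vectorized).
#' @export
compute_burden_score <- function(age, cag) {
  if (any(age <= 0)) stop("age must be positive")
  age * (cag - 35.5)
}

#' Total intracranial volume from tissue compartments
#'
#' TIV is the sum of cerebrospinal fluid, cortical gray matter, deep gray
#' matter, and white matter volumes.
#'
#' @param csf,cortical_gm,deep_gm,wm compartment volumes (mL), all >= 0.
#' @return total intracranial volume in the same units (vectorized).
#' @export
compute_tiv <- function(csf, cortical_gm, deep_gm, wm) {
  if (any(c(csf, cortical_gm, deep_gm, wm) < 0))
    stop("compartment volumes must be >= 0")
  csf + cortical_gm + deep_gm + wm
}

#' Combine left/right regional volumes into bilateral totals
#'
#' Hemispheric atrophy differences are small in Huntington disease, so
#' lateralized atlas regions are summed into bilateral volumes. Region names
#' carrying a `Left-`/`Right-` prefix (case-insensitive) are paired and
#' summed under the base name; midline regions pass through unchanged.
#'
#' @param volumes named numeric vector of regional volumes (mL).
#' @return named numeric vector with one entry per bilateral pair or midline
#'   region.
#' @export
combine_bilateral <- function(volumes) {
  stopifnot(is.numeric(volumes), !is.null(names(volumes)))
  nm <- names(volumes)
  left <- grepl("^left-", nm, ignore.case = TRUE)
  right <- grepl("^right-", nm, ignore.case = TRUE)
  base <- sub("^(left|right)-", "", nm, ignore.case = TRUE)
  lbase <- base[left]; rbase <- base[right]
  orphans <- c(setdiff(lbase, rbase), setdiff(rbase, lbase))
  if (length(orphans))
    stop("unpaired lateralized region(s): ", paste(orphans, collapse = ", "))
  if (anyDuplicated(lbase) || anyDuplicated(rbase))
    stop("duplicated lateralized region names")
  out <- volumes[!(left | right)]
  if (length(lbase)) {
    combined <- volumes[left][order(lbase)] +
      volumes[right][match(sort(lbase), rbase)]
    names(combined) <- sort(lbase)
    out <- c(out, combined)
  }
  out
}
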
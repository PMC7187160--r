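FIXED_TERM_VOCAB <- c("time", "age", "sex", "tiv", "group", "time:age",
                      "scanner", "voxel_size", "study:group")

#' Specify a nested random-intercept mixed model
#'
#' The model family is fixed: Gaussian response, fixed effects drawn from a
#' small vocabulary (`time, age, sex, tiv, group, time:age, scanner,
#' voxel_size, study:group`), and random intercepts for center and for
#' participant nested in center. `study:group` implies the `study` main
#' effect. Estimation is by REML by default.
#'
#' @param response name of the outcome column (region or clinical marker).
#' @param fixed_terms character vector of fixed-effect terms beyond the
#'   intercept (always included).
#' @param random `c("center", "participant")` for the nested two-level
#'   structure (default) or `"center"` for a single random intercept.
#' @param reml logical, fit by REML (default) or ML.
#' @return an object of class `model_spec`.
#' @export
model_spec <- function(response,
                       fixed_terms = c("time", "age", "sex", "tiv", "group",
                                       "time:age"),
                       random = c("center", "participant"), reml = TRUE) {
  stopifnot(is.character(response), length(response) == 1L)
  bad <- setdiff(fixed_terms, FIXED_TERM_VOCAB)
  if (length(bad))
    stop("unknown fixed term(s): ", paste(bad, collapse = ", "),
         " (vocabulary: ", paste(FIXED_TERM_VOCAB, collapse = ", "), ")")
  if (!all(random %in% c("center", "participant")) || !"center" %in% random)
    stop("random structure must be 'center' or c('center', 'participant')")
  if ("study:group" %in% fixed_terms)
    fixed_terms <- union(c(setdiff(fixed_terms, "study:group"), "study"),
                         "study:group")
  structure(list(response = response, fixed_terms = fixed_terms,
                 random = random, reml = isTRUE(reml)),
            class = "model_spec")
}

#' Default per-region adjustment model
#'
#' Time, age, sex, TIV, group and the time-by-age interaction as fixed
#' effects; scanner added for multi-scanner studies.
#'
#' @param response outcome column name.
#' @param scanner include a scanner fixed effect.
#' @return a [model_spec()].
#' @export
default_volume_spec <- function(response, scanner = FALSE) {
  terms <- c("time", "age", "sex", "tiv", "group", "time:age")
  if (scanner) terms <- c(terms, "scanner")
  model_spec(response, terms)
}

spec_formula <- function(spec, data) {
  fixed <- spec$fixed_terms
  # drop constant factors that would make the design rank-deficient by
  # construction (e.g. a single-scanner study)
  for (tm in intersect(c("scanner", "voxel_size"), fixed)) {
    if (!tm %in% names(data) || length(unique(data[[tm]])) < 2)
      fixed <- setdiff(fixed, tm)
  }
  rand <- if (identical(spec$random, "center")) "(1 | center)" else
    "(1 | center/participant)"
  rhs <- paste(c("1", fixed, rand), collapse = " + ")
  stats::as.formula(paste(spec$response, "~", rhs))
}

prepare_frame <- function(table, spec) {
  need <- unique(c(spec$response, "center",
                   if ("participant" %in% spec$random) "participant",
                   unlist(strsplit(spec$fixed_terms, ":", fixed = TRUE))))
  missing_cols <- setdiff(need, names(table))
  if (length(missing_cols))
    stop("table lacks column(s): ", paste(missing_cols, collapse = ", "))
  df <- as.data.frame(table)[, unique(c(need, intersect(
    c("participant", "group", "study", "time"), names(table)))), drop = FALSE]
  if ("group" %in% names(df))
    df$group <- factor(df$group, levels = intersect(GROUPS, unique(df$group)))
  for (fc in intersect(c("scanner", "voxel_size", "study"), names(df)))
    df[[fc]] <- factor(df[[fc]])
  df
}

#' Fit the nested random-intercept linear mixed model
#'
#' Fits `response ~ fixed terms + (1 | center/participant)` by REML using
#' \pkg{lme4}. With a single center the center intercept is dropped (its
#' variance is reported as 0, with a message). Non-convergence triggers up to
#' two refits with alternative optimizers (bobyqa, then Nelder-Mead); a fit
#' that still fails is returned with `converged = FALSE`, never silently.
#' Wald standard errors and t tests use residual degrees of freedom
#' `n_obs - rank(X)`.
#'
#' @param table a `cohort_table` or compatible `data.frame`.
#' @param spec a [model_spec()].
#' @return an object of class `fitted_lmm`: fixed-effect table `beta`
#'   (estimate, SE, t, p), variance components `sigma2_center`,
#'   `sigma2_subject`, `sigma2_resid`, the REML log-likelihood, convergence
#'   flag, dimensions, and the underlying \pkg{lme4} fit in `$model`.
#' @export
fit_lmm <- function(table, spec) {
  stopifnot(inherits(spec, "model_spec"))
  df <- prepare_frame(table, spec)
  n_centers <- length(unique(df$center))
  form <- spec_formula(spec, df)
  fixed_form <- lme4::nobars(form)
  X <- stats::model.matrix(fixed_form, df)
  qrX <- qr(X)
  if (qrX$rank < ncol(X)) {
    drop_cols <- colnames(X)[qrX$pivot[(qrX$rank + 1):ncol(X)]]
    stop("rank-deficient fixed-effect design; collinear column(s): ",
         paste(drop_cols, collapse = ", "))
  }

  if (n_centers < 2) {
    if (!"participant" %in% spec$random)
      stop("single-center data with center-only random structure")
    message("single center: center variance fixed to 0")
    form <- stats::as.formula(paste(
      spec$response, "~",
      paste(c("1", attr(stats::terms(fixed_form), "term.labels"),
              "(1 | participant)"), collapse = " + ")))
  }

  ctrl <- lme4::lmerControl(
    check.conv.singular = lme4::.makeCC(action = "ignore", tol = 1e-4))
  fit_once <- function(optimizer) {
    msgs <- character(0)
    m <- withCallingHandlers(
      lme4::lmer(form, data = df, REML = spec$reml,
                 control = if (is.null(optimizer)) ctrl else
                   lme4::lmerControl(optimizer = optimizer,
                                     check.conv.singular =
                                       lme4::.makeCC(action = "ignore",
                                                     tol = 1e-4))),
      warning = function(w) {
        msgs <<- c(msgs, conditionMessage(w))
        invokeRestart("muffleWarning")
      })
    list(model = m,
         converged = !any(grepl("converge|Hessian|unable to evaluate", msgs,
                                ignore.case = TRUE)))
  }
  res <- fit_once(NULL)
  for (opt in c("bobyqa", "Nelder_Mead")) {
    if (res$converged) break
    res <- fit_once(opt)
  }
  m <- res$model

  vc <- as.data.frame(lme4::VarCorr(m))
  pick_var <- function(grp) {
    i <- which(vc$grp == grp)
    if (length(i)) vc$vcov[i[1]] else 0
  }
  sigma2_center <- if (n_centers < 2) 0 else pick_var("center")
  sigma2_subject <- if ("participant" %in% spec$random) {
    if (n_centers < 2) pick_var("participant") else
      pick_var("participant:center")
  } else 0
  sigma2_resid <- stats::sigma(m)^2

  beta_hat <- lme4::fixef(m)
  se <- sqrt(diag(as.matrix(stats::vcov(m))))
  df_resid <- nrow(df) - qrX$rank
  tval <- beta_hat / se
  beta <- data.frame(term = names(beta_hat), estimate = unname(beta_hat),
                     se = unname(se), t = unname(tval), df = df_resid,
                     p = unname(2 * pt(-abs(tval), df_resid)),
                     stringsAsFactors = FALSE)

  structure(list(
    beta = beta, sigma2_center = sigma2_center,
    sigma2_subject = sigma2_subject, sigma2_resid = sigma2_resid,
    reml_loglik = as.numeric(stats::logLik(m)),
    converged = res$converged,
    n_obs = nrow(df), n_centers = n_centers,
    n_participants = if ("participant" %in% names(df))
      length(unique(df$participant)) else nrow(df),
    spec = spec, formula = form, frame = df, model = m),
    class = "fitted_lmm")
}

#' @export
print.fitted_lmm <- function(x, ...) {
  cat("Nested random-intercept LMM for", x$spec$response,
      if (!x$converged) "(NOT converged)", "\n")
  cat(sprintf("  %d obs, %d participants, %d centers\n", x$n_obs,
              x$n_participants, x$n_centers))
  cat(sprintf("  var components: center %.4g, subject %.4g, residual %.4g\n",
              x$sigma2_center, x$sigma2_subject, x$sigma2_resid))
  print(x$beta, digits = 4, row.names = FALSE)
  invisible(x)
}

#' Export a fitted model as JSON
#'
#' @param fit a `fitted_lmm`.
#' @param path optional file path; if `NULL`, the JSON string is returned.
#' @export
fit_to_json <- function(fit, path = NULL) {
  stopifnot(inherits(fit, "fitted_lmm"))
  payload <- list(
    response = fit$spec$response, fixed_terms = fit$spec$fixed_terms,
    beta = fit$beta,
    sigma2_center = fit$sigma2_center, sigma2_subject = fit$sigma2_subject,
    sigma2_resid = fit$sigma2_resid, reml_loglik = fit$reml_loglik,
    converged = fit$converged, n_obs = fit$n_obs,
    n_centers = fit$n_centers, n_participants = fit$n_participants)
  if (is.null(path))
    return(jsonlite::toJSON(payload, auto_unbox = TRUE, digits = NA))
  jsonlite::write_json(payload, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Covariate-adjusted baseline volumes
#'
#' The adjusted baseline volume is the observed baseline value minus the
#' fitted nuisance contributions (age, sex, TIV, scanner, voxel size, study
#' where present), with each nuisance covariate centered at its sample mean
#' over baseline records so that adjusted values stay on the observed scale.
#' Terms involving time contribute nothing at baseline (t = 0) and the group
#' contribution is retained, so group differences survive adjustment. The
#' residual is observed minus the full fitted value including predicted
#' random effects.
#'
#' @param fit a converged `fitted_lmm`.
#' @return a `data.frame` with one row per participant: `participant`,
#'   `center`, `group` (and `study` if present), `adjusted_baseline`,
#'   `residual`.
#' @export
adjust_baseline <- function(fit) {
  stopifnot(inherits(fit, "fitted_lmm"))
  if (!fit$converged) stop("refusing to adjust from a non-converged fit")
  df <- fit$frame
  t0 <- min(df$time)
  base <- df$time == t0
  if (!any(base)) stop("no baseline records")
  missing_base <- setdiff(unique(df$participant), unique(df$participant[base]))
  if (length(missing_base))
    message("excluding ", length(missing_base),
            " participant(s) without a baseline visit")

  fixed_form <- lme4::nobars(fit$formula)
  X <- stats::model.matrix(fixed_form, df)
  trm <- stats::terms(fixed_form)
  labels <- attr(trm, "term.labels")
  nuis <- labels[!grepl("group|time", labels)]
  asgn <- attr(X, "assign")
  nuis_cols <- which(asgn %in% match(nuis, labels))
  beta_hat <- lme4::fixef(fit$model)

  Xb <- X[base, , drop = FALSE]
  y <- df[[fit$spec$response]][base]
  adj <- y
  if (length(nuis_cols)) {
    Xn <- Xb[, nuis_cols, drop = FALSE]
    Xn_c <- sweep(Xn, 2, colMeans(Xn))
    adj <- y - as.numeric(Xn_c %*% beta_hat[nuis_cols])
  }
  out <- data.frame(participant = df$participant[base],
                    center = as.character(df$center[base]),
                    group = as.character(df$group[base]),
                    stringsAsFactors = FALSE)
  if ("study" %in% names(df)) out$study <- as.character(df$study[base])
  out$adjusted_baseline <- adj
  out$residual <- stats::residuals(fit$model)[base]
  out
}

#' Residual standard deviation within a group
#'
#' The denominator of the standardized effect size. Conditional residuals
#' (observed minus fitted including predicted random effects) are the
#' default; marginal residuals (observed minus fixed-effect prediction) are
#' available as a switch.
#'
#' @param fit a `fitted_lmm` whose model includes `group`.
#' @param group group label (default `"PreHD"`).
#' @param type `"conditional"` (default) or `"marginal"`.
#' @return the residual SD over all records of that group.
#' @export
group_residual_sd <- function(fit, group = "PreHD",
                              type = c("conditional", "marginal")) {
  type <- match.arg(type)
  stopifnot(inherits(fit, "fitted_lmm"), "group" %in% names(fit$frame))
  sel <- fit$frame$group == group
  if (!any(sel)) stop("no records in group ", group)
  r <- if (type == "conditional") {
    stats::residuals(fit$model)
  } else {
    X <- stats::model.matrix(lme4::nobars(fit$formula), fit$frame)
    fit$frame[[fit$spec$response]] - as.numeric(X %*% lme4::fixef(fit$model))
  }
  sd(r[sel])
}

#' Test study-by-group interactions
#'
#' Fits the adjustment model on the pooled multi-study table with a
#' `study:group` interaction and, for every pair of studies and every
#' non-control group they share, Wald-tests whether the group effect differs
#' between the two studies. P values are Bonferroni-adjusted over the number
#' of contrasts tested. Study-group cells with fewer than 2 participants are
#' skipped with a message.
#'
#' @param table pooled `cohort_table` covering at least 2 studies.
#' @param spec a [model_spec()] for the response; `study:group` is added
#'   automatically.
#' @return a `data.frame` with columns `group, study1, study2, estimate, se,
#'   t, p, p_adj` (zero rows if fewer than 2 studies share 2 groups).
#' @export
test_study_group_interaction <- function(table, spec) {
  stopifnot(inherits(spec, "model_spec"))
  empty <- data.frame(group = character(), study1 = character(),
                      study2 = character(), estimate = numeric(),
                      se = numeric(), t = numeric(), p = numeric(),
                      p_adj = numeric(), stringsAsFactors = FALSE)
  studies <- unique(table$study)
  if (length(studies) < 2) return(empty)

  ispec <- model_spec(spec$response,
                      union(spec$fixed_terms, "study:group"),
                      random = spec$random, reml = spec$reml)
  fit <- fit_lmm(table, ispec)
  V <- as.matrix(stats::vcov(fit$model))
  beta_hat <- lme4::fixef(fit$model)
  cn <- names(beta_hat)
  df_resid <- fit$beta$df[1]

  # per-study-group participant counts at baseline
  base <- table$time == min(table$time)
  cell_n <- table(table$study[base], table$group[base])

  # interaction coefficient name for (study s, group g); the reference
  # study's coefficient is identically 0
  ref_study <- levels(fit$frame$study)[1]
  ref_group <- levels(fit$frame$group)[1]
  coef_name <- function(s, g) {
    nm <- paste0("study", s, ":group", g)
    if (nm %in% cn) nm else {
      nm2 <- paste0("group", g, ":study", s)
      if (nm2 %in% cn) nm2 else NA_character_
    }
  }

  rows <- list()
  test_groups <- setdiff(levels(fit$frame$group), ref_group)
  pairs <- utils::combn(sort(studies), 2, simplify = FALSE)
  for (g in test_groups) {
    for (pr in pairs) {
      s1 <- pr[1]; s2 <- pr[2]
      has_cells <- all(c(s1, s2) %in% rownames(cell_n)) &&
        cell_n[s1, g] >= 2 && cell_n[s2, g] >= 2
      if (!has_cells) {
        message("skipping contrast ", g, ": ", s1, " vs ", s2,
                " (study-group cell with < 2 participants)")
        next
      }
      cvec <- stats::setNames(numeric(length(cn)), cn)
      for (s in c(s1, s2)) {
        if (s == ref_study) next
        nm <- coef_name(s, g)
        if (is.na(nm)) stop("interaction coefficient not found for study ",
                            s, ", group ", g)
        cvec[nm] <- if (s == s1) 1 else -1
      }
      est <- sum(cvec * beta_hat)
      se <- sqrt(as.numeric(t(cvec) %*% V %*% cvec))
      tv <- est / se
      rows[[length(rows) + 1L]] <- data.frame(
        group = g, study1 = s1, study2 = s2, estimate = est, se = se,
        t = tv, p = 2 * pt(-abs(tv), df_resid), stringsAsFactors = FALSE)
    }
  }
  if (!length(rows)) return(empty)
  out <- do.call(rbind, rows)
  out$p_adj <- pmin(1, out$p * nrow(out))
  rownames(out) <- NULL
  out
}

#' Trial hyperparameters for power simulation
#'
#' Generative parameters of a simulated placebo arm plus the between-center
#' spread of the treatment effect.
#'
#' @param baseline_mean outcome mean at baseline (mL for volumes).
#' @param placebo_slope untreated change per year (negative for atrophying
#'   regions).
#' @param sigma2_center,sigma2_subject,sigma2_resid variance components
#'   (squared outcome units), all >= 0.
#' @param tau_treatment between-center SD of the treatment-effect fraction
#'   (dimensionless, >= 0).
#' @return an object of class `trial_hyperparameters`.
#' @export
trial_hyperparameters <- function(baseline_mean, placebo_slope,
                                  sigma2_center, sigma2_subject,
                                  sigma2_resid, tau_treatment = 0) {
  if (any(c(sigma2_center, sigma2_subject, sigma2_resid) < 0))
    stop("variance components must be >= 0")
  if (tau_treatment < 0) stop("tau_treatment must be >= 0")
  structure(list(baseline_mean = baseline_mean,
                 placebo_slope = placebo_slope,
                 sigma2_center = sigma2_center,
                 sigma2_subject = sigma2_subject,
                 sigma2_resid = sigma2_resid,
                 tau_treatment = tau_treatment),
            class = "trial_hyperparameters")
}

#' Extract trial hyperparameters from a fitted model
#'
#' Maps the fitted intercept to the simulated baseline mean, the time
#' coefficient to the placebo progression slope, and copies the variance
#' components. The between-center treatment-effect SD is not identified by
#' observational data and is supplied by the caller.
#'
#' @param fit a converged `fitted_lmm` whose model includes a `time` term.
#' @param treated_fraction_sd between-center SD of the treatment-effect
#'   fraction (`tau_treatment`).
#' @return a [trial_hyperparameters()] object.
#' @export
extract_hyperparameters <- function(fit, treated_fraction_sd = 0) {
  stopifnot(inherits(fit, "fitted_lmm"))
  if (!fit$converged)
    stop("refusing to extract hyperparameters from a non-converged fit")
  if (!"time" %in% fit$beta$term)
    stop("fit has no time term; cannot derive a progression slope")
  trial_hyperparameters(
    baseline_mean = fit$beta$estimate[fit$beta$term == "(Intercept)"],
    placebo_slope = fit$beta$estimate[fit$beta$term == "time"],
    sigma2_center = fit$sigma2_center,
    sigma2_subject = fit$sigma2_subject,
    sigma2_resid = fit$sigma2_resid,
    tau_treatment = treated_fraction_sd)
}
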
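#' Define a multicenter trial design
#'
#' @param n_centers number of centers, >= 2.
#' @param n_per_center participants per center, >= 2.
#' @param allocation treated fraction within each center (default 0.5).
#' @param visit_times assessment times in years (default annual visits over
#'   2 years, i.e. 3 time points).
#' @param outcome label of the simulated outcome (informational).
#' @param delta treatment-effect fraction in [0, 1]: the proportional
#'   slowing of the placebo progression slope (0.2 = a 20% disease-
#'   modifying effect).
#' @param alpha two-sided significance level (default 0.05).
#' @param n_sim Monte-Carlo replicates for power estimation (default 1,000).
#' @return an object of class `trial_design`.
#' @export
trial_design <- function(n_centers, n_per_center, allocation = 0.5,
                         visit_times = c(0, 1, 2), outcome = "volume",
                         delta = 0.2, alpha = 0.05, n_sim = 1000) {
  stopifnot(n_centers >= 2, n_per_center >= 2,
            allocation > 0, allocation < 1,
            length(visit_times) >= 2, all(diff(visit_times) > 0),
            delta >= 0, delta <= 1, alpha > 0, alpha < 1, n_sim >= 1)
  structure(list(n_centers = as.integer(n_centers),
                 n_per_center = as.integer(n_per_center),
                 total_n = as.integer(n_centers) * as.integer(n_per_center),
                 allocation = allocation, visit_times = visit_times,
                 outcome = outcome, delta = delta, alpha = alpha,
                 n_sim = as.integer(n_sim)),
            class = "trial_design")
}

# Fixed skeleton of a simulated trial: center/participant/time columns plus
# a within-center randomized allocation.
trial_frame <- function(design, arm = NULL) {
  n_c <- design$n_centers; n_p <- design$n_per_center
  n_vis <- length(design$visit_times)
  part <- seq_len(n_c * n_p)
  if (is.null(arm)) {
    n_treat <- round(n_p * design$allocation)
    arm <- unlist(lapply(seq_len(n_c), function(cc)
      sample(rep(c(1L, 0L), c(n_treat, n_p - n_treat)))), use.names = FALSE)
  }
  data.frame(
    center = factor(rep(rep(seq_len(n_c), each = n_p), each = n_vis)),
    participant = factor(rep(part, each = n_vis)),
    arm = rep(arm, each = n_vis),
    time = rep(design$visit_times, times = n_c * n_p))
}

# Outcome draw on an existing trial frame. Center-level treatment fractions
# delta_c ~ N(delta, tau^2) truncated to [0, 1]; treated participants
# progress at placebo_slope * (1 - delta_c).
trial_outcome <- function(frame, design, hyper) {
  n_c <- design$n_centers
  n_tot <- design$total_n
  n_vis <- length(design$visit_times)
  delta_c <- rtruncnorm(n_c, design$delta, hyper$tau_treatment, 0, 1)
  u_c <- rnorm(n_c, 0, sqrt(hyper$sigma2_center))
  u_i <- rnorm(n_tot, 0, sqrt(hyper$sigma2_subject))
  eps <- rnorm(n_tot * n_vis, 0, sqrt(hyper$sigma2_resid))
  c_idx <- as.integer(frame$center)
  p_idx <- as.integer(frame$participant)
  slope <- hyper$placebo_slope * (1 - frame$arm * delta_c[c_idx])
  hyper$baseline_mean + u_c[c_idx] + u_i[p_idx] + slope * frame$time + eps
}

#' Simulate one multicenter trial
#'
#' Participants are nested in centers and randomized to treatment within
#' center at the design's allocation fraction. Untreated participants
#' decline at the placebo slope; treated participants at
#' `placebo_slope * (1 - delta_c)`, where the center-level effect fraction
#' `delta_c ~ N(delta, tau_treatment^2)` truncated to [0, 1] captures
#' between-center heterogeneity of the treatment effect. Center and subject
#' random intercepts and i.i.d. visit noise follow the hyperparameters.
#'
#' @param design a [trial_design()].
#' @param hyper a [trial_hyperparameters()] object.
#' @param seed integer seed; the dataset is deterministic given the seed.
#' @return a `data.frame` with columns `center, participant, arm, time, y`.
#' @export
simulate_trial <- function(design, hyper, seed = 1L) {
  stopifnot(inherits(design, "trial_design"),
            inherits(hyper, "trial_hyperparameters"))
  if (hyper$tau_treatment > 0 && design$n_centers == 1)
    warning("tau_treatment > 0 with a single center: ",
            "treatment-effect variance is inestimable")
  with_seed(seed, {
    frame <- trial_frame(design)
    frame$y <- trial_outcome(frame, design, hyper)
  })
  frame
}

#' Test the treatment effect in a simulated trial
#'
#' Fits `y ~ time + arm + arm:time + (1 | center/participant)` by REML and
#' returns the two-sided Wald p value for the `arm:time` coefficient — the
#' treatment-by-time interaction, i.e. the slowing of progression. The
#' denominator degrees of freedom follow the containment (between/within)
#' rule for a within-participant coefficient,
#' `n_obs - n_participants - 2`: information about the slope contrast comes
#' from within-participant changes, and pairing the within-based standard
#' error with the full residual df is anticonservative when the subject
#' variance sits near its boundary. With two visits and no random-effect
#' variance this test coincides with the two-sample t test on
#' per-participant slopes.
#'
#' @param dataset a trial `data.frame` from [simulate_trial()].
#' @return the p value, with attributes `estimate`, `se`, `converged`.
#'   `NA` (with `converged = FALSE`) if the fit fails.
#' @export
test_treatment <- function(dataset) {
  stopifnot(all(c("center", "participant", "arm", "time", "y") %in%
                  names(dataset)))
  if (length(unique(dataset$arm)) < 2) stop("both arms must be present")
  m <- tryCatch(
    suppressMessages(lme4::lmer(
      y ~ time + arm + arm:time + (1 | center / participant),
      data = dataset, REML = TRUE, control = power_lmer_control())),
    error = function(e) NULL)
  if (is.null(m))
    return(structure(NA_real_, estimate = NA_real_, se = NA_real_,
                     converged = FALSE))
  wald_arm_time(m, nrow(dataset))
}

power_lmer_control <- function() {
  lme4::lmerControl(
    check.conv.singular = lme4::.makeCC(action = "ignore", tol = 1e-4),
    calc.derivs = FALSE)
}

wald_arm_time <- function(m, n_obs) {
  beta_hat <- lme4::fixef(m)
  k <- match("time:arm", names(beta_hat))
  if (is.na(k)) k <- match("arm:time", names(beta_hat))
  se <- sqrt(diag(as.matrix(stats::vcov(m))))[k]
  # containment df for a within-participant coefficient: subtract one df
  # per participant and the two time-varying fixed terms (time, arm:time)
  df <- n_obs - max(lme4::ngrps(m)) - 2
  tv <- beta_hat[k] / se
  structure(unname(2 * pt(-abs(tv), df)), estimate = unname(beta_hat[k]),
            se = unname(se), converged = TRUE)
}

#' Estimate power for one trial design by simulation
#'
#' Simulates `n_sim` trials and reports the fraction in which the
#' treatment-by-time test rejects at the design's `alpha`. The within-center
#' allocation is drawn once per design point from the seed (participants
#' are exchangeable, so power is unaffected) which lets each replicate be
#' refitted from the same model structure; replicates whose refit fails are
#' excluded from the denominator and counted. Results are flagged if more
#' than 10% of refits fail.
#'
#' @param design a [trial_design()].
#' @param hyper a [trial_hyperparameters()] object.
#' @param seed integer seed.
#' @return an object of class `power_estimate`: design point, `power`,
#'   binomial `mc_se = sqrt(p(1-p)/n_sim)`, replicate counts and `flagged`.
#' @export
estimate_power <- function(design, hyper, seed = 1L) {
  stopifnot(inherits(design, "trial_design"),
            inherits(hyper, "trial_hyperparameters"))
  n_sim <- design$n_sim
  p_vals <- rep(NA_real_, n_sim)
  with_seed(seed, {
    frame <- trial_frame(design)
    frame$y <- trial_outcome(frame, design, hyper)
    m0 <- tryCatch(
      suppressMessages(lme4::lmer(
        y ~ time + arm + arm:time + (1 | center / participant),
        data = frame, REML = TRUE, control = power_lmer_control())),
      error = function(e) NULL)
    if (!is.null(m0)) p_vals[1] <- wald_arm_time(m0, nrow(frame))
    for (b in seq_len(n_sim)[-1]) {
      y_new <- trial_outcome(frame, design, hyper)
      m <- tryCatch(
        suppressMessages(if (is.null(m0)) {
          frame$y <- y_new
          lme4::lmer(y ~ time + arm + arm:time + (1 | center / participant),
                     data = frame, REML = TRUE,
                     control = power_lmer_control())
        } else {
          lme4::refit(m0, newresp = y_new)
        }),
        error = function(e) NULL)
      if (!is.null(m)) p_vals[b] <- wald_arm_time(m, nrow(frame))
    }
  })
  ok <- is.finite(p_vals)
  n_conv <- sum(ok)
  if (n_conv == 0) stop("no simulated trial could be fitted")
  power <- mean(p_vals[ok] < design$alpha)
  flagged <- n_conv < 0.9 * n_sim
  if (flagged)
    warning(sprintf("only %d/%d simulated fits converged", n_conv, n_sim))
  structure(list(n_centers = design$n_centers,
                 n_per_center = design$n_per_center,
                 total_n = design$total_n,
                 power = power,
                 mc_se = sqrt(power * (1 - power) / n_conv),
                 n_sim = n_sim, n_converged = n_conv, flagged = flagged,
                 delta = design$delta, alpha = design$alpha),
            class = "power_estimate")
}

#' @export
print.power_estimate <- function(x, ...) {
  cat(sprintf(
    "Power %.3f (MC SE %.3f) at Nc=%d x Nppc=%d (n=%d), delta=%.2f%s\n",
    x$power, x$mc_se, x$n_centers, x$n_per_center, x$total_n, x$delta,
    if (x$flagged) " [FLAGGED: >10% non-converged]" else ""))
  invisible(x)
}

#' Power over a grid of trial designs
#'
#' Two canonical ways to grow a multicenter trial: add centers at a fixed
#' per-center enrollment (`vary_centers`, default 6-100 centers in steps of
#' 2 with 20 participants each) or enroll more participants at a fixed set
#' of centers (`vary_per_center`, default 30-500 per center at 4 centers).
#' Totals beyond `n_cap` (default 2,000 participants) are truncated with a
#' warning. Raw Monte-Carlo power estimates are kept alongside an
#' isotonic-regression-smoothed copy used for threshold search, so MC noise
#' cannot produce spurious threshold crossings.
#'
#' @param mode `"vary_centers"` or `"vary_per_center"`.
#' @param hyper a [trial_hyperparameters()] object.
#' @param delta treatment-effect fraction.
#' @param alpha two-sided significance level.
#' @param n_sim Monte-Carlo replicates per grid point.
#' @param seed master seed; each grid point derives its own sub-seed.
#' @param grid integer vector overriding the varied quantity (centers or
#'   participants per center).
#' @param n_fixed the fixed quantity (participants per center, default 20,
#'   or centers, default 4).
#' @param n_cap maximum total participants (default 2,000).
#' @param visit_times assessment times (default `c(0, 1, 2)`).
#' @param outcome outcome label carried through to the results.
#' @return an object of class `power_curve`: `grid` (a `data.frame` with
#'   `n_centers, n_per_center, total_n, power, mc_se, power_smooth,
#'   n_converged`), `threshold_n` (smallest total with smoothed power >
#'   0.8, `NA` if not reached by `n_cap`), and the settings.
#' @export
power_curve <- function(mode = c("vary_centers", "vary_per_center"), hyper,
                        delta = 0.2, alpha = 0.05, n_sim = 1000, seed = 1L,
                        grid = NULL, n_fixed = NULL, n_cap = 2000,
                        visit_times = c(0, 1, 2), outcome = "volume") {
  mode <- match.arg(mode)
  if (mode == "vary_centers") {
    n_fixed <- n_fixed %||% 20L
    grid <- grid %||% seq(6L, 100L, by = 2L)
    designs <- lapply(grid, function(nc)
      trial_design(nc, n_fixed, visit_times = visit_times, outcome = outcome,
                   delta = delta, alpha = alpha, n_sim = n_sim))
  } else {
    n_fixed <- n_fixed %||% 4L
    grid <- grid %||% seq(30L, 500L, by = 10L)
    designs <- lapply(grid, function(np)
      trial_design(n_fixed, np, visit_times = visit_times, outcome = outcome,
                   delta = delta, alpha = alpha, n_sim = n_sim))
  }
  totals <- vapply(designs, `[[`, integer(1L), "total_n")
  if (any(totals > n_cap)) {
    warning("grid truncated at n_cap = ", n_cap, " total participants")
    designs <- designs[totals <= n_cap]
    totals <- totals[totals <= n_cap]
  }
  if (!length(designs)) stop("empty design grid after applying n_cap")
  ord <- order(totals)
  designs <- designs[ord]

  est <- lapply(designs, function(d)
    estimate_power(d, hyper,
                   seed = derive_seed(seed, "power", mode, outcome, delta,
                                      d$n_centers, d$n_per_center)))
  g <- data.frame(
    n_centers = vapply(est, `[[`, integer(1L), "n_centers"),
    n_per_center = vapply(est, `[[`, integer(1L), "n_per_center"),
    total_n = vapply(est, `[[`, integer(1L), "total_n"),
    power = vapply(est, `[[`, numeric(1L), "power"),
    mc_se = vapply(est, `[[`, numeric(1L), "mc_se"),
    n_converged = vapply(est, `[[`, numeric(1L), "n_converged"))
  g$power_smooth <- if (nrow(g) > 1)
    stats::isoreg(g$total_n, g$power)$yf else g$power

  curve <- structure(list(mode = mode, grid = g, delta = delta,
                          alpha = alpha, n_sim = n_sim, n_cap = n_cap,
                          outcome = outcome, threshold_n = NA_integer_),
                     class = "power_curve")
  curve$threshold_n <- sample_size_threshold(curve)
  curve
}

#' @export
print.power_curve <- function(x, ...) {
  cat(sprintf("Power curve (%s), delta=%.2f, alpha=%.2f, n_sim=%d\n",
              x$mode, x$delta, x$alpha, x$n_sim))
  print(x$grid, digits = 3, row.names = FALSE)
  cat("threshold n (power > 0.8):",
      if (is.na(x$threshold_n)) "not reached by cap" else x$threshold_n, "\n")
  invisible(x)
}

#' Smallest sample size reaching a power target
#'
#' Searches the isotonic-smoothed power curve for the smallest grid total
#' with power strictly above the target (default 80%). Returns `NA` when the
#' target is not reached before the participant cap — reported downstream as
#' a missing threshold.
#'
#' @param curve a [power_curve()] result, or a `data.frame` with columns
#'   `total_n` and `power` (smoothed on the fly if needed).
#' @param target power target (default 0.8).
#' @return total participant count, or `NA_integer_`.
#' @export
sample_size_threshold <- function(curve, target = 0.8) {
  g <- if (inherits(curve, "power_curve")) curve$grid else curve
  stopifnot(is.data.frame(g), all(c("total_n", "power") %in% names(g)))
  g <- g[order(g$total_n), , drop = FALSE]
  smooth <- g$power_smooth %||%
    (if (nrow(g) > 1) stats::isoreg(g$total_n, g$power)$yf else g$power)
  hit <- which(smooth > target)
  if (!length(hit)) return(NA_integer_)
  as.integer(g$total_n[hit[1]])
}
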
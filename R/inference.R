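# REML inference on simulated trials, the Monte-Carlo power loop, the
# closed-form power oracle, and the exact Blaker binomial interval.

.check_balance <- function(plots, treatments) {
  tab <- table(plots$farm_id, plots$treatment)
  if (ncol(tab) != 2L)
    .stopf("fit_lmm supports exactly two treatments (got %d)", ncol(tab))
  if (any(tab != tab[1, 1]))
    .stopf("unbalanced treatments within farms: incomplete blocks are out of scope")
  invisible(tab[1, 1])
}

# per-farm mean treatment difference (treated - control)
.farm_differences <- function(plots, treatments) {
  ag <- tapply(plots$response,
               list(plots$farm_id, plots$treatment != treatments[1]), mean)
  d <- ag[, "TRUE"] - ag[, "FALSE"]
  d[order(as.numeric(rownames(ag)))]
}

#' Fit the nested linear mixed model to plot data
#'
#' REML fit of `response ~ treatment` with random intercepts for site and
#' for farm-within-site (non-negative variances at the bound), as used to
#' analyse each simulated trial. The two-sided p-value uses a t statistic
#' with containment degrees of freedom: the treatment contrast lives at
#' plot level, so df = N - n_farms - 1, which for one plot per treatment
#' per farm equals the paired-test df (n_farms - 1).
#'
#' Restarts with alternative optimizers are attempted before flagging
#' non-convergence; a data set with (numerically) zero plot-level noise is
#' handled directly from the within-farm difference algebra.
#'
#' @param data Plot data table from [simulate_trial()] (columns `site_id`,
#'   `farm_id`, `treatment`, `response`; the first treatment level sorted
#'   ascending is the reference unless a `control` level is present).
#' @return An object of class `lmm_fit`: list with `treatment_estimate`,
#'   `treatment_se`, `variance_estimates` (site, farm, residual), `p_value`,
#'   `df`, `converged`.
#' @export
fit_lmm <- function(data) {
  need <- c("site_id", "farm_id", "treatment", "response")
  if (!all(need %in% names(data))) .stopf("`data` needs columns %s",
                                          paste(need, collapse = ", "))
  lev <- sort(unique(data$treatment))
  if ("control" %in% lev) lev <- c("control", setdiff(lev, "control"))
  .check_balance(data, lev)
  data$treatment <- factor(data$treatment, levels = lev)
  n_farms <- length(unique(data$farm_id))
  if (n_farms < 2) .stopf("need at least 2 farms")
  df <- nrow(data) - n_farms - 1L

  d <- .farm_differences(data, lev)
  if (var(data$response) < 1e-12 || var(d) < 1e-12) {
    # degenerate noise-free case: exact answer from the block algebra
    est <- mean(d)
    return(structure(list(treatment_estimate = est, treatment_se = 0,
                          variance_estimates = c(site = 0, farm = 0,
                                                 residual = 0),
                          p_value = if (abs(est) > 0) 0 else 1,
                          df = df, converged = TRUE),
                     class = "lmm_fit"))
  }

  fit <- NULL
  for (opt in c("nloptwrap", "bobyqa", "Nelder_Mead")) {
    ctrl <- lme4::lmerControl(calc.derivs = FALSE,
                              check.conv.singular = "ignore",
                              optimizer = opt,
                              optCtrl = if (opt == "nloptwrap")
                                list(xtol_abs = 1e-14, ftol_abs = 1e-14,
                                     xtol_rel = 0, ftol_rel = 0)
                              else if (opt == "bobyqa")
                                list(rhoend = 1e-12) else list())
    fit <- tryCatch(
      suppressMessages(suppressWarnings(
        lme4::lmer(response ~ treatment + (1 | site_id) + (1 | farm_id),
                   data = data, REML = TRUE, control = ctrl))),
      error = function(e) NULL)
    if (!is.null(fit) && isTRUE(fit@optinfo$conv$opt == 0)) break
  }
  if (is.null(fit)) {
    return(structure(list(treatment_estimate = NA_real_,
                          treatment_se = NA_real_,
                          variance_estimates = c(site = NA, farm = NA,
                                                 residual = NA),
                          p_value = NA_real_, df = df, converged = FALSE),
                     class = "lmm_fit"))
  }
  est <- unname(lme4::fixef(fit)[2])
  se <- sqrt(as.matrix(stats::vcov(fit))[2, 2])
  vcdf <- as.data.frame(lme4::VarCorr(fit))
  getvc <- function(g) {
    i <- match(g, vcdf$grp)
    if (is.na(i)) 0 else vcdf$vcov[i]
  }
  structure(list(
    treatment_estimate = est, treatment_se = se,
    variance_estimates = c(site = getvc("site_id"), farm = getvc("farm_id"),
                           residual = getvc("Residual")),
    p_value = 2 * pt(-abs(est / se), df = df),
    df = df,
    converged = isTRUE(fit@optinfo$conv$opt == 0)),
    class = "lmm_fit")
}

#' @export
print.lmm_fit <- function(x, ...) {
  cat(sprintf("Treatment effect %.4g (SE %.4g), t df = %d, p = %.4g%s\n",
              x$treatment_estimate, x$treatment_se, x$df, x$p_value,
              if (x$converged) "" else " [NOT converged]"))
  invisible(x)
}

#' Closed-form power of the within-farm treatment contrast
#'
#' Because every farm is a complete block, the treatment contrast is
#' estimated entirely from within-farm comparisons and its power depends
#' only on the residual variance and the number of farms: a noncentral-t
#' computation with ncp = effect / sqrt(2 sigma2_res / (r n)) and
#' df = n(2r - 1) - 1, where r is the number of plots per treatment per
#' farm. This is the independent oracle against which the simulation
#' pipeline is checked.
#'
#' @param effect Treatment effect on the analysis scale.
#' @param sigma2_res Residual variance.
#' @param n_farms Number of farms (complete blocks), >= 2.
#' @param alpha Two-sided test level (default 0.05).
#' @param plots_per_treatment Plots per treatment per farm (default 1).
#' @return Power (probability of rejection).
#' @examples
#' analytic_power(2.5, 8.3, 50)   # teff-Zn-like scenario
#' @export
analytic_power <- function(effect, sigma2_res, n_farms, alpha = 0.05,
                           plots_per_treatment = 1L) {
  .check_num(effect, "effect"); .check_num(sigma2_res, "sigma2_res", lower = 0)
  if (n_farms < 2) .stopf("`n_farms` must be >= 2")
  r <- plots_per_treatment
  df <- n_farms * (2 * r - 1) - 1
  ncp <- effect / sqrt(2 * sigma2_res / (r * n_farms))
  tc <- qt(1 - alpha / 2, df)
  pt(tc, df, ncp = ncp, lower.tail = FALSE) + pt(-tc, df, ncp = ncp)
}

# Blaker acceptability at p for observed k of n
.blaker_accept <- function(k, n, p) {
  p1 <- 1 - pbinom(k - 1, n, p)   # P(X >= k)
  p2 <- pbinom(k, n, p)           # P(X <= k)
  a1 <- p1 + pbinom(qbinom(p1, n, p) - 1, n, p)
  a2 <- p2 + 1 - pbinom(qbinom(1 - p2, n, p), n, p)
  min(a1, a2)
}

#' Blaker exact binomial confidence interval
#'
#' Inverts Blaker's acceptability function (the probability, under p, of an
#' outcome whose smaller tail probability is at most the observed one);
#' the interval is the set of p with acceptability above 1 - level. Always
#' contained in the Clopper-Pearson interval at the same level. Endpoints
#' are located by stepping inward from the Clopper-Pearson bounds to a
#' 1e-6 tolerance.
#'
#' @param k Number of successes, 0 <= k <= n.
#' @param n Number of trials.
#' @param level Confidence level (default 0.95).
#' @param tol Endpoint tolerance (default 1e-6).
#' @return Numeric vector `c(low, high)`; contains `k/n`.
#' @examples
#' blaker_ci(7, 10)
#' @export
blaker_ci <- function(k, n, level = 0.95, tol = 1e-6) {
  if (!is.numeric(k) || !is.numeric(n) || length(k) != 1 || length(n) != 1 ||
      k < 0 || n < 1 || k > n || k != round(k) || n != round(n))
    .stopf("need integers 0 <= k <= n")
  alpha <- 1 - level
  step <- 1e-4
  lower <- 0; upper <- 1
  if (k > 0) {
    # Blaker's lower bound sits at or above the Clopper-Pearson bound:
    # coarse scan upward for the acceptability crossing, then bisect
    lo <- qbeta(alpha / 2, k, n - k + 1)
    while (.blaker_accept(k, n, lo + step) < alpha) lo <- lo + step
    hi <- lo + step
    while (hi - lo > tol) {
      mid <- (lo + hi) / 2
      if (.blaker_accept(k, n, mid) < alpha) lo <- mid else hi <- mid
    }
    lower <- hi
  }
  if (k < n) {
    hi <- qbeta(1 - alpha / 2, k + 1, n - k)
    while (.blaker_accept(k, n, hi - step) < alpha) hi <- hi - step
    lo <- hi - step
    while (hi - lo > tol) {
      mid <- (lo + hi) / 2
      if (.blaker_accept(k, n, mid) < alpha) hi <- mid else lo <- mid
    }
    upper <- lo
  }
  c(low = lower, high = upper)
}

#' Monte-Carlo power of a trial design
#'
#' Simulates `n_reps` realizations of the design under the variance model
#' and treatment effect, fits the nested mixed model to each, and reports
#' the proportion of two-sided rejections at level `alpha` with its Blaker
#' 95% confidence interval. Replicate seeds derive from `seed`; the site
#' correlation Cholesky factor is computed once. Non-converged fits are
#' counted and reported, never treated as rejections.
#'
#' @param design A [make_cluster_layout()] trial design.
#' @param params A [simulation_params()] object.
#' @param n_reps Number of realizations (default 1000).
#' @param alpha Rejection threshold (default two-sided 0.05).
#' @param seed Integer seed.
#' @param ci_level Confidence level for the Blaker interval (default 0.95).
#' @return An object of class `power_result`: list with `n_reject`,
#'   `n_reps`, `power`, `ci_low`, `ci_high`, `alpha`, `n_nonconverged`,
#'   `n_farms`.
#' @export
estimate_power <- function(design, params, n_reps = 1000L, alpha = 0.05,
                           seed = 1L, ci_level = 0.95) {
  stopifnot(inherits(design, "trial_design"),
            inherits(params, "simulation_params"))
  n_reps <- as.integer(n_reps)
  ch <- if (params$vc$sigma2_site > 0)
    .site_chol(design$sites, params$vc$matern) else NULL
  set.seed(seed)
  rep_seeds <- sample.int(.Machine$integer.max - 1L, n_reps)
  n_reject <- 0L; n_nonconv <- 0L
  for (i in seq_len(n_reps)) {
    dat <- .simulate_core(design, params, rep_seeds[i], ch)
    f <- fit_lmm(dat)
    if (!f$converged) { n_nonconv <- n_nonconv + 1L; next }
    if (is.finite(f$p_value) && f$p_value < alpha) n_reject <- n_reject + 1L
  }
  ci <- blaker_ci(n_reject, n_reps, level = ci_level)
  structure(list(n_reject = n_reject, n_reps = n_reps,
                 power = n_reject / n_reps,
                 ci_low = unname(ci[1]), ci_high = unname(ci[2]),
                 alpha = alpha, n_nonconverged = n_nonconv,
                 n_farms = nrow(design$farms)),
            class = "power_result")
}

#' @export
print.power_result <- function(x, ...) {
  cat(sprintf("Power %.3f (%d/%d rejections; Blaker 95%% CI %.3f-%.3f; alpha %.3g)\n",
              x$power, x$n_reject, x$n_reps, x$ci_low, x$ci_high, x$alpha))
  if (x$n_nonconverged > 0)
    cat(sprintf("  %d non-converged fits (excluded from rejections)\n",
                x$n_nonconverged))
  invisible(x)
}
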
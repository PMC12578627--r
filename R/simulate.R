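# Plot-level response realizations under the nested spatial variance model.

#' Simulation parameters for trial realizations
#'
#' @param vc A [variance_components()] object.
#' @param effect Additive treatment effect on the analysis scale (for a
#'   log-scale variable use [percent_to_log_effect()] to convert a
#'   percentage increase).
#' @param control_mean Mean response of the control treatment on the
#'   analysis scale (the treatment contrast is invariant to it).
#' @return An object of class `simulation_params`.
#' @export
simulation_params <- function(vc, effect, control_mean = 0) {
  stopifnot(inherits(vc, "variance_components"))
  .check_num(effect, "effect"); .check_num(control_mean, "control_mean")
  structure(list(vc = vc, effect = effect, control_mean = control_mean,
                 scale = vc$scale),
            class = "simulation_params")
}

#' Convert a percentage increase to a log-scale effect
#'
#' A proportional increase of `x` percent corresponds to an additive effect
#' of `log(1 + x/100)` on the natural-log scale.
#'
#' @param x Percentage increase, > -100. Vectorized.
#' @return Effect size on the log scale.
#' @examples
#' percent_to_log_effect(50)  # log(1.5)
#' @export
percent_to_log_effect <- function(x) {
  .check_num(x, "x", allow_vec = TRUE)
  if (any(x <= -100)) .stopf("`x` must be > -100 (responses are positive)")
  log1p(x / 100)
}

# Cholesky factor of the between-site correlation matrix, reusable across
# replicates of the same design. Jitter handles near-duplicate coordinates.
.site_chol <- function(sites, matern, jitter = 1e-10) {
  D <- as.matrix(dist(sites[, c("x", "y")]))
  R <- matern_correlation(as.vector(D), matern)
  R <- matrix(R, nrow(D), nrow(D))
  diag(R) <- 1
  ch <- tryCatch(chol(R + diag(jitter, nrow(R))), error = function(e) NULL)
  if (is.null(ch)) {
    dup <- which(D + diag(Inf, nrow(D)) < 1e-9, arr.ind = TRUE)
    if (nrow(dup))
      .stopf("site correlation matrix not positive definite: sites %d and %d are (near-)coincident",
             dup[1, 1], dup[1, 2])
    .stopf("site correlation matrix not positive definite after jitter")
  }
  ch
}

# Core draw with precomputed site Cholesky; separate seeded streams per
# variance component so component ablations are paired across replicates.
.simulate_core <- function(design, params, seed, site_chol_R) {
  vc <- params$vc
  plots <- design$plots
  ord <- order(plots$site_id, plots$farm_id, plots$plot_id)
  plots <- plots[ord, ]
  ns <- nrow(design$sites); nf <- nrow(design$farms); np <- nrow(plots)
  set.seed(seed)
  seeds <- sample.int(.Machine$integer.max - 1L, 3L)
  set.seed(seeds[1])
  u <- if (vc$sigma2_site > 0)
    sqrt(vc$sigma2_site) * drop(crossprod(site_chol_R, rnorm(ns)))
  else numeric(ns)
  set.seed(seeds[2])
  v <- rnorm(nf, 0, sqrt(vc$sigma2_farm))
  set.seed(seeds[3])
  e <- rnorm(np, 0, sqrt(vc$sigma2_res))
  si <- match(plots$site_id, design$sites$site_id)
  fi <- match(plots$farm_id, design$farms$farm_id)
  treated <- plots$treatment != design$treatments[1]
  plots$response <- params$control_mean + params$effect * treated +
    u[si] + v[fi] + e
  plots[order(plots$plot_id), ]
}

#' Simulate plot-level responses for a trial design
#'
#' Draws one realization of the nested model
#' \deqn{y = \mu + \delta\,[treated] + u_{site} + v_{farm} + e_{plot},}
#' where the site effects `u` are a zero-mean Gaussian vector with
#' covariance \eqn{\varsigma^2_{site}\,\rho(h)} over the site coordinates
#' (factorized by Cholesky with a 1e-10 diagonal jitter), and the farm and
#' plot effects are iid Gaussian. Site, farm and plot components use
#' separate seeded streams derived from `seed`, and plot residuals are
#' drawn in plot-id order, so realizations are reproducible and invariant
#' to row ordering.
#'
#' @param design A [make_cluster_layout()] trial design.
#' @param params A [simulation_params()] object.
#' @param seed Integer seed.
#' @return The design's plot table with a `response` column
#'   (site_id, farm_id, plot_id, treatment, x_km, y_km, response).
#' @examples
#' d <- make_domain("rectangle", c(100, 100))
#' des <- make_cluster_layout(d, 5, 4, seed = 2)
#' dat <- simulate_trial(des, simulation_params(vc_for("teff_zn"), 2.5), seed = 9)
#' @export
simulate_trial <- function(design, params, seed = 1L) {
  stopifnot(inherits(design, "trial_design"),
            inherits(params, "simulation_params"))
  ch <- if (params$vc$sigma2_site > 0)
    .site_chol(design$sites, params$vc$matern) else NULL
  .simulate_core(design, params, seed, ch)
}

#' Write a simulated plot data table with metadata sidecar
#'
#' @param data Plot data table from [simulate_trial()].
#' @param path CSV output path; a `.json` sidecar with seed and parameters
#'   is written alongside when `meta` is given.
#' @param meta Optional named list of metadata (seed, parameters, ...).
#' @export
write_plot_data <- function(data, path, meta = NULL) {
  write.csv(data, path, row.names = FALSE, quote = FALSE)
  if (!is.null(meta))
    jsonlite::write_json(meta, paste0(sub("\\.csv$", "", path), "_meta.json"),
                         auto_unbox = TRUE, digits = NA)
  invisible(path)
}
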
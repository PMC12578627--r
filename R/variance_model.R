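#' Matern correlation parameters
#'
#' Smoothness and distance parameters of the Matern spatial correlation
#' function used for the between-site random effect.
#'
#' @param kappa Smoothness parameter, dimensionless, > 0.
#' @param phi Distance parameter, km, > 0.
#' @return An object of class `matern_params`.
#' @examples
#' matern_params(kappa = 0.5, phi = 15.9)
#' @export
matern_params <- function(kappa, phi) {
  .check_num(kappa, "kappa"); .check_num(phi, "phi")
  if (kappa <= 0) .stopf("`kappa` must be > 0")
  if (phi <= 0) .stopf("`phi` must be > 0")
  structure(list(kappa = kappa, phi = phi), class = "matern_params")
}

#' @export
print.matern_params <- function(x, ...) {
  cat(sprintf("Matern correlation: kappa = %g, phi = %g km\n", x$kappa, x$phi))
  invisible(x)
}

#' Nested spatial variance components for one response variable
#'
#' The hierarchical variance model for plot-level responses: a residual
#' (between-plot within-farm) variance, a between-farm within-site variance,
#' and a spatially correlated between-site variance with Matern correlation.
#' The total sill is the sum of the three variances.
#'
#' @param sigma2_res Residual variance, response units squared, >= 0.
#' @param sigma2_farm Between-farm within-site variance, >= 0.
#' @param sigma2_site Between-site (spatially correlated) variance, >= 0.
#' @param kappa,phi Matern parameters for the site component; alternatively
#'   pass a ready-made `matern` object.
#' @param matern Optional `matern_params` object (overrides `kappa`, `phi`).
#' @param scale Analysis scale of the variable, `"linear"` or `"log"`.
#' @param variable Optional label naming the response variable.
#' @return An object of class `variance_components`.
#' @examples
#' vc <- variance_components(17.5, 4.6, 14.4, kappa = 0.75, phi = 19.6)
#' total_sill(vc)
#' @export
variance_components <- function(sigma2_res, sigma2_farm, sigma2_site,
                                kappa = NULL, phi = NULL, matern = NULL,
                                scale = c("linear", "log"),
                                variable = NULL) {
  scale <- match.arg(scale)
  .check_num(sigma2_res, "sigma2_res", lower = 0)
  .check_num(sigma2_farm, "sigma2_farm", lower = 0)
  .check_num(sigma2_site, "sigma2_site", lower = 0)
  if (is.null(matern)) {
    if (is.null(kappa) || is.null(phi))
      .stopf("supply either `matern` or both `kappa` and `phi`")
    matern <- matern_params(kappa, phi)
  }
  if (!inherits(matern, "matern_params")) .stopf("`matern` must be matern_params")
  structure(list(sigma2_res = sigma2_res, sigma2_farm = sigma2_farm,
                 sigma2_site = sigma2_site, matern = matern,
                 scale = scale, variable = variable),
            class = "variance_components")
}

#' @export
print.variance_components <- function(x, ...) {
  cat(sprintf("Variance components%s [%s scale]\n",
              if (is.null(x$variable)) "" else paste0(" for ", x$variable),
              x$scale))
  cat(sprintf("  residual  : %g\n  farm:site : %g\n  site      : %g (Matern kappa %g, phi %g km)\n",
              x$sigma2_res, x$sigma2_farm, x$sigma2_site,
              x$matern$kappa, x$matern$phi))
  cat(sprintf("  total sill: %g\n", total_sill(x)))
  invisible(x)
}

#' Total sill of a nested variance model
#'
#' @param vc A [variance_components()] object.
#' @return Sum of the residual, farm and site variances.
#' @export
total_sill <- function(vc) {
  stopifnot(inherits(vc, "variance_components"))
  vc$sigma2_res + vc$sigma2_farm + vc$sigma2_site
}

#' Matern spatial correlation function
#'
#' \deqn{\rho(h) = \frac{1}{2^{\kappa-1}\Gamma(\kappa)}
#'   \left(\frac{h}{\phi}\right)^{\kappa} K_\kappa(h/\phi)}
#' with \eqn{\rho(0) = 1} (the continuity limit). \eqn{K_\kappa} is the
#' modified Bessel function of the second kind. For \eqn{\kappa = 0.5} this
#' reduces to \eqn{\exp(-h/\phi)}; for \eqn{\kappa = 1.5} to
#' \eqn{(1 + h/\phi)\exp(-h/\phi)}.
#'
#' @param h Distance(s), km, >= 0. Vectorized.
#' @param params A [matern_params()] object.
#' @return Correlation values in (0, 1]; strictly decreasing in `h`.
#'   Distances below 1e-12 km are treated as zero.
#' @examples
#' matern_correlation(15.9, matern_params(0.5, 15.9))  # exp(-1)
#' @export
matern_correlation <- function(h, params) {
  stopifnot(inherits(params, "matern_params"))
  .check_num(h, "h", lower = 0, allow_vec = TRUE)
  u <- h / params$phi
  k <- params$kappa
  out <- rep(1, length(h))
  pos <- u > 1e-12 / params$phi
  if (any(pos)) {
    up <- u[pos]
    out[pos] <- (2^(1 - k) / gamma(k)) * up^k * besselK(up, k)
  }
  # guard against floating overflow/underflow artefacts at extreme lags
  pmin(pmax(out, 0), 1)
}

#' Variogram of the nested spatial model
#'
#' Semivariance of plot-level responses at lag `h`:
#' \deqn{\gamma(h) = \varsigma^2_{res} + \varsigma^2_{farm} +
#'   \varsigma^2_{site}\{1 - \rho(h)\}, \quad h > 0,}
#' with \eqn{\gamma(0) = 0} by the variogram convention. The residual and
#' farm variances form the nugget; the limit at large `h` is the total sill.
#'
#' @param h Distance(s), km, >= 0. Vectorized.
#' @param vc A [variance_components()] object.
#' @return Semivariance, response units squared.
#' @export
variogram <- function(h, vc) {
  stopifnot(inherits(vc, "variance_components"))
  .check_num(h, "h", lower = 0, allow_vec = TRUE)
  rho <- matern_correlation(h, vc$matern)
  out <- vc$sigma2_res + vc$sigma2_farm + vc$sigma2_site * (1 - rho)
  out[h == 0] <- 0
  out
}

#' Covariance between two plots under the nested model
#'
#' \deqn{\mathrm{cov} = \varsigma^2_{site}\,\rho(h) +
#'   \varsigma^2_{farm}\,[same\ farm] + \varsigma^2_{res}\,[same\ plot].}
#' Complementary to the variogram: for distinct plots on distinct farms,
#' `variogram(h, vc) + plot_covariance(h, ...)` equals the total sill.
#'
#' @param h Between-site distance(s), km. Within-site farm separations
#'   (a few hundred metres) are negligible at the site-component scale
#'   (effective ranges tens of km); pass the exact distance or 0 as desired.
#' @param same_farm,same_plot Logical flags (vectorized); `same_plot = TRUE`
#'   requires `same_farm = TRUE`.
#' @param vc A [variance_components()] object.
#' @return Covariance, response units squared.
#' @export
plot_covariance <- function(h, same_farm, same_plot, vc) {
  stopifnot(inherits(vc, "variance_components"))
  .check_num(h, "h", lower = 0, allow_vec = TRUE)
  n <- max(length(h), length(same_farm), length(same_plot))
  same_farm <- rep_len(as.logical(same_farm), n)
  same_plot <- rep_len(as.logical(same_plot), n)
  h <- rep_len(h, n)
  if (any(same_plot & !same_farm))
    .stopf("`same_plot = TRUE` requires `same_farm = TRUE`")
  vc$sigma2_site * matern_correlation(h, vc$matern) +
    vc$sigma2_farm * same_farm + vc$sigma2_res * same_plot
}

#' Effective (practical) range of the Matern correlation
#'
#' The distance at which the correlation decays to a small conventional
#' threshold, 0.05 by default (the practical-range convention; for
#' \eqn{\kappa = 0.5} this is \eqn{-\phi \log 0.05 \approx 3\phi}).
#' Solved by monotone bracketing and bisection.
#'
#' @param params A [matern_params()] object.
#' @param threshold Correlation level defining the range (default 0.05).
#' @param tol Absolute tolerance on the returned distance, km
#'   (default 1e-3 km, i.e. 1 m).
#' @return Distance in km.
#' @examples
#' effective_range(matern_params(0.5, 15.9))  # -15.9 * log(0.05)
#' @export
effective_range <- function(params, threshold = 0.05, tol = 1e-3) {
  stopifnot(inherits(params, "matern_params"))
  .check_num(threshold, "threshold")
  if (threshold <= 0 || threshold >= 1) .stopf("`threshold` must be in (0, 1)")
  f <- function(h) matern_correlation(h, params) - threshold
  upper <- params$phi
  while (f(upper) > 0) upper <- upper * 2
  uniroot(f, lower = 0, upper = upper, tol = tol)$root
}

#' Variance estimates from the two information sources
#'
#' Holds the variance components estimated from a pilot on-farm experiment
#' (residual, farm, site) and from a regional survey's geostatistical model
#' (nugget, partial sill, Matern parameters), prior to combination.
#'
#' @param exp_res,exp_farm,exp_site Experimental variance components, >= 0.
#' @param svy_nugget Survey model uncorrelated variance \eqn{\sigma^2_0}.
#' @param svy_partial_sill Survey model correlated variance \eqn{\sigma^2_1}.
#' @param svy_matern [matern_params()] of the survey model.
#' @return An object of class `source_estimates`.
#' @export
source_estimates <- function(exp_res, exp_farm, exp_site,
                             svy_nugget, svy_partial_sill, svy_matern) {
  for (nm in c("exp_res", "exp_farm", "exp_site", "svy_nugget",
               "svy_partial_sill"))
    .check_num(get(nm), nm, lower = 0)
  if (!inherits(svy_matern, "matern_params"))
    .stopf("`svy_matern` must be matern_params")
  structure(list(exp_res = exp_res, exp_farm = exp_farm, exp_site = exp_site,
                 svy_nugget = svy_nugget,
                 svy_partial_sill = svy_partial_sill,
                 svy_matern = svy_matern),
            class = "source_estimates")
}

#' Combine experiment- and survey-derived variance estimates
#'
#' The combination rule used to build the working variance model: the
#' residual variance is the larger (conservative) of the experimental
#' residual and the survey nugget, which estimate near-identical short-range
#' quantities; the between-site variance and its Matern parameters are taken
#' from the survey model's correlated component (the experimental between-site
#' estimate, from few sites, is ignored); the between-farm within-site
#' variance comes directly from the experiment, which is the only source
#' resolving that scale.
#'
#' @param src A [source_estimates()] object.
#' @param scale Analysis scale label to record, `"linear"` or `"log"`.
#' @param variable Optional variable label.
#' @return A [variance_components()] object.
#' @export
combine_variance_sources <- function(src, scale = c("linear", "log"),
                                     variable = NULL) {
  stopifnot(inherits(src, "source_estimates"))
  variance_components(
    sigma2_res  = max(src$exp_res, src$svy_nugget),
    sigma2_farm = src$exp_farm,
    sigma2_site = src$svy_partial_sill,
    matern      = src$svy_matern,
    scale       = match.arg(scale),
    variable    = variable)
}

#' Read or write a variance parameter table
#'
#' CSV layout: columns `variable, sigma2_res, sigma2_farm, sigma2_site,
#' phi, kappa, scale`, one row per response variable. `.json` paths are
#' read/written as JSON arrays of the same records. The table bundled with
#' the package (`default_variance_table()`) holds the four working parameter
#' sets (wheat/teff Zn on the measurement scale, wheat/teff Se on the natural
#' log scale).
#'
#' @param path File path (`.csv` or `.json`).
#' @return `read_variance_table()`: a data.frame;
#'   `default_variance_table()`: the bundled data.frame.
#' @export
read_variance_table <- function(path) {
  if (grepl("\\.json$", path, ignore.case = TRUE)) {
    tab <- as.data.frame(jsonlite::fromJSON(path))
  } else {
    tab <- read.csv(path, stringsAsFactors = FALSE)
  }
  need <- c("variable", "sigma2_res", "sigma2_farm", "sigma2_site",
            "phi", "kappa", "scale")
  if (!all(need %in% names(tab)))
    .stopf("variance table must have columns: %s", paste(need, collapse = ", "))
  tab[need]
}

#' @rdname read_variance_table
#' @param tab A data.frame in the variance-table layout.
#' @export
write_variance_table <- function(tab, path) {
  if (grepl("\\.json$", path, ignore.case = TRUE)) {
    jsonlite::write_json(tab, path, dataframe = "rows", digits = NA)
  } else {
    write.csv(tab, path, row.names = FALSE, quote = FALSE)
  }
  invisible(path)
}

#' @rdname read_variance_table
#' @export
default_variance_table <- function() {
  read_variance_table(system.file("extdata", "variance_parameters.csv",
                                  package = "onfarmdesign", mustWork = TRUE))
}

#' Extract one variable's components from a variance table
#'
#' @param variable Variable name matching the table's `variable` column.
#' @param tab Variance table data.frame; defaults to the bundled table.
#' @return A [variance_components()] object.
#' @examples
#' vc_for("teff_zn")
#' @export
vc_for <- function(variable, tab = default_variance_table()) {
  i <- match(variable, tab$variable)
  if (is.na(i)) .stopf("variable '%s' not in table (%s)", variable,
                       paste(tab$variable, collapse = ", "))
  variance_components(tab$sigma2_res[i], tab$sigma2_farm[i], tab$sigma2_site[i],
                      kappa = tab$kappa[i], phi = tab$phi[i],
                      scale = tab$scale[i], variable = tab$variable[i])
}
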
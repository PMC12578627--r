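test_that("Matern correlation matches its closed forms and limits", {
  # kappa = 0.5 is exponential
  p <- matern_params(0.5, 15.9)
  expect_equal(matern_correlation(15.9, p), exp(-1), tolerance = 1e-12)
  expect_equal(matern_correlation(0, p), 1)
  # kappa = 1.5 closed form (1 + u) exp(-u), checked over a distance grid
  p15 <- matern_params(1.5, 10)
  h <- c(0.1, 1, 5, 10, 25, 80)
  u <- h / 10
  expect_equal(matern_correlation(h, p15), (1 + u) * exp(-u),
               tolerance = 1e-10)
  expect_equal(matern_correlation(10, p15), 2 * exp(-1), tolerance = 1e-10)
})

test_that("Matern correlation is continuous at 0, strictly decreasing, vanishing", {
  h <- c(1e-9, 1e-6, 1e-3, seq(0.5, 500, by = 0.5))
  for (k in c(0.25, 0.5, 0.75, 1, 1.5, 2)) {
    p <- matern_params(k, 17)
    r <- matern_correlation(h, p)
    expect_equal(r[1], 1, tolerance = 1e-3)      # continuity at the origin
    expect_true(all(diff(r) < 0))                # strictly decreasing
    expect_lt(r[length(h)], 1e-6)                # vanishes at long range
    expect_true(all(r > 0 & r <= 1))
  }
  expect_error(matern_correlation(-1, p), "h")
  expect_error(matern_correlation(NaN, p), "h")
})

test_that("variogram obeys the nugget/sill structure", {
  expect_equal(variogram(0, vc_wheat_zn), 0)
  # sill limit is the Table column sum
  expect_equal(total_sill(vc_wheat_zn), 17.5 + 4.6 + 14.4)
  expect_equal(variogram(1e5, vc_wheat_zn), 36.5, tolerance = 1e-8)
  expect_true(all(diff(variogram(seq(0.01, 400, by = 0.5), vc_wheat_zn)) > 0))
  # no site component: pure nugget for any h > 0
  vc0 <- variance_components(3, 2, 0, kappa = 0.5, phi = 10)
  expect_equal(variogram(c(0.1, 1, 50), vc0), rep(5, 3))
  expect_error(variogram(-0.1, vc0), "h")
})

test_that("plot covariance complements the variogram and handles flags", {
  # same plot at zero lag: the total variance
  expect_equal(plot_covariance(0, TRUE, TRUE, vc_wheat_zn),
               total_sill(vc_wheat_zn))
  # different sites at long range: zero
  expect_equal(plot_covariance(1e5, FALSE, FALSE, vc_wheat_zn), 0,
               tolerance = 1e-8)
  # two farms at the same site (site-scale lag 0): the site variance + farm?
  # no -- different farms share only the site effect
  expect_equal(plot_covariance(0, FALSE, FALSE, vc_wheat_zn), 14.4)
  # complementarity: gamma(h) + cov(h) = sill for distinct-farm pairs, h > 0
  h <- c(0.5, 3, 20, 75, 300)
  expect_equal(variogram(h, vc_teff_zn) +
                 plot_covariance(h, FALSE, FALSE, vc_teff_zn),
               rep(total_sill(vc_teff_zn), length(h)), tolerance = 1e-10)
  expect_error(plot_covariance(0, FALSE, TRUE, vc_wheat_zn), "same_farm")
})

test_that("plot-covariance matrices over random designs are positive semidefinite", {
  set.seed(11)
  for (rep in 1:4) {
    vc <- list(vc_wheat_zn, vc_teff_zn, vc_wheat_se, vc_teff_se)[[rep]]
    n_sites <- sample(3:8, 1); farms <- sample(2:5, 1)
    d <- make_domain("rectangle", c(300, 300), n_cells = 400)
    des <- make_cluster_layout(d, n_sites, farms, seed = rep,
                               plots_per_treatment = sample(1:2, 1))
    p <- des$plots
    n <- nrow(p)
    expect_lte(n, 200)
    D <- as.matrix(dist(p[, c("x_km", "y_km")]))
    Fm <- outer(p$farm_id, p$farm_id, "==")
    Pm <- outer(p$plot_id, p$plot_id, "==")
    C <- matrix(plot_covariance(as.vector(D), as.vector(Fm), as.vector(Pm), vc),
                n, n)
    expect_equal(C, t(C))
    ev <- eigen(C, symmetric = TRUE, only.values = TRUE)$values
    expect_gt(min(ev), -1e-8 * total_sill(vc))
  }
})

test_that("effective range follows the practical-range convention", {
  # closed form at kappa = 0.5: -phi log(0.05)
  expect_equal(effective_range(matern_params(0.5, 15.9)),
               -15.9 * log(0.05), tolerance = 1e-3)
  expect_equal(effective_range(matern_params(0.5, 1)), -log(0.05),
               tolerance = 1e-3)
  # bisection agrees with direct evaluation at the root
  for (k in c(0.25, 0.75, 2)) {
    p <- matern_params(k, 20)
    h <- effective_range(p)
    expect_equal(matern_correlation(h, p), 0.05, tolerance = 1e-4)
  }
  # configurable threshold
  expect_equal(effective_range(matern_params(0.5, 10), threshold = exp(-1)),
               10, tolerance = 1e-3)
})

test_that("combining sources applies the conservative max / survey-sill rule", {
  m <- matern_params(0.75, 19.6)
  src <- source_estimates(exp_res = 17.0, exp_farm = 4.6, exp_site = 99,
                          svy_nugget = 17.5, svy_partial_sill = 14.4,
                          svy_matern = m)
  vc <- combine_variance_sources(src)
  expect_equal(vc$sigma2_res, 17.5)    # the larger of the two
  expect_equal(vc$sigma2_farm, 4.6)    # experimental estimate
  expect_equal(vc$sigma2_site, 14.4)   # survey partial sill; exp_site ignored
  expect_identical(vc$matern, m)
  # tie case
  src2 <- source_estimates(5, 1, 0, 5, 2, m)
  expect_equal(combine_variance_sources(src2)$sigma2_res, 5)
  # degenerate farm variance flows through
  src3 <- source_estimates(5, 0, 0, 4, 2, m)
  vc3 <- combine_variance_sources(src3)
  expect_equal(vc3$sigma2_farm, 0)
  expect_equal(variogram(1e4, vc3), 7, tolerance = 1e-6)
})

test_that("a parameter-table column round-trips through decomposed sources", {
  for (v in tab1$variable) {
    vc <- vc_for(v)
    # plausible sources: survey nugget equals the (conservative) residual,
    # experimental residual slightly smaller
    src <- source_estimates(exp_res = 0.97 * vc$sigma2_res,
                            exp_farm = vc$sigma2_farm, exp_site = 1,
                            svy_nugget = vc$sigma2_res,
                            svy_partial_sill = vc$sigma2_site,
                            svy_matern = vc$matern)
    back <- combine_variance_sources(src, scale = vc$scale, variable = v)
    expect_equal(back$sigma2_res, vc$sigma2_res)
    expect_equal(back$sigma2_farm, vc$sigma2_farm)
    expect_equal(back$sigma2_site, vc$sigma2_site)
    expect_equal(back$matern$phi, vc$matern$phi)
  }
})

test_that("variance tables round-trip through CSV and JSON", {
  for (ext in c(".csv", ".json")) {
    f <- tempfile(fileext = ext)
    write_variance_table(tab1, f)
    back <- read_variance_table(f)
    expect_equal(back$sigma2_res, tab1$sigma2_res)
    expect_equal(back$kappa, tab1$kappa)
    expect_equal(back$variable, tab1$variable)
  }
  expect_error(vc_for("maize_fe"), "not in table")
})
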
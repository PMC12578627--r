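vc_nugget <- variance_components(3, 2, 0, kappa = 0.5, phi = 10)

test_that("point-to-domain average semivariance has the right limits", {
  d <- square100
  # pure nugget: gamma-bar is the nugget (self-cell bias < one cell weight)
  gb <- gammabar_point_domain(c(50, 50), d, vc_nugget)
  expect_equal(gb, 5, tolerance = 2 / nrow(d$grid))
  # a point far beyond the effective range sees the total sill
  far <- gammabar_point_domain(c(5000, 5000), d, vc_wheat_zn)
  expect_equal(far, total_sill(vc_wheat_zn), tolerance = 1e-6)
  # grid-refinement convergence: halving the cell size moves the value <0.5%
  d2 <- make_domain("rectangle", c(100, 100), n_cells = 4 * nrow(d$grid))
  g1 <- gammabar_point_domain(c(30, 70), d, vc_wheat_zn)
  g2 <- gammabar_point_domain(c(30, 70), d2, vc_wheat_zn)
  expect_lt(abs(g1 - g2) / g2, 0.005)
})

test_that("domain-to-domain average semivariance matches Monte-Carlo integration", {
  d <- square100
  gbb <- gammabar_domain_domain(d, vc_wheat_zn)
  expect_lte(gbb, total_sill(vc_wheat_zn))
  expect_equal(gammabar_domain_domain(d, vc_nugget), 5,
               tolerance = 3 / nrow(d$grid))
  set.seed(99)
  n <- 1e6
  h <- sqrt((runif(n, 0, 100) - runif(n, 0, 100))^2 +
              (runif(n, 0, 100) - runif(n, 0, 100))^2)
  mc <- mean(variogram(h, vc_wheat_zn))
  expect_equal(gbb, mc, tolerance = 0.01)
})

test_that("regional mean variance obeys the pure-nugget closed form", {
  d <- square100
  set.seed(4)
  pts <- cbind(runif(10, 0, 100), runif(10, 0, 100))
  tol <- 5 * 3 / nrow(d$grid)   # discretization of the self-cell terms
  rv <- regional_mean_variance(pts, d, vc_nugget)
  expect_equal(rv$sigma2_m, 5 / 10, tolerance = tol)
  rv1 <- regional_mean_variance(pts[1, , drop = FALSE], d, vc_nugget)
  expect_equal(rv1$sigma2_m, 5, tolerance = tol)
  # invariance to point relabelling; non-negativity
  rv2 <- regional_mean_variance(pts[sample.int(10), ], d, vc_nugget)
  expect_equal(rv2$sigma2_m, rv$sigma2_m, tolerance = 1e-12)
  expect_gte(rv$sigma2_m, -1e-9)
  expect_warning(
    regional_mean_variance(rbind(pts, c(500, 500)), d, vc_nugget), "outside")
})

test_that("regional mean variance matches a random-field simulation oracle", {
  # empirical MSE of the sample mean against the true areal mean over
  # repeated realizations of the spatial model
  d <- make_domain("rectangle", c(400, 425), n_cells = 900)
  des <- make_cluster_layout(d, 10, 5, seed = 13)
  vc <- vc_wheat_zn
  pts <- as.matrix(des$farms[, c("x", "y")])
  pred <- regional_mean_variance(pts, d, vc)$sigma2_m
  all_xy <- rbind(pts, as.matrix(d$grid[, c("x", "y")]))
  D <- as.matrix(dist(all_xy))
  C <- vc$sigma2_site * matern_correlation(as.vector(D), vc$matern)
  dim(C) <- dim(D)
  L <- chol(C + diag(1e-8, nrow(C)))
  n <- nrow(pts); m <- nrow(d$grid)
  w <- d$grid$w / sum(d$grid$w)
  nugget <- vc$sigma2_res + vc$sigma2_farm
  set.seed(71)
  Z <- crossprod(L, matrix(rnorm(nrow(C) * 2000), nrow(C)))
  samp_mean <- colMeans(Z[1:n, , drop = FALSE] +
                          matrix(rnorm(n * 2000, 0, sqrt(nugget)), n))
  true_mean <- as.vector(w %*% Z[(n + 1):(n + m), , drop = FALSE])
  mse <- mean((samp_mean - true_mean)^2)
  expect_equal(mse, pred, tolerance = 0.05)
})

test_that("regional precision gains from more clusters show diminishing returns", {
  d <- make_domain("rectangle", c(400, 425), n_cells = 900)
  s2 <- vapply(c(5, 10, 25), function(nc) {
    des <- make_cluster_layout(d, nc, 50 / nc, seed = 20)
    regional_mean_variance(des$farms[, c("x", "y")], d, vc_teff_zn)$sigma2_m
  }, numeric(1))
  expect_true(all(diff(s2) < 0))             # 5 -> 10 -> 25 improves
  expect_gt(s2[1] - s2[2], s2[2] - s2[3])    # larger drop from 5 -> 10
})

test_that("ordinary kriging solves the system it claims to solve", {
  d <- square100
  set.seed(33)
  sites <- cbind(runif(20, 0, 100), runif(20, 0, 100))
  vc <- vc_teff_zn
  ok <- block_kriging_pev(c(47, 53), 0, sites, vc)
  expect_equal(sum(ok$lambda), 1, tolerance = 1e-10)
  # dual covariance-form solution: C lambda + psi = c0, sum lambda = 1
  sill <- total_sill(vc)
  D <- as.matrix(dist(sites))
  G <- matrix(variogram(as.vector(D), vc), 20, 20); diag(G) <- 0
  C <- sill - G
  c0 <- sill - variogram(sqrt((sites[, 1] - 47)^2 + (sites[, 2] - 53)^2), vc)
  A <- rbind(cbind(C, 1), c(rep(1, 20), 0))
  sol <- solve(A, c(c0, 1))
  lam <- sol[1:20]; mu <- sol[21]
  pev_cov <- sill - sum(lam * c0) - mu
  expect_equal(ok$lambda, lam, tolerance = 1e-8)
  expect_equal(ok$pev, pev_cov, tolerance = 1e-8)
})

test_that("kriging respects symmetry and exactness", {
  vc <- vc_teff_zn
  # two sites symmetric about the target share the weight equally
  ok <- block_kriging_pev(c(50, 50), 0, rbind(c(40, 50), c(60, 50)), vc)
  expect_equal(ok$lambda, c(0.5, 0.5), tolerance = 1e-10)
  # punctual prediction at a site with no nugget is exact (PEV 0)
  vc0 <- variance_components(0, 0, 10, kappa = 1, phi = 15)
  sites <- rbind(c(10, 10), c(30, 40), c(70, 20))
  ok0 <- block_kriging_pev(c(30, 40), 0, sites, vc0)
  expect_equal(ok0$pev, 0, tolerance = 1e-8)
  # duplicated sites are deduplicated with a warning
  expect_warning(block_kriging_pev(c(50, 50), 0, rbind(sites, c(10, 10)), vc),
                 "duplicated")
})

test_that("pure-nugget punctual kriging variance is flat at c0 (1 + 1/n)", {
  d <- square100
  for (n in c(10, 25)) {
    set.seed(n)
    sites <- cbind(runif(n, 0, 100), runif(n, 0, 100))
    ok <- block_kriging_pev(c(50, 50), 0, sites, vc_nugget)
    expect_equal(ok$pev, 5 * (1 + 1 / n), tolerance = 1e-8)
  }
})

test_that("log-scale variables are rejected by the spatial quality measures", {
  d <- square100
  expect_error(regional_mean_variance(cbind(50, 50), d, vc_wheat_se),
               "log scale")
  expect_error(block_kriging_pev(c(50, 50), 0.2,
                                 rbind(c(10, 10), c(90, 90)), vc_teff_se),
               "log scale")
  # explicit override runs
  rv <- regional_mean_variance(cbind(50, 50), d, vc_wheat_se,
                               allow_log = TRUE)
  expect_true(is.finite(rv$sigma2_m))
})

test_that("block averaging removes part of the nugget", {
  d <- square100
  set.seed(12)
  sites <- cbind(runif(30, 0, 100), runif(30, 0, 100))
  p0 <- block_kriging_pev(c(50, 50), 0, sites, vc_wheat_zn)$pev
  pb <- block_kriging_pev(c(50, 50), 0.2, sites, vc_wheat_zn)$pev
  expect_lt(pb, p0)
})
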
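# Estimation variance of the regional treatment mean and ordinary
# block-kriging prediction-error variance. These quality measures are only
# meaningful on the measurement scale, so log-scale variance models are
# rejected unless explicitly overridden.

.check_linear_scale <- function(vc, allow_log) {
  if (identical(vc$scale, "log") && !isTRUE(allow_log))
    .stopf(paste0("this quality measure is defined on the measurement scale; ",
                  "the variance model is on the log scale ",
                  "(set allow_log = TRUE to override)"))
  invisible(vc)
}

#' Average semivariance between a point and the domain
#'
#' The area-weighted average \eqn{\bar\gamma(x, B)} of the variogram between
#' location `x` and all locations of the domain, evaluated over the domain's
#' grid cells. Converges on grid refinement (the vanishing self-cell
#' contribution when `x` lies on a grid point biases the result low by at
#' most one cell weight times the sill).
#'
#' @param x Numeric length-2 location (km), or a 2-column matrix of
#'   locations.
#' @param domain A [make_domain()] object.
#' @param vc A [variance_components()] object.
#' @param allow_log Permit a log-scale variance model (default FALSE).
#' @return Average semivariance (vector if `x` is a matrix).
#' @export
gammabar_point_domain <- function(x, domain, vc, allow_log = FALSE) {
  stopifnot(inherits(domain, "domain"))
  .check_linear_scale(vc, allow_log)
  if (is.null(dim(x))) x <- matrix(x, ncol = 2)
  g <- domain$grid
  if (nrow(g) == 0) .stopf("domain grid is empty")
  W <- sum(g$w)
  vapply(seq_len(nrow(x)), function(i) {
    d <- sqrt((g$x - x[i, 1])^2 + (g$y - x[i, 2])^2)
    sum(g$w * variogram(d, vc)) / W
  }, numeric(1))
}

#' Average semivariance within the domain
#'
#' The double area-weighted average \eqn{\bar\gamma(B, B)} of the variogram
#' over all pairs of domain locations; always at most the total sill.
#'
#' @inheritParams gammabar_point_domain
#' @return Average semivariance (scalar).
#' @export
gammabar_domain_domain <- function(domain, vc, allow_log = FALSE) {
  stopifnot(inherits(domain, "domain"))
  .check_linear_scale(vc, allow_log)
  g <- domain$grid
  W <- sum(g$w)
  acc <- 0
  chunk <- max(1L, floor(4e6 / nrow(g)))
  for (i0 in seq(1L, nrow(g), by = chunk)) {
    i1 <- min(i0 + chunk - 1L, nrow(g))
    dx <- outer(g$x[i0:i1], g$x, "-")
    dy <- outer(g$y[i0:i1], g$y, "-")
    gv <- variogram(sqrt(dx * dx + dy * dy), vc)
    dim(gv) <- dim(dx)
    acc <- acc + sum((g$w[i0:i1] * gv) %*% g$w)
  }
  acc / W^2
}

#' Estimation variance of the regional (domain) mean
#'
#' The error variance of the sample mean of `n` observation locations as an
#' estimator of the areal mean over the domain:
#' \deqn{\sigma^2_m = \frac{2}{n}\sum_i \bar\gamma(x_i, B)
#'   - \frac{1}{n^2}\sum_i\sum_j \gamma(x_i - x_j) - \bar\gamma(B, B),}
#' with \eqn{\gamma(x_i - x_i) = 0} on the diagonal. In the pure-nugget
#' limit this reduces to (nugget)/n.
#'
#' @param points Matrix or data.frame of observation locations (farm
#'   locations; columns x, y in km).
#' @param domain A [make_domain()] object.
#' @param vc A [variance_components()] object.
#' @param allow_log Permit a log-scale variance model (default FALSE).
#' @return An object of class `regional_variance_result`: list with
#'   `sigma2_m`, `n_points`, `integration_resolution`.
#' @export
regional_mean_variance <- function(points, domain, vc, allow_log = FALSE) {
  stopifnot(inherits(domain, "domain"))
  .check_linear_scale(vc, allow_log)
  pts <- as.matrix(as.data.frame(points)[, 1:2])
  n <- nrow(pts)
  if (n < 1) .stopf("need at least one point")
  inside <- if (domain$kind == "rectangle") {
    xr <- range(domain$boundary[, 1]); yr <- range(domain$boundary[, 2])
    pts[, 1] >= xr[1] & pts[, 1] <= xr[2] & pts[, 2] >= yr[1] & pts[, 2] <= yr[2]
  } else .points_in_polygon(domain$boundary, pts)
  if (!all(inside))
    warning(sum(!inside), " point(s) fall outside the domain; proceeding")
  gbar <- gammabar_point_domain(pts, domain, vc, allow_log = allow_log)
  D <- as.matrix(dist(pts))
  G <- matrix(variogram(as.vector(D), vc), n, n)
  diag(G) <- 0
  s2 <- 2 / n * sum(gbar) - sum(G) / n^2 -
    gammabar_domain_domain(domain, vc, allow_log = allow_log)
  structure(list(sigma2_m = s2, n_points = n,
                 integration_resolution = nrow(domain$grid)),
            class = "regional_variance_result")
}

#' @export
print.regional_variance_result <- function(x, ...) {
  cat(sprintf("Estimation variance of the regional mean: %.6g (n = %d points, %d cells)\n",
              x$sigma2_m, x$n_points, x$integration_resolution))
  invisible(x)
}

# offsets of the block discretization cells relative to the block centre
.block_offsets <- function(block_side, block_res = 8L) {
  if (block_side <= 0) return(matrix(0, 1, 2))
  s <- ((seq_len(block_res) - 0.5) / block_res - 0.5) * block_side
  as.matrix(expand.grid(ox = s, oy = s))
}

# within-block average semivariance (diagonal gamma(0)=0, per convention)
.gammabar_block_block <- function(block_side, vc, block_res = 8L) {
  if (block_side <= 0) return(0)
  off <- .block_offsets(block_side, block_res)
  D <- as.matrix(dist(off))
  mean(variogram(as.vector(D), vc))
}

# Ordinary block-kriging PEV for many targets sharing one site set:
# one factorization of the bordered semivariance system, one solve for all
# right-hand sides.
.ok_pev_batch <- function(targets, sites, vc, block_side, block_res = 8L) {
  st <- as.matrix(as.data.frame(sites)[, 1:2])
  tg <- as.matrix(as.data.frame(targets)[, 1:2])
  # deduplicate coincident sites, which make the system singular
  dup <- duplicated(round(st, 9))
  if (any(dup)) {
    warning(sum(dup), " duplicated site location(s) removed for kriging")
    st <- st[!dup, , drop = FALSE]
  }
  n <- nrow(st)
  if (n < 2) .stopf("need at least 2 distinct sites")
  D <- as.matrix(dist(st))
  G <- matrix(variogram(as.vector(D), vc), n, n)
  diag(G) <- 0
  A <- rbind(cbind(G, 1), c(rep(1, n), 0))
  off <- .block_offsets(block_side, block_res)
  gbb <- .gammabar_block_block(block_side, vc, block_res)
  m <- nrow(tg)
  # point-to-block semivariances, accumulated over block cells
  B <- matrix(0, n, m)
  for (k in seq_len(nrow(off))) {
    dx <- outer(st[, 1], tg[, 1] + off[k, 1], "-")
    dy <- outer(st[, 2], tg[, 2] + off[k, 2], "-")
    B <- B + matrix(variogram(as.vector(sqrt(dx^2 + dy^2)), vc), n, m)
  }
  B <- B / nrow(off)
  sol <- solve(A, rbind(B, rep(1, m)))
  lambda <- sol[seq_len(n), , drop = FALSE]
  psi <- sol[n + 1, ]
  pev <- colSums(lambda * B) + psi - gbb
  list(pev = pev, lambda = lambda, psi = psi, gbb = gbb,
       residual = max(abs(colSums(lambda) - 1)))
}

#' Ordinary block-kriging prediction error variance at a target
#'
#' Solves the ordinary-kriging system in semivariance form, with the
#' unbiasedness constraint (weights summing to 1) enforced by a Lagrange
#' multiplier \eqn{\psi}:
#' \deqn{PEV = \sum_i \lambda_i \bar\gamma(x_i, B_{blk}) + \psi -
#'   \bar\gamma(B_{blk}, B_{blk}).}
#' The prediction support is a square block of side `block_side` centred on
#' the target (8 x 8 discretization; `block_side = 0` gives punctual
#' kriging). Block averaging removes the within-block part of the nugget,
#' so farm-scale block predictions are more precise than punctual ones.
#'
#' @param target Numeric length-2 location (km).
#' @param block_side Side of the square prediction block, km (>= 0).
#' @param sites Matrix or data.frame of observation site locations.
#' @param vc A [variance_components()] object.
#' @param block_res Block discretization per side (default 8).
#' @param allow_log Permit a log-scale variance model (default FALSE).
#' @return List with `pev`, `lambda` (kriging weights), `psi` (Lagrange
#'   multiplier).
#' @export
block_kriging_pev <- function(target, block_side, sites, vc,
                              block_res = 8L, allow_log = FALSE) {
  .check_linear_scale(vc, allow_log)
  .check_num(block_side, "block_side", lower = 0)
  res <- .ok_pev_batch(matrix(target, ncol = 2), sites, vc, block_side,
                       block_res)
  list(pev = unname(res$pev[1]), lambda = unname(res$lambda[, 1]),
       psi = unname(res$psi[1]))
}

#' Kriging prediction-error-variance summary over a domain
#'
#' For each candidate number of parent sites: select sites by spatially
#' balanced sampling, compute the farm-scale block-kriging PEV at `n_eval`
#' spread evaluation locations, and summarize by median and quartiles.
#'
#' @param site_counts Integer vector of site numbers.
#' @param domain A [make_domain()] object.
#' @param vc A [variance_components()] object.
#' @param n_eval Number of evaluation locations (default 5000).
#' @param block_side Prediction block side, km (default 0.2, a farm-scale
#'   support).
#' @param seed Integer seed.
#' @param frame_factor Candidates per site in the selection frame.
#' @param allow_log Permit a log-scale variance model (default FALSE).
#' @return An object of class `pev_summary`: data.frame with columns
#'   `n_sites`, `q1`, `median`, `q3`, `max_weight_residual` (unbiasedness
#'   residual, should be ~1e-10).
#' @export
pev_summary <- function(site_counts, domain, vc, n_eval = 5000L,
                        block_side = 0.2, seed = 1L, frame_factor = 20L,
                        allow_log = FALSE) {
  stopifnot(inherits(domain, "domain"))
  .check_linear_scale(vc, allow_log)
  ep <- spread_points(domain, n_eval, seed = seed)
  frame <- make_candidate_frame(domain, frame_factor * max(site_counts),
                                seed = seed + 101L)
  rows <- lapply(seq_along(site_counts), function(k) {
    ns <- site_counts[k]
    ids <- balanced_sample(frame, ns, seed = seed + 200L + k)
    sites <- frame[match(ids, frame$id), c("x", "y")]
    res <- .ok_pev_batch(ep, sites, vc, block_side)
    q <- quantile(res$pev, probs = c(0.25, 0.5, 0.75), names = FALSE)
    data.frame(n_sites = ns, q1 = q[1], median = q[2], q3 = q[3],
               max_weight_residual = res$residual)
  })
  out <- do.call(rbind, rows)
  attr(out, "seed") <- seed
  attr(out, "block_side") <- block_side
  class(out) <- c("pev_summary", "data.frame")
  out
}
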
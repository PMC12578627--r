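# Spatially balanced sampling (local pivotal method) and
# distance-to-nearest-site coverage analysis.

#' Spatially balanced sample by the local pivotal method
#'
#' Selects `n` of the candidate locations with equal marginal inclusion
#' probability `n/N` and spatial spread, using the local pivotal method
#' variant 1 (LPM1): inclusion probability is repeatedly transferred at
#' random within mutually-nearest pairs of unresolved units until every
#' probability resolves to 0 or 1. Nearby units thereby "compete", which
#' pushes selected units apart and yields a spatially well-spread sample.
#'
#' @param frame A [make_candidate_frame()] object, or any data.frame with
#'   columns `id`, `x`, `y`.
#' @param n Sample size, 1 <= n <= nrow(frame).
#' @param seed Integer seed.
#' @return Integer vector of `n` selected ids.
#' @examples
#' d <- make_domain("rectangle", c(100, 100))
#' fr <- make_candidate_frame(d, 200, seed = 3)
#' ids <- balanced_sample(fr, 20, seed = 4)
#' @export
balanced_sample <- function(frame, n, seed = 1L) {
  if (!all(c("x", "y") %in% names(frame))) .stopf("`frame` needs x, y columns")
  N <- nrow(frame)
  if (n < 1 || n > N) .stopf("`n` must be in [1, %d]", N)
  if (n == N) return(frame$id)
  set.seed(seed)
  idx <- .lpm1_cpp(frame$x, frame$y, as.integer(n))
  frame$id[idx]
}

#' Distance from evaluation points to the nearest site
#'
#' @param eval_points Matrix or data.frame of evaluation locations
#'   (columns x, y in km).
#' @param sites Matrix or data.frame of site locations (columns x, y).
#' @return Numeric vector: the Euclidean distance from each evaluation
#'   point to its nearest site (zero iff the point coincides with a site).
#' @export
nearest_site_distances <- function(eval_points, sites) {
  ep <- as.matrix(as.data.frame(eval_points)[, 1:2])
  st <- as.matrix(as.data.frame(sites)[, 1:2])
  if (nrow(st) < 1) .stopf("need at least one site")
  out <- numeric(nrow(ep))
  # chunked vectorized scan keeps memory bounded for large inputs
  chunk <- max(1L, floor(2e6 / nrow(st)))
  for (i0 in seq(1L, nrow(ep), by = chunk)) {
    i1 <- min(i0 + chunk - 1L, nrow(ep))
    dx <- outer(ep[i0:i1, 1], st[, 1], "-")
    dy <- outer(ep[i0:i1, 2], st[, 2], "-")
    d2 <- dx * dx + dy * dy
    out[i0:i1] <- sqrt(do.call(pmin, as.data.frame(d2)))
  }
  out
}

#' Spread evaluation points across a domain
#'
#' Draws a dense uniform candidate frame and thins it to `n` locations by
#' the local pivotal method, mirroring how survey evaluation locations are
#' selected (spatially balanced, with spread).
#'
#' @param domain A [make_domain()] object.
#' @param n Number of evaluation points.
#' @param seed Integer seed.
#' @param factor Frame density multiplier (candidates per retained point).
#' @return data.frame with columns `x`, `y`.
#' @export
spread_points <- function(domain, n, seed = 1L, factor = 4L) {
  frame <- make_candidate_frame(domain, as.integer(n * factor), seed = seed)
  ids <- balanced_sample(frame, n, seed = seed + 1L)
  frame[match(ids, frame$id), c("x", "y")]
}

#' Distance-to-nearest-site coverage curve
#'
#' For each candidate number of parent sites: select that many sites by
#' spatially balanced sampling over a dense frame, compute the distance from
#' each of `n_eval` spread evaluation locations to its nearest site, and
#' summarize by the first decile, quartiles, median and ninth decile. The
#' evaluation locations are drawn independently of the site sample.
#'
#' @param domain A [make_domain()] object.
#' @param site_counts Integer vector of site numbers to evaluate.
#' @param n_eval Number of evaluation locations (default 5000).
#' @param seed Integer seed.
#' @param frame_factor Candidates per site in the selection frame
#'   (default 20).
#' @return An object of class `coverage_curve`: data.frame with columns
#'   `n_sites`, `d10`, `q1`, `median`, `q3`, `d90` (km).
#' @export
coverage_curve <- function(domain, site_counts, n_eval = 5000L, seed = 1L,
                           frame_factor = 20L) {
  stopifnot(inherits(domain, "domain"))
  if (length(site_counts) < 1) .stopf("`site_counts` must be non-empty")
  ep <- spread_points(domain, n_eval, seed = seed)
  frame <- make_candidate_frame(domain, frame_factor * max(site_counts),
                                seed = seed + 101L)
  rows <- lapply(seq_along(site_counts), function(k) {
    ns <- site_counts[k]
    ids <- balanced_sample(frame, ns, seed = seed + 200L + k)
    sites <- frame[match(ids, frame$id), c("x", "y")]
    d <- nearest_site_distances(ep, sites)
    q <- quantile(d, probs = c(0.1, 0.25, 0.5, 0.75, 0.9), names = FALSE)
    data.frame(n_sites = ns, d10 = q[1], q1 = q[2], median = q[3],
               q3 = q[4], d90 = q[5])
  })
  out <- do.call(rbind, rows)
  attr(out, "seed") <- seed
  attr(out, "n_eval") <- n_eval
  class(out) <- c("coverage_curve", "data.frame")
  out
}
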
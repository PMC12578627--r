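# Synthetic study domains: bounded planar polygons in km coordinates with a
# regular grid discretization (cell centres + clipped cell weights) used for
# the variogram integrals and as a dense frame for sampling.

.shoelace_area <- function(poly) {
  x <- poly[, 1]; y <- poly[, 2]
  n <- nrow(poly)
  j <- c(2:n, 1)
  abs(sum(x * y[j] - x[j] * y)) / 2
}

.points_in_polygon <- function(poly, pts) {
  # mgcv::in.out expects a closed loop
  bnd <- rbind(poly, poly[1, , drop = FALSE])
  mgcv::in.out(as.matrix(bnd), as.matrix(pts))
}

#' Generate a synthetic study domain
#'
#' A bounded planar region in km coordinates standing in for a regional
#' survey frame. `"rectangle"` gives an axis-aligned rectangle (default
#' 400 x 425 km, the same order of size as the Amhara region, so coverage
#' and precision curves are on a comparable scale). `"blob"` gives a random
#' simple polygon with a smooth radial boundary, for checking that nothing
#' depends on rectangularity.
#'
#' The discretization stores cell centres and per-cell weights; cells
#' straddling the boundary get fractional weights from 4x4 subsampling, so
#' the weights sum to the polygon area to well within 1%.
#'
#' @param kind `"rectangle"` or `"blob"`.
#' @param size Side lengths in km: length 2 (width, height) for a rectangle,
#'   length 1 (approximate diameter) for a blob.
#' @param seed Integer seed (used by `"blob"`; a rectangle is deterministic).
#' @param n_cells Target number of interior grid cells (default 3000,
#'   >= 2000 recommended for stable integrals).
#' @return An object of class `domain`: list with `boundary` (polygon
#'   vertex matrix), `area` (km^2), `grid` (data.frame `x`, `y`, `w` with
#'   weights in km^2), `kind`.
#' @examples
#' d <- make_domain("rectangle", size = c(100, 100))
#' d$area
#' @export
make_domain <- function(kind = c("rectangle", "blob"), size = c(400, 425),
                        seed = 1L, n_cells = 3000) {
  kind <- match.arg(kind)
  .check_num(size, "size", allow_vec = TRUE)
  if (any(size <= 0)) .stopf("`size` must be positive")
  if (n_cells < 100) .stopf("`n_cells` too small for stable integration")
  if (kind == "rectangle") {
    if (length(size) == 1L) size <- c(size, size)
    w <- size[1]; h <- size[2]
    boundary <- cbind(x = c(0, w, w, 0), y = c(0, 0, h, h))
    area <- w * h
    side <- sqrt(area / n_cells)
    nx <- max(2L, round(w / side)); ny <- max(2L, round(h / side))
    grid <- expand.grid(x = (seq_len(nx) - 0.5) * w / nx,
                        y = (seq_len(ny) - 0.5) * h / ny)
    grid$w <- area / (nx * ny)
  } else {
    r0 <- size[1] / 2
    set.seed(seed)
    kvec <- 2:5
    amp <- runif(length(kvec), 0, 0.15 / sqrt(kvec))
    pha <- runif(length(kvec), 0, 2 * pi)
    th <- seq(0, 2 * pi, length.out = 181L)[-181L]
    r <- r0 * (1 + colSums(amp * cos(outer(kvec, th) + pha)))
    boundary <- cbind(x = r0 + r * cos(th), y = r0 + r * sin(th))
    area <- .shoelace_area(boundary)
    side <- sqrt(area / n_cells)
    xr <- range(boundary[, 1]); yr <- range(boundary[, 2])
    nx <- ceiling(diff(xr) / side); ny <- ceiling(diff(yr) / side)
    grid <- expand.grid(x = xr[1] + (seq_len(nx) - 0.5) * diff(xr) / nx,
                        y = yr[1] + (seq_len(ny) - 0.5) * diff(yr) / ny)
    dx <- diff(xr) / nx; dy <- diff(yr) / ny
    # fractional weights for boundary cells by 4x4 subsampling
    off <- expand.grid(ox = ((1:4) - 2.5) / 4 * dx, oy = ((1:4) - 2.5) / 4 * dy)
    frac <- numeric(nrow(grid))
    for (i in seq_len(nrow(off))) {
      frac <- frac + .points_in_polygon(
        boundary, cbind(grid$x + off$ox[i], grid$y + off$oy[i]))
    }
    grid$w <- dx * dy * frac / nrow(off)
    grid <- grid[grid$w > 0, , drop = FALSE]
    rownames(grid) <- NULL
  }
  structure(list(boundary = boundary, area = area, grid = grid, kind = kind),
            class = "domain")
}

#' @export
print.domain <- function(x, ...) {
  cat(sprintf("Synthetic domain (%s): area %.0f km^2, %d grid cells (weight sum %.0f km^2)\n",
              x$kind, x$area, nrow(x$grid), sum(x$grid$w)))
  invisible(x)
}

#' Uniform-random candidate frame within a domain
#'
#' Candidate locations from which sites are selected by spatially balanced
#' sampling, standing in for a survey sampling frame.
#'
#' @param domain A [make_domain()] object.
#' @param n Number of candidate points, >= 1.
#' @param seed Integer seed.
#' @return An object of class `candidate_frame`: data.frame with `id`, `x`,
#'   `y` (km).
#' @export
make_candidate_frame <- function(domain, n, seed = 1L) {
  stopifnot(inherits(domain, "domain"))
  if (!is.numeric(n) || n < 1) .stopf("`n` must be >= 1")
  n <- as.integer(n)
  set.seed(seed)
  xr <- range(domain$boundary[, 1]); yr <- range(domain$boundary[, 2])
  pts <- matrix(numeric(0), ncol = 2)
  while (nrow(pts) < n) {
    m <- max(2L * (n - nrow(pts)), 100L)
    cand <- cbind(runif(m, xr[1], xr[2]), runif(m, yr[1], yr[2]))
    keep <- if (domain$kind == "rectangle") rep(TRUE, m) else
      .points_in_polygon(domain$boundary, cand)
    pts <- rbind(pts, cand[keep, , drop = FALSE])
  }
  pts <- pts[seq_len(n), , drop = FALSE]
  structure(data.frame(id = seq_len(n), x = pts[, 1], y = pts[, 2]),
            class = c("candidate_frame", "data.frame"))
}

#' Cluster-of-farms trial layout
#'
#' Place `n_sites` cluster (site) locations by spatially balanced sampling
#' over a dense candidate frame, scatter `farms_per_site` farms uniformly
#' within a disc of radius `spread_scale` around each site, and give every
#' farm one plot per treatment (complete blocks). The default disc radius of
#' 0.55 km makes the within-site pairwise farm distances match the pilot
#' statistics (median about 0.5 km).
#'
#' @param domain A [make_domain()] object.
#' @param n_sites Number of cluster sites, >= 1.
#' @param farms_per_site Farms per site, >= 2 (a within-farm treatment
#'   contrast needs at least two farms for inference).
#' @param spread_scale Disc radius for farm scatter, km (>= 0; 0 collapses
#'   all farms onto the site).
#' @param seed Integer seed.
#' @param treatments Character vector of treatment labels (default a control
#'   and one intervention).
#' @param plots_per_treatment Plots per treatment on each farm (default 1,
#'   matching a single within-farm replication).
#' @param frame_factor Candidate-frame density: candidates per site
#'   (default 25, at least 20 so frame discreteness does not distort spread).
#' @return An object of class `trial_design`: list with `sites` (data.frame
#'   `site_id`, `x`, `y`), `farms` (`site_id`, `farm_id`, `x`, `y`) and
#'   `plots` (`site_id`, `farm_id`, `plot_id`, `treatment`, `x_km`, `y_km`).
#' @examples
#' d <- make_domain("rectangle", c(100, 100))
#' des <- make_cluster_layout(d, n_sites = 5, farms_per_site = 4, seed = 7)
#' nrow(des$plots)  # 5 * 4 * 2
#' @export
make_cluster_layout <- function(domain, n_sites, farms_per_site,
                                spread_scale = 0.55, seed = 1L,
                                treatments = c("control", "treated"),
                                plots_per_treatment = 1L,
                                frame_factor = 25L) {
  stopifnot(inherits(domain, "domain"))
  if (n_sites < 1) .stopf("`n_sites` must be >= 1")
  if (farms_per_site < 2)
    .stopf("`farms_per_site` must be >= 2: a single farm cannot support a within-farm treatment contrast")
  .check_num(spread_scale, "spread_scale", lower = 0)
  if (length(treatments) < 2) .stopf("need at least 2 treatments")
  n_sites <- as.integer(n_sites); farms_per_site <- as.integer(farms_per_site)
  frame <- make_candidate_frame(domain, frame_factor * n_sites, seed = seed)
  ids <- balanced_sample(frame, n_sites, seed = seed + 1L)
  sites <- data.frame(site_id = seq_len(n_sites),
                      x = frame$x[ids], y = frame$y[ids])
  set.seed(seed + 2L)
  nf <- n_sites * farms_per_site
  # uniform in disc: radius ~ R*sqrt(U)
  r <- spread_scale * sqrt(runif(nf))
  a <- runif(nf, 0, 2 * pi)
  farms <- data.frame(site_id = rep(sites$site_id, each = farms_per_site),
                      farm_id = seq_len(nf),
                      x = rep(sites$x, each = farms_per_site) + r * cos(a),
                      y = rep(sites$y, each = farms_per_site) + r * sin(a))
  np <- length(treatments) * plots_per_treatment
  plots <- data.frame(
    site_id = rep(farms$site_id, each = np),
    farm_id = rep(farms$farm_id, each = np),
    plot_id = seq_len(nf * np),
    treatment = rep(rep(treatments, each = plots_per_treatment), nf),
    x_km = rep(farms$x, each = np),
    y_km = rep(farms$y, each = np),
    stringsAsFactors = FALSE)
  structure(list(sites = sites, farms = farms, plots = plots,
                 treatments = treatments,
                 plots_per_treatment = as.integer(plots_per_treatment)),
            class = "trial_design")
}

#' @export
print.trial_design <- function(x, ...) {
  cat(sprintf("Trial design: %d sites, %d farms, %d plots (%s)\n",
              nrow(x$sites), nrow(x$farms), nrow(x$plots),
              paste(x$treatments, collapse = " vs ")))
  invisible(x)
}

#' Serialize a trial design to CSV
#'
#' Writes (and reads back) the plot table with columns
#' `site_id, farm_id, plot_id, x_km, y_km, treatment`.
#'
#' @param design A `trial_design`.
#' @param path Output CSV path.
#' @export
write_design_csv <- function(design, path) {
  stopifnot(inherits(design, "trial_design"))
  write.csv(design$plots[, c("site_id", "farm_id", "plot_id",
                             "x_km", "y_km", "treatment")],
            path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_design_csv
#' @return `read_design_csv()` rebuilds a `trial_design` from the plot table
#'   (site and farm coordinates are recovered from their plots).
#' @export
read_design_csv <- function(path) {
  plots <- read.csv(path, stringsAsFactors = FALSE)
  farms <- unique(plots[, c("site_id", "farm_id", "x_km", "y_km")])
  names(farms)[3:4] <- c("x", "y")
  sites <- do.call(rbind, lapply(split(farms, farms$site_id), function(d)
    data.frame(site_id = d$site_id[1], x = mean(d$x), y = mean(d$y))))
  rownames(sites) <- rownames(farms) <- NULL
  trts <- unique(plots$treatment)
  ppt <- nrow(plots) / (nrow(farms) * length(trts))
  structure(list(sites = sites, farms = farms, plots = plots,
                 treatments = trts, plots_per_treatment = as.integer(ppt)),
            class = "trial_design")
}

#' GeoJSON input/output for domains and designs
#'
#' Minimal GeoJSON (RFC 7946 geometry, planar km coordinates): a domain is a
#' single Polygon feature carrying its area; a design is a FeatureCollection
#' of Point features with site/farm ids.
#'
#' @param domain A `domain` object.
#' @param path File path.
#' @param n_cells Grid resolution when rebuilding a read domain.
#' @export
write_domain_geojson <- function(domain, path) {
  stopifnot(inherits(domain, "domain"))
  ring <- rbind(domain$boundary, domain$boundary[1, , drop = FALSE])
  gj <- list(type = "Feature",
             properties = list(area_km2 = domain$area, kind = domain$kind),
             geometry = list(type = "Polygon",
                             coordinates = list(unname(
                               lapply(seq_len(nrow(ring)),
                                      function(i) as.numeric(ring[i, ]))))))
  jsonlite::write_json(gj, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_domain_geojson
#' @export
read_domain_geojson <- function(path, n_cells = 3000) {
  gj <- jsonlite::fromJSON(path, simplifyVector = FALSE)
  if (!identical(gj$geometry$type, "Polygon"))
    .stopf("expected a Polygon feature")
  ring <- do.call(rbind, lapply(gj$geometry$coordinates[[1]], unlist))
  boundary <- ring[-nrow(ring), , drop = FALSE]
  colnames(boundary) <- c("x", "y")
  area <- .shoelace_area(boundary)
  # rebuild the grid over the polygon (same scheme as make_domain blob branch)
  side <- sqrt(area / n_cells)
  xr <- range(boundary[, 1]); yr <- range(boundary[, 2])
  nx <- ceiling(diff(xr) / side); ny <- ceiling(diff(yr) / side)
  grid <- expand.grid(x = xr[1] + (seq_len(nx) - 0.5) * diff(xr) / nx,
                      y = yr[1] + (seq_len(ny) - 0.5) * diff(yr) / ny)
  dx <- diff(xr) / nx; dy <- diff(yr) / ny
  off <- expand.grid(ox = ((1:4) - 2.5) / 4 * dx, oy = ((1:4) - 2.5) / 4 * dy)
  frac <- numeric(nrow(grid))
  for (i in seq_len(nrow(off)))
    frac <- frac + .points_in_polygon(
      boundary, cbind(grid$x + off$ox[i], grid$y + off$oy[i]))
  grid$w <- dx * dy * frac / nrow(off)
  grid <- grid[grid$w > 0, , drop = FALSE]
  rownames(grid) <- NULL
  structure(list(boundary = boundary, area = area, grid = grid,
                 kind = "polygon"), class = "domain")
}

#' @rdname write_domain_geojson
#' @param design A `trial_design`.
#' @export
write_design_geojson <- function(design, path) {
  stopifnot(inherits(design, "trial_design"))
  feats <- lapply(seq_len(nrow(design$farms)), function(i) {
    f <- design$farms[i, ]
    list(type = "Feature",
         properties = list(site_id = f$site_id, farm_id = f$farm_id),
         geometry = list(type = "Point", coordinates = c(f$x, f$y)))
  })
  gj <- list(type = "FeatureCollection", features = feats)
  jsonlite::write_json(gj, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}
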
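# End-to-end experiments tying the modules together, with CSV/JSON outputs.

.read_config <- function(config) {
  if (is.character(config) && length(config) == 1L) {
    config <- if (grepl("\\.ya?ml$", config, ignore.case = TRUE))
      yaml::read_yaml(config)
    else jsonlite::fromJSON(config, simplifyVector = TRUE)
  }
  if (!is.list(config)) .stopf("`config` must be a list or a YAML/JSON path")
  if (is.null(config$experiment)) .stopf("config must name an `experiment`")
  if (is.null(config$seed)) .stopf("config must carry a `seed`")
  config
}

.config_domain <- function(config) {
  if (!is.null(config$domain_geojson))
    return(read_domain_geojson(config$domain_geojson))
  make_domain(kind = config$domain_kind %||% "rectangle",
              size = config$domain_size %||% c(400, 425),
              seed = config$seed,
              n_cells = config$n_cells %||% 3000)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

.config_effect <- function(config, vc) {
  if (!is.null(config$effect_percent)) {
    if (vc$scale != "log")
      .stopf("`effect_percent` requires a log-scale variable")
    percent_to_log_effect(config$effect_percent)
  } else if (!is.null(config$effect)) {
    config$effect
  } else .stopf("config must give `effect` (absolute) or `effect_percent`")
}

#' Run a named design-evaluation experiment
#'
#' Executes one of the headline experiments end-to-end from a configuration
#' (a list, or a path to a YAML/JSON file) and writes a result CSV plus a
#' JSON metadata sidecar (seed, parameters, package version). Experiments:
#'
#' * `"effective-range"`: effective range per variable of a variance table.
#' * `"simulate-power"`: Monte-Carlo power over a grid of farm numbers
#'   (config: `variable`, `effect` or `effect_percent`, `farms` vector,
#'   `clusters`, `reps`).
#' * `"regional-variance"`: estimation variance of the regional mean for a
#'   fixed number of farms split over varying cluster counts (config:
#'   `variable`, `n_farms`, `clusters` vector).
#' * `"kriging-pev"`: block-kriging PEV quantiles against number of sites
#'   (config: `variable`, `site_counts`, `n_eval`, `block_side`).
#' * `"coverage"`: distance-to-nearest-site quantiles against number of
#'   sites (config: `site_counts`, `n_eval`).
#' * `"make-domain"`: generate and serialize a synthetic domain.
#'
#' @param config Named list or path to YAML/JSON. Must contain `experiment`
#'   and `seed`; `out_dir` defaults to `tempdir()`. An optional
#'   `variance_table` path overrides the bundled parameter table.
#' @return The result data.frame (invisibly also written to
#'   `<out_dir>/<experiment>.csv`), with attribute `files` naming outputs.
#' @export
run_experiment <- function(config) {
  config <- .read_config(config)
  out_dir <- config$out_dir %||% tempdir()
  if (!dir.exists(out_dir)) dir.create(out_dir, recursive = TRUE)
  seed <- as.integer(config$seed)
  tab <- if (is.null(config$variance_table)) default_variance_table()
         else read_variance_table(config$variance_table)
  exp <- config$experiment

  result <- switch(
    exp,
    "effective-range" = {
      data.frame(variable = tab$variable,
                 phi = tab$phi, kappa = tab$kappa,
                 effective_range_km = vapply(tab$variable, function(v)
                   effective_range(vc_for(v, tab)$matern), numeric(1)),
                 row.names = NULL)
    },
    "simulate-power" = {
      vc <- vc_for(config$variable, tab)
      eff <- .config_effect(config, vc)
      clusters <- config$clusters %||% 10L
      reps <- config$reps %||% 1000L
      domain <- .config_domain(config)
      rows <- lapply(seq_along(config$farms), function(i) {
        nf <- config$farms[i]
        if (nf %% clusters != 0)
          .stopf("farms (%d) must be a multiple of clusters (%d)", nf, clusters)
        des <- make_cluster_layout(domain, clusters, nf / clusters,
                                   seed = seed + i)
        pr <- estimate_power(des, simulation_params(vc, eff),
                             n_reps = reps, seed = seed + 1000L + i)
        data.frame(variable = config$variable, n_farms = nf,
                   n_clusters = clusters, effect = eff, power = pr$power,
                   ci_low = pr$ci_low, ci_high = pr$ci_high,
                   n_nonconverged = pr$n_nonconverged)
      })
      do.call(rbind, rows)
    },
    "regional-variance" = {
      vc <- vc_for(config$variable, tab)
      domain <- .config_domain(config)
      nf <- config$n_farms %||% 50L
      rows <- lapply(seq_along(config$clusters), function(i) {
        nc <- config$clusters[i]
        if (nf %% nc != 0)
          .stopf("n_farms (%d) must be a multiple of clusters (%d)", nf, nc)
        des <- make_cluster_layout(domain, nc, nf / nc, seed = seed + i)
        rv <- regional_mean_variance(des$farms[, c("x", "y")], domain, vc)
        data.frame(variable = config$variable, n_farms = nf, n_clusters = nc,
                   sigma2_m = rv$sigma2_m)
      })
      do.call(rbind, rows)
    },
    "kriging-pev" = {
      vc <- vc_for(config$variable, tab)
      domain <- .config_domain(config)
      out <- pev_summary(config$site_counts, domain, vc,
                         n_eval = config$n_eval %||% 5000L,
                         block_side = config$block_side %||% 0.2,
                         seed = seed)
      cbind(variable = config$variable, as.data.frame(out))
    },
    "coverage" = {
      domain <- .config_domain(config)
      as.data.frame(coverage_curve(domain, config$site_counts,
                                   n_eval = config$n_eval %||% 5000L,
                                   seed = seed))
    },
    "make-domain" = {
      domain <- .config_domain(config)
      gj <- file.path(out_dir, "domain.geojson")
      write_domain_geojson(domain, gj)
      data.frame(kind = domain$kind, area_km2 = domain$area,
                 n_cells = nrow(domain$grid), file = gj)
    },
    .stopf("unknown experiment '%s'", exp))

  csv <- file.path(out_dir, paste0(exp, ".csv"))
  write.csv(result, csv, row.names = FALSE, quote = FALSE)
  meta <- list(experiment = exp, seed = seed, config = config,
               package_version = as.character(utils::packageVersion("onfarmdesign")),
               timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"))
  metafile <- file.path(out_dir, paste0(exp, "_meta.json"))
  jsonlite::write_json(meta, metafile, auto_unbox = TRUE, digits = NA,
                       force = TRUE)
  attr(result, "files") <- c(csv = csv, meta = metafile)
  result
}
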
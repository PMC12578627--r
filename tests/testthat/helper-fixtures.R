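# Shared fixtures: small domains and the bundled parameter table.

tab1 <- default_variance_table()

vc_wheat_zn <- vc_for("wheat_zn")
vc_teff_zn  <- vc_for("teff_zn")
vc_wheat_se <- vc_for("wheat_se")
vc_teff_se  <- vc_for("teff_se")

square100 <- make_domain("rectangle", size = c(100, 100), n_cells = 2500)

# paired differences (treated - control) per farm, in farm order
farm_diffs <- function(dat) {
  dd <- dat[order(dat$farm_id, dat$treatment), ]
  with(dd, tapply(response, list(farm_id, treatment), mean))[, 2] -
    with(dd, tapply(response, list(farm_id, treatment), mean))[, 1]
}
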
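---
title: "Evaluating designs for on-farm trial networks"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Evaluating designs for on-farm trial networks}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(onfarmdesign)
```

## The model

Every quality measure in this package derives from one hierarchical
variance model for plot-level responses in an on-farm trial network.
A network consists of *sites* (clusters of neighbouring farms) spread
across a region; each *farm* is a complete block carrying every treatment;
*plots* within a farm receive the treatments. For a response variable on
its analysis scale (Zn concentrations in mg kg⁻¹; Se concentrations in
natural logarithms, because their residuals are lognormal),

$$y_{ijkt} = \mu + \delta\,[t = \text{treated}] + u_i + v_{ij} + e_{ijk},$$

where $u$ is a zero-mean Gaussian between-site effect with covariance
$\varsigma^2_{\text{site}}\,\rho(h)$ over site separations $h$ (km), $v$ is
an iid between-farm-within-site effect with variance
$\varsigma^2_{\text{farm}}$, and $e$ is an iid residual with variance
$\varsigma^2_{\text{res}}$. The site correlation is Matérn,

$$\rho(h) = \frac{1}{2^{\kappa-1}\Gamma(\kappa)}
  \left(\frac{h}{\phi}\right)^{\kappa} K_{\kappa}(h/\phi),$$

with smoothness $\kappa$ and distance parameter $\phi$ (km). The implied
variogram is nugget ($\varsigma^2_{\text{res}} + \varsigma^2_{\text{farm}}$)
plus $\varsigma^2_{\text{site}}\{1 - \rho(h)\}$, zero at $h = 0$ by
convention.

### Where the parameters come from

The bundled table holds the five parameters per variable. They combine two
sources with different strengths. A pilot experiment resolves the
within-site scales (residual and farm variances) but, with few sites, its
between-site variance is too uncertain to use. A regional geostatistical
survey resolves the between-site scale: its correlated variance and Matérn
parameters are adopted for the site component. The survey nugget and the
experimental residual estimate nearly the same quantity (short-range
variation plus analytical error, since the survey's closest pairs sit at a
few hundred metres, far below the effective ranges); the larger of the two
is taken as a conservative residual. `combine_variance_sources()`
implements exactly this rule; regularization of the survey variogram to
site support is deliberately omitted, because within-site separations
(~0.3–1 km) are two orders of magnitude below the effective ranges, making
the correction negligible and its omission slightly conservative.

### Effective range

The *effective (practical) range* is reported as the distance at which
$\rho(h)$ falls to 0.05 — the usual practical-range convention, which for
$\kappa = 0.5$ gives the familiar $3\phi$. The threshold is an argument of
`effective_range()`; the solution uses monotone bracketing and bisection to
1 m. Published range figures for the same parameter sets can differ by a
few kilometres depending on the convention and on parameter rounding, so
ranges computed here should be compared at that granularity.

## Power analysis

### Why only the residual variance matters

Each farm is a complete block. The treatment contrast is therefore
estimated entirely from within-farm comparisons: site and farm effects
cancel, and with one plot per treatment per farm the REML mixed-model
t-test is algebraically the paired t-test on within-farm differences
$d_{ij}$, with $\mathrm{var}(d) = 2\varsigma^2_{\text{res}}$ and
$n_{\text{farms}} - 1$ degrees of freedom. Two consequences shape the
analyses:

* power depends on the *total number of farms*, almost not at all on how
  they are split into clusters (the tests verify this as a property);
* `analytic_power()` — a noncentral-t computation with
  $\text{ncp} = \delta / \sqrt{2\varsigma^2_{\text{res}}/(r\,n)}$ and
  $df = n(2r - 1) - 1$ for $r$ plots per treatment per farm — is an
  *independent* oracle for the whole simulation pipeline.

### The Monte-Carlo loop

`estimate_power()` simulates `n_reps` (default 1000) realizations:
correlated site effects by a Cholesky factor of the Matérn correlation
matrix (computed once per design, with a $10^{-10}$ jitter guarding
near-coincident sites), iid farm and plot effects, each component on its
own seeded stream so ablations are paired across replicates. Each
realization is analysed by REML (`fit_lmm()`, which delegates the
numerical fit to `lme4` with variances bounded at zero and tight optimizer
tolerances) and the two-sided p-value uses containment degrees of freedom
($N - n_{\text{farms}} - 1$), chosen because it reproduces the paired-test
equivalence that the block algebra dictates. Fits that fail after three
optimizer restarts are flagged and counted, never treated as rejections.
The rejection proportion gets an exact Blaker 95% confidence interval
(`blaker_ci()`, inversion of the acceptability function by a coarse scan
from the Clopper–Pearson bounds plus bisection to $10^{-6}$; it is always
nested inside Clopper–Pearson).

### Plots per farm

The default is one plot per treatment per farm (a single within-farm
replication, as in the pilot). This is configurable
(`plots_per_treatment`), and it matters at the margins: for the hardest
scenario considered — a 10% increase in teff Se at 70 farms —
`analytic_power(log(1.1), 0.60, 70)` gives 0.111 with one plot per
treatment and `analytic_power(log(1.1), 0.60, 70, plots_per_treatment = 2)`
gives 0.176. Small published power figures for such scenarios are
sensitive to this configuration choice, so the package reports both routes
rather than hiding the gap.

## Regional-mean and spatial precision

For Zn (measurement scale) two further quality measures are computed from
the variogram alone. Both refuse log-scale variables unless explicitly
overridden, because variogram-based error variances on a log scale do not
translate into useful precision statements for the original units.

**Estimation variance of the regional mean.**
$\sigma^2_m = \frac{2}{n}\sum_i \bar\gamma(x_i, B) - \frac{1}{n^2}
\sum_i\sum_j \gamma(x_i - x_j) - \bar\gamma(B, B)$, where
$\bar\gamma(\cdot, B)$ are variogram averages over the domain $B$,
implemented as area-weighted means over the domain grid (the averages must
be area-normalized for the expression to be dimensionally consistent).
The observation points are the farm locations. In the pure-nugget limit
the expression collapses to $c_0/n$ exactly, and the full version is
validated against a 2000-realization random-field simulation of the
mean-squared error.

**Block-kriging prediction error variance.** Ordinary kriging in
semivariance form with the unbiasedness constraint; the prediction support
is a square block (default side 0.2 km, a farm-scale support) discretized
8 × 8; within-block semivariance averages use $\gamma(0) = 0$ on the
coincident diagonal, the standard block-kriging convention, so block
averaging removes part of the nugget. One factorization of the bordered
system per site configuration serves all evaluation points. The
covariance-form solution is maintained in the tests as a dual check to
$10^{-8}$ relative.

## Synthetic geometry

The generator replaces the real survey frame so every analysis is
self-contained:

* **Domain**: a 400 × 425 km rectangle by default — the order of size of
  the motivating region — so coverage and precision curves are on a
  comparable scale; a smooth random "blob" polygon checks that nothing
  depends on rectangularity. Planar km coordinates throughout; geodesy is
  out of scope at these extents. Grids target ≥ 2000 interior cells
  (boundary cells get fractional areas from 4 × 4 subsampling, so cell
  weights integrate the area to well under 1%); convergence tests double
  the resolution.
* **Sites**: selected by LPM1 (`balanced_sample()`) from a uniform
  candidate frame of at least 20–25 candidates per site, dense enough that
  frame discreteness does not distort spread. LPM1 was chosen over other
  spread designs as the canonical local pivotal variant whose equal
  inclusion probabilities ($n/N$) are straightforward to verify by
  Monte Carlo.
* **Farms**: scattered uniformly in a disc of radius 0.55 km around their
  site. The radius was calibrated once so the within-site pairwise
  distance median matches the pilot statistic (≈ 0.5 km); the disc is a
  stand-in (how farms were really located is not recorded), so quartiles
  beyond the median match only approximately, and distances scale linearly
  with `spread_scale`.

What the generator does **not** emulate: the real cropland mask and its
holes, landscape-position strata, unequal cluster sizes, non-Gaussian
responses, year-to-year variance. Passing tests therefore demonstrate the
*methods* and the model's internal consistency; absolute kilometre or
variance values for a real region require that region's frame and
parameters.

## Numerical choices and degenerate inputs

* Matérn evaluation by the standard modified-Bessel routine; lags below
  $10^{-12}$ km return $\rho = 1$; correlations are clamped to $(0, 1]$
  against floating-point underflow at extreme lags.
* `effective_range()` bisection tolerance $10^{-3}$ km.
* Zero variance components are legal everywhere (pure-nugget models,
  noise-free trials); the noise-free mixed model is answered exactly from
  the block algebra rather than fitted.
* Duplicate kriging sites are deduplicated with a warning; a still-singular
  system errors.
* Points outside the domain in `regional_mean_variance()` warn and
  proceed (the formula remains defined).
* Test problem sizes are chosen to exercise the asymptotics the properties
  rely on while keeping the default suite fast: e.g. 1500–2000 evaluation
  points for coverage/PEV curves, 300–1000 Monte-Carlo replicates with
  3–3.5 standard-error tolerances, a 900-cell grid for the
  regional-variance simulation oracle.

## Known limitations

* Two treatments, complete blocks only; incomplete blocks would make power
  depend on cluster structure and are not analysed.
* The REML/paired-t equivalence is exact only while variance estimates are
  interior; at boundary estimates ($\hat\varsigma^2 = 0$) the REML pools
  strata and the p-values can differ slightly — the convention of the
  standard mixed-model toolchain.
* Back-transformation of log-scale results to original units is out of
  scope for the spatial quality measures.
* LPM nearest-neighbour searches are linear scans (adequate to a few tens
  of thousands of candidates); very large frames would want a spatial
  index.
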
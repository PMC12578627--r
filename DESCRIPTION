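Package: onfarmdesign
Title: Design Evaluation for On-Farm Trial Networks Under Nested Spatial
    Variance Models
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Tools for planning regional networks of on-farm field trials,
    motivated by agronomic biofortification (zinc, selenium) trials on
    smallholder farms. Combines pilot-experiment variance components with a
    survey-derived Matern spatial model into a nested plot/farm/site variance
    model, and evaluates candidate designs by Monte-Carlo power analysis of
    the blocked treatment contrast (with exact Blaker binomial confidence
    intervals), by the estimation variance of a regional treatment mean from
    variogram averages, by ordinary block-kriging prediction-error variance
    surfaces, and by distance-to-nearest-site spatial coverage curves. Sites
    are placed by spatially balanced sampling (local pivotal method).
    Synthetic study domains and cluster/farm layouts reproduce the geometric
    statistics of the motivating pilot, so every analysis runs without
    external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    jsonlite,
    lme4,
    mgcv,
    Rcpp,
    stats,
    utils,
    yaml
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
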
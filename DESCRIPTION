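Package: povgp
Title: Multi-Source Gaussian Process Small-Area Estimation of Multidimensional Poverty
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Small-area estimation of multidimensional poverty by fusing
    heterogeneous per-commune data sources. Each source is modelled with
    Gaussian-process regression using a product feature-by-spatial squared
    exponential kernel and an elastic-net-penalized linear mean, fitted by
    maximizing the penalized marginal likelihood. Source-specific posterior
    predictions are combined per commune as an inverse-variance-weighted
    Gaussian mixture with exact first and second moments. The package also
    computes Alkire-Foster deprivation statistics (headcount H, intensity A,
    MPI) from household microdata, aggregates subscriber-level call-record
    features to communes through home-antenna assignment and Voronoi overlap
    weights, evaluates models with a distance-buffered spatial
    cross-validation protocol, and ships seeded synthetic generators for
    communes, antennas, event logs and household censuses so that the whole
    pipeline runs end-to-end without proprietary data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    graphics,
    jsonlite
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
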
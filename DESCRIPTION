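Package: aviland
Title: Land-Use Diversity and Avian Taxonomic and Functional Richness
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A reproducible pipeline linking regional land-use diversity to
    bird taxonomic and functional richness on an equal-area grid. Provides a
    seeded synthetic-world generator with known ground-truth effect structure
    (categorical land-cover rasters, productivity surfaces, trait pools,
    habitat-gated occupancies), grid assembly with range filtering and cell
    exclusions, a mixed-trait functional space (trait PCAs, Gower distances,
    trait contributions, principal coordinates), per-cell diversity metrics
    including convex-hull functional richness in five dimensions, zonal
    Shannon land-cover diversity with environmental covariates, and the
    competing additive-model suite (shrinkage thin-plate smooths, AIC and
    deviance-explained comparison, jackknife variable importance, per-realm
    partial slopes, residual diagnostics, smoothing-basis sensitivity).
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    mgcv,
    Rcpp,
    jsonlite,
    yaml,
    stats,
    utils,
    graphics,
    grDevices,
    tools
LinkingTo: Rcpp, RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    cluster,
    ape,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
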
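Package: laisens
Title: Temperature Sensitivity to Leaf Area Change and Vegetation-Driven
    Climate Mitigation
Version: 0.1.0
Authors@R:
    person("Package", "Maintainer", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Estimates the sensitivity of near-surface air temperature to
    leaf-area-index (LAI) change from gridded monthly observations using a
    space-for-time decomposition with inverse-distance-weighted stable-LAI
    reference cells, expresses the sensitivity as regime-specific bivariate
    quadratic response surfaces in background-climate drivers (snow cover,
    shortwave radiation, land evaporation), and applies the fitted surfaces to
    multi-model scenario ensembles to project and attribute future
    vegetation-driven biophysical and biochemical temperature mitigation. A
    synthetic-data module generates observation-like baselines with a known
    injected sensitivity and CMIP6-like scenario ensembles so the whole
    pipeline is testable at desk scale.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    data.table,
    jsonlite,
    stats,
    utils
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
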
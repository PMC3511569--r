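Package: firekrige
Title: Bayesian Kriging and Microbial Lipid Analysis of Post-Fire Soil
    Spatial Structure
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Model-based geostatistics for fine-scale spatial structure of
    soil and microbial variables on nested post-fire sampling grids.
    Implements Bayesian kriging of a Gaussian spatial linear model with
    exponential correlation: the joint posterior of the correlation scale
    and relative nugget is computed on a discrete parameter grid with the
    trend coefficients and sill marginalized analytically under flat and
    reciprocal priors, followed by posterior sampling, spatial prediction,
    and leave-one-out cross-validation. Also provides phospholipid fatty
    acid (PLFA) community metrics (abundance, fungi-to-bacteria ratio,
    Gram-positive/negative marker sums, stress ratio) with the associated
    core-filtering rules, isotope pool-dilution net-rate arithmetic,
    bidirectional stepwise-AIC selection of net N mineralization
    predictors, a synthetic-data generator emulating an 81-core nested
    sampling design with known ground truth, and a YAML-configured
    pipeline driver.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    yaml
Suggests:
    testthat (>= 3.0.0),
    MASS,
    pracma,
    jsonlite,
    optparse
Config/testthat/edition: 3
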
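Package: popfire
Title: Geographically Weighted Analysis of Burned Area and Population Density
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for studying how satellite-derived burned area relates to
    human population density on a global lon/lat grid. Implements
    geographically weighted regression (GWR) with an adaptive Gaussian kernel,
    corrected-AIC bandwidth selection, hat-matrix diagnostics and effective
    parameter counts; per-cell t-tests with a family-wise alpha correction and
    a Monte Carlo permutation test of coefficient nonstationarity; ordinary
    least squares baselines; cross-tabulation of significant slope signs
    against major anthrome (anthropogenic biome) types; and continuous
    piecewise-linear ("broken stick") quantile regression for locating
    population-density thresholds in fire response. A synthetic-world
    generator with known spatially varying coefficient surfaces makes every
    stage testable without external rasters.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    geosphere,
    jsonlite,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
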
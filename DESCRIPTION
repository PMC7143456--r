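Package: streamsem
Title: Path Analysis of Watershed Land Use, Stream Water Quality and
    Benthic Macroinvertebrate Condition
Version: 1.0.0
Authors@R: person("streamsem", "developers", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: Tools for linking watershed land use to stream water quality
    and benthic macroinvertebrate condition with recursive path models
    (structural equation models over observed variables). Provides the
    saprobic Benthic Macroinvertebrate Index (BMI) score, maximum-likelihood
    covariance-structure estimation with standard errors and critical
    ratios, direct/indirect/total effect decomposition, the six classical
    goodness-of-fit indices (NFI, TLI, CFI, GFI, AGFI, RMSEA), critical-ratio
    based model pruning, Kolmogorov-Smirnov/Lilliefors normality screening
    with log transformation, and a linear-Gaussian synthetic-data generator
    so the whole pipeline is testable without access to monitoring data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
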
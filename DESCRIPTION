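Package: dpcrcode
Title: Combinatorial Fluorescence Encoding and Poisson Deconvolution for
    Multiplexed Digital PCR
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Tools for universal-signal-encoding digital PCR (dPCR), where each
    target carries a combinatorial tag built from one or more universal
    hydrolysis probe sites at two amplitude levels across the instrument's
    color channels. Provides codebook algebra and encoding-capacity
    combinatorics, a partition-level simulator with Poisson loading and
    configurable instrument artifacts (cluster noise, baseline offsets,
    spectral crosstalk, rain, incomplete probe hydrolysis), amplitude
    preprocessing (baseline subtraction, crosstalk compensation, 1i
    calibration), threshold classification of partitions into ternary labels,
    hierarchical Poisson deconvolution of ambiguous partition labels into
    per-target copy numbers, evaluation metrics (partition- and target-level
    accuracy, variant allele fractions), and Monte Carlo design studies of
    multiplexing limits (co-presence thresholds, CV scaling, crosstalk
    sensitivity).
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    graphics,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr,
    knitr
Config/testthat/edition: 3
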
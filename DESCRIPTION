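Package: lesionnet
Title: Wavelet Functional Connectomes and Lesion Network Analysis
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Constructs parcel-level functional brain networks from BOLD-like
    time series via maximal overlap discrete wavelet transform (MODWT)
    correlation, thresholds them to a fixed mean degree under a false
    discovery rate constraint, and characterises the resulting binary graphs:
    small-world indices against degree-preserving rewired nulls, hub tables,
    degree-distribution model selection (exponential, power law, exponentially
    truncated power law) by AIC, robustness under random error and targeted
    attack, and lesion "connections-at-risk" reports classified by anatomical
    range. Includes a synthetic cohort generator with known modular covariance
    ground truth and lesion injection for validation, plus exporters for
    BrainNet Viewer and circular-plot tooling.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    igraph,
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
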
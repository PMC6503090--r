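Package: barotrend
Title: Robust Bootstrap Trend Analysis of Baroreflex-HRV Correlations
    Across Blood-Pressure Groups
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Tools for studying how systolic arterial pressure (SAP) groups
    modulate the correlation between the cardiac baroreflex alpha index and
    heart-rate-variability / autonomic proxies. Provides a synthetic cohort
    generator with a realistic demographic and SAP stratum structure,
    age-by-gender ANOVA adjustment and the composite ANSI index, Winsorized
    correlation, stratified balanced bootstrap with per-replicate
    recomputation, BCa confidence intervals, permutation tests of zero
    correlation, the Hettmansperger-Norton patterned-trend test against
    monotonic and umbrella alternatives, and a synoptic trend classifier.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    grDevices,
    ggplot2,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    boot
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
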
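Package: hcofam
Title: Family-Based Robustness Analysis of Half-Center Oscillator Model
    Databases
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Tools for assessing the robustness of bursting activity in
    brute-force databases of conductance-based half-center oscillator
    (HCO) model instances.  Provides parameter-grid enumeration and a
    tabular instance database, burst detection and characterization of
    paired voltage traces (period, phase, duty cycle, spike frequency),
    activity classification into realistic and functional HCO classes,
    grouping of instances into one-parameter families, family-structure
    robustness measures and the weighted robustness score, slope-based
    period-sensitivity classification of family curves, ensemble
    selection, a config-driven two-cell conductance-based simulator, and
    a synthetic-data generator so the whole pipeline runs at desk scale.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    tidyr,
    purrr,
    tibble,
    readr,
    rlang,
    ggplot2,
    generics,
    withr,
    yaml,
    deSolve,
    pracma,
    e1071,
    stats,
    tools
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    optparse,
    knitr,
    rmarkdown
VignetteBuilder: knitr
Config/testthat/edition: 3
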
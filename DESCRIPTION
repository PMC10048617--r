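Package: strpg
Title: Probabilistic Genotyping Validation for Single-Cell STR Profiles
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools to validate probabilistic genotyping of short tandem
    repeat (STR) profiles obtained from single or few cells. Includes a
    synthetic low-template electropherogram generator (drop-out, extreme
    heterozygote imbalance, elevated stutter of six types, drop-in,
    degradation, inhibition, saturation clipping), calibration estimators
    for analytical thresholds, stutter-ratio regressions, drop-in rate and
    cap, instrument saturation and heterozygote-balance variance bounds, a
    replicate-aware semi-continuous drop-out/drop-in likelihood-ratio
    engine and a simplified quantitative gamma peak-height engine with
    Balding-Nichols theta-corrected genotype probabilities, plus
    validation experiment harnesses (sensitivity/specificity against a
    non-contributor database, number-of-contributors misspecification,
    replicate misclassification, mixture deconvolution).
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    yaml
Suggests:
    jsonlite,
    knitr,
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
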
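Package: neovalid
Title: Validation of EPR-Derived Neonatal Registry Data Against a Gold-Standard Cohort
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for auditing the completeness and accuracy of a neonatal
    registry extracted from electronic patient records (EPR) against an
    independently collected gold-standard cohort. Links infants and episodes
    of care across the two databases, derives process and outcome variables
    from daily care records, classifies gold-versus-registry value pairs
    under preset tolerance bands, and reports discordancy rates (exact
    Poisson and Agresti-Coull intervals), diagnostic accuracy (sensitivity,
    specificity, predictive values with Clopper-Pearson intervals), and
    per-variable completeness profiles. Includes a synthetic twin-cohort
    simulator with a configurable error model and per-cell truth log, so the
    whole pipeline can be exercised end-to-end with known, recoverable error.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
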
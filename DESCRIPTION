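Package: sedrisk
Title: Tiered Probabilistic Ecological Risk Assessment for Sediment Contaminants
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Tools for tiered ecological risk assessment of contaminated
    sediments: screening of station-by-element concentration tables against
    sediment quality guideline trigger values (ISQG-Low/High), maximum
    likelihood fitting of log-normal and Burr Type III distributions to
    exposure and species toxicity data with Kolmogorov-Smirnov goodness of
    fit by parametric bootstrap, hazardous concentration (HC) estimation
    with nonparametric bootstrap lower confidence limits, convolution of
    exposure and species sensitivity distributions to estimate the
    percentage of species affected, and computation of required reductions
    and median target concentrations to reach a chosen protection level.
    Includes seeded synthetic generators for exposure tables and species
    toxicity datasets with known distributional structure.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
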
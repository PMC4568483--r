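Package: spheroscreen
Title: Image-Based Spheroid Contraction Toxicity Screening
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Quantifies cytotoxicity from time-lapse images of magnetically
    bioprinted spheroids in multiwell plates. Dark spheroids on a bright
    light-pad background are segmented per well, their projected area is
    tracked over time, and the negated least-squares slope of area over the
    first 150 minutes ("contraction rate") serves as the cytotoxic endpoint.
    Rates are normalized to solvent-matched vehicle controls, fitted against
    log concentration with a Boltzmann sigmoidal to estimate IC50, and
    screening quality is summarised with the Z'-factor, one-way ANOVA and
    Tukey HSD post hoc tests. A fully seeded synthetic plate-image generator
    with analytic contraction kinetics provides ground truth for validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    EBImage,
    generics,
    ggplot2,
    jsonlite,
    minpack.lm,
    png,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    tiff,
    utils,
    withr
Suggests:
    jpeg,
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
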
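Package: caffval
Title: Validation Toolkit for GC-FID Caffeine Quantification in Coffee
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A reusable, tested pipeline for single-laboratory validation of
    gas-chromatography flame-ionisation (GC-FID) quantification of caffeine in
    coffee grains, following ISO 17025 and Commission Decision 2002/657/EC
    practice. Provides synthetic chromatogram and study generators with known
    ground truth, peak detection and trapezoidal integration, external and
    standard-addition calibration with LOD/LOQ from the intercept standard
    error, matrix-effect slope comparison, intra/inter-day precision via
    one-way ANOVA variance components with Horwitz/HORRAT acceptance, spike
    recovery, Shewhart internal quality-control charting, a Eurachem/CITAC
    combined and expanded uncertainty budget, and dietary caffeine intake
    assessment, orchestrated end to end from a single JSON run configuration.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    pracma,
    purrr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
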
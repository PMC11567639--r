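Package: ethnosurvey
Title: Quantitative Ethnobotany Indices for Informant Use-Report Surveys
Version: 0.1.0
Authors@R:
    person("Package", "Author", , "author@example.org", role = c("aut", "cre"))
Description: Analysis of long-format ethnobotanical use-report tables, in
    which each row records one informant citing one plant species for one
    use category. Computes the standard per-species indices (use reports
    UR, frequency of citation FC, number of uses NU, cultural importance
    CI, relative frequency of citation RFC, relative importance RI,
    cultural value CVe), per-use-category informant agreement ratios
    (IAR), and species-by-category fidelity levels (FL). Includes a seeded
    synthetic survey generator with closed-form expected indices for
    parameter-recovery testing, a reproducible reporting pipeline with CSV
    and markdown writers, and the published summary tables of a survey of
    258 vernacular-building artisans in Ghana's Adaklu district as
    reference data, from which an exact record-level table can be
    reconstructed.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    jsonlite,
    readr,
    rlang,
    stats,
    tibble,
    tools,
    utils
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
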
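Package: electrotherm
Title: Electrothermal Phenotyping and Delineation of Ex Vivo Breast Biopsy Tissue
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Simulation and analysis pipeline for microchip-based electrothermal
    phenotyping of ex vivo breast biopsy tissue. Provides a forward model of
    bulk-resistance, surface-resistance, microheater power and resistance
    temperature detector (RTD) measurements on cubical tissue blocks heated
    from 25 to 37 degrees Celsius; inverse estimators for bulk resistivity,
    surface (sheet) resistivity and steady-state thermal conductivity; a
    synthetic cohort generator reproducing the group structure of a paired
    tumor/adjacent-normal study of deparaffinized and formalin-fixed samples;
    multi-parameter statistical delineation (paired and Welch t tests, fold
    changes, Fisher's combined probability test, pairwise regression) and a
    bimodal tumor/normal classification rule; and a lightweight 2-D
    finite-difference steady-state heat solver for studying the effect of the
    chip's thermal isolation trench.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    jsonlite,
    Matrix,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    tools,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
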
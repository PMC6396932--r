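Package: hscdyn
Title: Feedback-Mediated Kinetics of Hematopoietic Stem Cell Cultures
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Ordinary differential equation models of in-vitro hematopoietic
    stem cell differentiation under cytokine feedback. Implements a 3-state
    (LSK, CMP, Terminal) and a 5-state (LT-HSC, ST-HSC, MPP, CMP, Terminal)
    differentiation hierarchy in which self-renewal, quiescence, proliferation,
    apoptosis and a direct progenitor-to-Terminal 'jump' respond to stem cell
    factor, nutrient availability and four pools of cell-secreted biomolecules.
    Simulates pulsed media-exchange cultures, fits kinetic parameters to cell
    count time series, performs local one-at-a-time parameter sensitivity
    analysis, and generates synthetic flow-cytometry-like observations with
    multiplicative replicate noise.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    deSolve,
    tibble,
    dplyr,
    tidyr,
    purrr,
    rlang,
    ggplot2,
    generics,
    yaml,
    jsonlite,
    stats,
    utils,
    minpack.lm,
    lhs
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
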
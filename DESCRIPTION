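Package: ivperm
Title: Barrier-Model Analysis of Ion-Channel Current-Voltage Relations
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.com",
                  role = c("aut", "cre"))
Description: Tools for the quantitative analysis of patch-clamp
    current-voltage (I-V) relations of anion channels with an Eyring-type
    multi-barrier permeation model. Provides the closed-form n-barrier
    current equation and an independent steady-state hopping-chain solver,
    conversion of relative rate constants to descriptive activation-energy
    profiles, rectification indices, rundown correction via a fixed
    pre-pulse reference, background subtraction, voltage-offset quality
    control, normalization and aggregation of replicate patches, weighted
    nonlinear fitting of the barrier model to normalized I-V data, slope
    conductance and concentration-conductance summaries, solution
    bookkeeping with Nernst-potential based anion-selectivity analysis,
    and a synthetic inside-out patch recording generator with known ground
    truth for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
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
    utils,
    withr
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
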
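Package: vactrace
Title: Solution Design and Single-Channel Analysis for Vacuolar Patch-Clamp
    Recordings
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for the quantitative analysis chain of vacuolar (tonoplast)
    patch-clamp experiments on nitrate-permeable anion channels: Ca/Mg-EGTA
    buffer design by multi-equilibrium solving, activity-corrected
    electrochemistry (Nernst and Goldman-Hodgkin-Katz reversal potentials,
    permeability ratios, Henderson liquid junction potentials), a seeded
    stochastic simulator of multi-channel patch currents under voltage-step
    protocols, and the measurement pipeline built on amplitude histograms
    with Gaussian-mixture fits (open probability from peak areas, channel
    counting, unitary current and chord conductance, I/V and J/V curves with
    reversal-potential estimation). All user-facing functions take and
    return tidy data frames.
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
    minpack.lm,
    purrr,
    rlang,
    signal,
    stats,
    tibble,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
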
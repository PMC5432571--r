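Package: glyrblock
Title: Voltage-Dependent Open-Channel Block Analysis for Glycine Receptor Channels
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for quantifying voltage-dependent open-channel block of
    glycine-receptor (GlyR) chloride channels by anionic blockers such as
    niflumic acid. Implements kinetic gating-plus-block schemes with Woodhull
    voltage dependence and their analytic equilibrium solutions; a synthetic
    patch-clamp generator (whole-cell ramp and long application protocols,
    single-channel Gillespie simulation) with known ground truth; trace
    analysis (percent inhibition, fraction-remaining versus voltage,
    rectification, cell quality filters); Hill equation dose-response fitting
    and IC50(V) tables; Woodhull estimation of the fractional electrical
    distance of the blocking site; single-channel idealization, burst and
    flicker-block analysis; and a Monte-Carlo energy-minimization module that
    pulls a flexible anionic ligand through pentameric TM2 pore models to map
    interaction-energy profiles along the pore axis.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    tidyr,
    purrr,
    tibble,
    rlang,
    ggplot2,
    readr,
    jsonlite,
    minpack.lm,
    deSolve,
    generics,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    bio3d
Config/testthat/edition: 3
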
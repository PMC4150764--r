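Package: tetrdna
Title: Structural and Thermodynamic Analysis of TetR-Family Repressor-Operator
    Complexes
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for dissecting how TetR-family transcriptional regulators
    recognize their operator DNA. Builds ideal and deformed B-form DNA
    duplexes from fiber parameters, computes base-pair step parameters,
    global bend and groove widths in the 3DNA-style mid-step-triad
    convention, inventories protein-DNA and protein-protein polar contacts
    and diffs them between apo and DNA-bound states, classifies disulfide
    geometry and torsional strain, measures dimer-of-dimers quaternary
    arrangement and solvent-accessible surface area, models and fits
    isothermal titration calorimetry data with one- and two-sets-of-sites
    cooperative binding models, and scans genomes for degenerate operator
    consensus matches. Every analysis stage can be exercised on synthetic
    inputs generated by the package itself.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    bio3d,
    Biostrings,
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    minpack.lm,
    purrr,
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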
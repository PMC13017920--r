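Package: mealkinetics
Title: Postprandial Stable-Isotope Amino Acid and Protein Kinetics
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Analysis of primed-continuous stable-isotope tracer studies of
    postprandial protein metabolism. Implements non-steady-state Steele
    isotope-dilution estimators of whole-body phenylalanine and tyrosine
    rates of appearance and disappearance, meal-derived (oral) and
    endogenous appearance from an intrinsically labelled meal protein,
    phenylalanine hydroxylation, whole-body protein synthesis, degradation
    and net balance, precursor-product fractional synthesis rates for
    muscle and plasma proteins, two-pool arteriovenous balances across a
    tissue bed, and Matsuda/HOMA-IR insulin-sensitivity indices with
    trapezoid AUC utilities. A seeded forward simulator of the full study
    design (one-pool tracer dynamics, labelled-meal absorption,
    hydroxylation, arteriovenous gradients, biopsy incorporation,
    measurement noise) provides ground truth for parameter-recovery
    verification without any real data.
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
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    zoo
Suggests:
    deSolve,
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
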
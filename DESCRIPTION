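Package: trtsim
Title: Simulation of Tumor Response to Targeted Alpha-Particle Radionuclide Therapy
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Tools for modelling targeted radionuclide therapy with the
    alpha emitter astatine-211 in implanted (xenograft) mouse tumors. Provides
    a four-compartment pharmacokinetic model of drug delivery (blood, tumor,
    body organs, excretion) with both a stiff-capable numerical solver and a
    closed-form solution for the no-return-path case; tumor dosimetry from the
    tumor time-activity curve (dose rate, cumulative and total absorbed dose,
    multi-injection superposition); logistic tumor-growth models with a
    radiation kill term, a damaged-cell volume-loss delay, and dose-dependent
    impairment of regrowth; per-animal log-linear growth-rate estimation with
    cohort summaries; and a reproducible synthetic-cohort generator for
    dose-response experiments. Results are returned as tibbles that work
    naturally with dplyr and ggplot2.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    deSolve,
    dplyr,
    generics,
    ggplot2,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    withr
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
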
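Package: patlakr
Title: Dynamic PET Quantification, Uptake-Time Correction, and Intrascan Repeatability
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for quantitative dynamic positron emission tomography (PET).
    Simulates two-tissue-compartment tracer kinetics and arterial input
    functions, renders small 4D voxel phantoms, fits and extrapolates arterial
    input functions, estimates the Patlak net influx rate (Ki) at lesion and
    voxel level, computes SUV and tumor-to-blood ratios (SUR) with
    uptake-time-corrected variants (cSUV, cSUR), and summarizes intrascan
    test-retest repeatability (Bland-Altman limits of repeatability,
    absolute-agreement intraclass correlation, Wilcoxon signed-rank tests).
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    minpack.lm,
    purrr,
    rlang,
    RNifti,
    stats,
    tibble,
    tidyr,
    utils,
    yaml
Suggests:
    deSolve,
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
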
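Package: scnclone
Title: Two-Phase Clonal Dynamics of CSF3R-Truncation Mutants in Severe
    Congenital Neutropenia
Version: 1.0.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Models the progression from severe congenital neutropenia (SCN)
    to secondary myelodysplastic syndrome as a two-phase clonal process. Phase
    one is a Markov branching process of fetal bone-marrow expansion that
    seeds tens to hundreds of cells carrying a CSF3R truncation mutation;
    phase two is selective takeover of the myeloid progenitor pool under
    chronic G-CSF therapy, modelled both as a constant-size Moran process with
    directional selection (analytic formulas, an exact absorbing-chain oracle
    and a stochastic simulator) and as a Moran process with age-varying
    population size on a calibrated compartmental model of human
    hematopoiesis. Also provides the experimental selection-coefficient
    estimator based on G1/G0 cell-cycle fractions, Hill-type dose-response
    fitting with a shared baseline, split-dose rank testing, and synthetic
    generators emulating the flow-cytometry and MTT assay readouts.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    deSolve,
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    Matrix,
    purrr,
    Rcpp,
    rlang,
    stats,
    tibble,
    tidyr,
    utils
LinkingTo:
    Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr,
    yaml
Config/testthat/edition: 3
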
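Package: pbpkddi
Title: Whole-Body PBPK Simulation of Drug-Drug Interactions in
    Stem-Cell Transplantation Regimens
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: A reduced whole-body physiologically based pharmacokinetic
    (PBPK) engine for evaluating drug-drug interactions among drugs used
    before and early after hematopoietic stem-cell transplantation.
    Implements perfusion-limited organ models with gut and liver first-pass
    metabolism, the five reversible inhibition mechanisms plus
    mechanism-based inactivation and Emax/EC50 induction acting on dynamic
    enzyme pools, genotype-aware virtual populations with log-normal
    variability, middle-out parameter fitting against observed
    concentration-time data, DDI-ratio evaluation under the two-fold and
    Guest acceptance criteria, and dose optimization against therapeutic
    windows over multi-drug clinical timelines. Ships a curated 13-drug
    compound library and synthetic-data generators for testing.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    deSolve,
    jsonlite,
    lhs,
    stats,
    utils,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
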
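## Enzyme and transporter registry.
##
## E0 is the baseline reference concentration (umol/L) of the protein in its
## expressing tissue; kdeg the first-order turnover rate of the pool. These
## are shipped defaults in the tradition of reference-human compilations:
## CYP abundances converted from microsomal pmol/mg data, transporters set to
## unit scale so that pathway CLint values absorb the absolute level. All are
## overridable per individual.

ENZYME_IDS <- c("CYP3A4", "CYP3A5", "CYP2C9", "CYP2C19", "CYP2D6", "CYP1A2",
                "UGT1A1", "UGT1A3", "UGT1A4", "GSTA1",
                "P-gp", "BCRP", "OATP1B1", "OATP1B3", "MRP", "BSEP")

## kdeg 0.0158 1/h (pool half-life ~44 h) is the shipped default for all
## proteins: it places post-inducer enzyme recovery in the clinically
## reported 7-10 day window and is within the range of measured hepatic CYP
## turnover half-lives (26-140 h).
DEFAULT_KDEG <- 0.0158

#' Enzyme and transporter registry
#'
#' Shipped reference levels for the 16 enzymes/transporters the engine knows
#' about: baseline concentration `E0` (umol/L in expressing tissue), pool
#' degradation rate `kdeg` (1/h), and the organ weights over which a pathway's
#' intrinsic clearance is partitioned.
#'
#' @return data.frame with columns `enzyme`, `E0`, `kdeg`
#' @export
enzyme_registry <- function() {
  data.frame(
    enzyme = ENZYME_IDS,
    E0 = c(4.32, 0.04, 3.84, 0.76, 1.56, 1.80,
           2.00, 1.00, 1.20, 10.0,
           1.00, 0.50, 2.00, 1.00, 1.00, 0.50),
    kdeg = DEFAULT_KDEG,
    stringsAsFactors = FALSE
  )
}

## Relative expression weights across organs (sum to 1 per enzyme).
## CYP3A4 and the apical efflux transporters have a gut component (first-pass
## wall metabolism / efflux); everything else is hepatic here.
enzyme_organ_weights <- function(enzyme) {
  switch(enzyme,
    "CYP3A4" = c(liver = 0.9, gut = 0.1),
    "P-gp"   = c(liver = 0.3, gut = 0.7),
    "BCRP"   = c(liver = 0.5, gut = 0.5),
    c(liver = 1.0))
}

## Genotype phenotype tables: reference protein concentrations (umol/L).
PHENOTYPE_TABLES <- list(
  CYP2C19 = c(NM = 0.76, IM = 0.40, PM = 0.01),
  CYP3A5  = c(expresser = 0.68, non_expresser = 0.04)
)

#' Registered genotype phenotypes for an enzyme
#'
#' @param enzyme enzyme id, e.g. `"CYP2C19"`
#' @return named numeric vector of reference concentrations (umol/L)
#' @export
phenotype_table <- function(enzyme) {
  tab <- PHENOTYPE_TABLES[[enzyme]]
  if (is.null(tab))
    stop("no phenotype table registered for ", enzyme,
         " (available: ", paste(names(PHENOTYPE_TABLES), collapse = ", "), ")")
  tab
}

## Age-dependent activity multipliers, piecewise linear in age (years).
## Default is 1 (adult) for every enzyme. GSTA1 ships an elevated childhood
## activity consistent with the faster weight-normalised busulfan clearance
## observed in children.
ONTOGENY_TABLES <- list(
  GSTA1 = list(age = c(0, 12, 120), factor = c(1.4, 1.0, 1.0))
)

#' Enzyme ontogeny factor
#'
#' Multiplicative activity factor applied to the baseline enzyme
#' concentration as a function of age. Enzymes without a shipped table
#' return 1 at all ages.
#'
#' @param enzyme enzyme id
#' @param age years
#' @export
ontogeny_factor <- function(enzyme, age) {
  tab <- ONTOGENY_TABLES[[enzyme]]
  if (is.null(tab)) return(1.0)
  stats::approx(tab$age, tab$factor, xout = age, rule = 2)$y
}
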
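## Tissue:plasma partition coefficients from lipophilicity, plasma protein
## binding and tissue composition, by the classic tissue-composition method
## (neutral lipid / phospholipid / water fractions; phospholipid treated as
## 30% lipid-like, 70% water-like). One documented method, applied uniformly
## to every compound. Ionisation is not modelled: logP stands in for the
## effective partitioning lipophilicity (logD may be supplied in its place in
## a compound file).

TISSUE_COMPOSITION <- local({
  m <- rbind(
    #                 water   neutral.lipid  phospholipid
    lung           = c(0.811, 0.0030, 0.0090),
    liver          = c(0.751, 0.0348, 0.0252),
    gut            = c(0.718, 0.0487, 0.0163),
    kidney         = c(0.783, 0.0207, 0.0162),
    muscle         = c(0.760, 0.0238, 0.0072),
    adipose        = c(0.180, 0.7900, 0.0020),
    skin           = c(0.718, 0.0284, 0.0111),
    brain          = c(0.770, 0.0392, 0.0533),
    heart          = c(0.758, 0.0115, 0.0166),
    bone           = c(0.439, 0.0740, 0.0011),
    spleen         = c(0.788, 0.0201, 0.0198),
    rest           = c(0.760, 0.0400, 0.0100),
    plasma         = c(0.945, 0.0035, 0.00225)
  )
  colnames(m) <- c("water", "nl", "ph")
  m
})

#' Tissue:plasma partition coefficients
#'
#' Computes a Kp for every tissue compartment from `logP` and `fu` using the
#' shipped tissue-composition table. Blood pools are assigned the
#' blood:plasma ratio so that outflow concentrations are handled uniformly by
#' the engine.
#'
#' @param logp partitioning lipophilicity (log10)
#' @param fu fraction unbound in plasma (0-1)
#' @param bp blood:plasma concentration ratio
#' @return named numeric vector over the 14 organ compartments
#' @export
compute_kp <- function(logp, fu, bp = 1) {
  stopifnot(fu > 0, fu <= 1, bp > 0)
  P <- 10^logp
  tis <- TISSUE_COMPOSITION
  lip <- function(row) P * (row["nl"] + 0.3 * row["ph"]) +
                       (row["water"] + 0.7 * row["ph"])
  denom <- lip(tis["plasma", ])
  ## tissue binding approximated from plasma binding (tissue macromolecule
  ## concentration ~ half of plasma's)
  fut <- 1 / (1 + 0.5 * (1 - fu) / fu)
  kp <- setNames(numeric(length(ORGAN_NAMES)), ORGAN_NAMES)
  for (o in setdiff(ORGAN_NAMES, c("arterial_blood", "venous_blood")))
    kp[o] <- unname(lip(tis[o, ]) / denom * (fu / fut))
  kp["arterial_blood"] <- bp
  kp["venous_blood"] <- bp
  kp
}
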
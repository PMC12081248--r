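## Reference physiology: organ volumes and regional blood-flow fractions for
## a 73 kg adult male, curated from standard reference-human compilations.
## Volumes scale linearly with body weight; cardiac output and all regional
## flows scale with weight^0.75 (classic allometry), which makes flow per kg
## higher in children than in adults.

REF_WEIGHT <- 73    # kg
REF_CO     <- 360   # L/h (6 L/min)

## volumes (L) at 73 kg
REF_VOLUMES <- c(lung = 0.50, liver = 1.80, gut = 1.10, kidney = 0.31,
                 muscle = 29.0, adipose = 18.2, skin = 3.30, brain = 1.45,
                 heart = 0.33, bone = 10.5, spleen = 0.15, rest = 2.40,
                 arterial_blood = 1.70, venous_blood = 3.90)

## fractions of cardiac output; hepatic artery listed separately, the liver's
## total outflow is artery + portal (gut + spleen). Fractions sum to 1.
FLOW_FRACTIONS <- c(hepatic_artery = 0.065, gut = 0.16, spleen = 0.03,
                    kidney = 0.19, muscle = 0.17, adipose = 0.05,
                    skin = 0.05, brain = 0.12, heart = 0.04, bone = 0.05,
                    rest = 0.075)

## adult mean anthropometrics by demographic label
ETHNICITY_DEFAULTS <- list(
  European = list(male = c(weight = 73, height = 176),
                  female = c(weight = 60, height = 163)),
  Japanese = list(male = c(weight = 57, height = 165),
                  female = c(weight = 51, height = 157))
)

ref_anthropometrics <- function(ethnicity, sex) {
  eth <- ETHNICITY_DEFAULTS[[ethnicity]] %||% ETHNICITY_DEFAULTS[["European"]]
  eth[[sex]]
}

#' Build a virtual individual
#'
#' Constructs a complete organ-scale physiology (14 compartments, flows
#' conserving cardiac output) together with the baseline enzyme/transporter
#' states from [enzyme_registry()], with ontogeny factors applied for the
#' given age. Defaults describe a 30-year-old European male with reference
#' mean weight and height.
#'
#' @param age years (> 0)
#' @param weight kg; default is the demographic reference mean
#' @param height cm; default is the demographic reference mean
#' @param sex `"male"` or `"female"`
#' @param ethnicity demographic label (`"European"`, `"Japanese"`, ...)
#' @return an `individual_physiology` object
#' @examples
#' ind <- build_individual()
#' ind$cardiac_output
#' @export
build_individual <- function(age = 30, weight = NULL, height = NULL,
                             sex = c("male", "female"),
                             ethnicity = "European") {
  sex <- match.arg(sex)
  assert_scalar_pos(age, "age")
  ref <- ref_anthropometrics(ethnicity, sex)
  weight <- weight %||% unname(ref["weight"])
  height <- height %||% unname(ref["height"])
  assert_scalar_pos(weight, "weight")
  assert_scalar_pos(height, "height")

  wf  <- weight / REF_WEIGHT
  co  <- REF_CO * wf^0.75
  vol <- REF_VOLUMES * wf

  flow <- setNames(numeric(length(ORGAN_NAMES)), ORGAN_NAMES)
  for (o in setdiff(names(FLOW_FRACTIONS), "hepatic_artery"))
    flow[o] <- FLOW_FRACTIONS[[o]] * co
  ## liver total perfusion = hepatic artery + portal inflow from gut + spleen
  flow["liver"] <- (FLOW_FRACTIONS[["hepatic_artery"]] +
                    FLOW_FRACTIONS[["gut"]] +
                    FLOW_FRACTIONS[["spleen"]]) * co
  flow["lung"] <- co            # pulmonary flow = cardiac output
  flow["arterial_blood"] <- 0   # blood pools route flow
  flow["venous_blood"] <- 0

  organs <- data.frame(name = ORGAN_NAMES,
                       volume = unname(vol[ORGAN_NAMES]),
                       blood_flow = unname(flow[ORGAN_NAMES]),
                       stringsAsFactors = FALSE)

  reg <- enzyme_registry()
  enzyme_states <- lapply(seq_len(nrow(reg)), function(i) {
    e0 <- reg$E0[i] * ontogeny_factor(reg$enzyme[i], age)
    list(enzyme = reg$enzyme[i], E0 = e0, E = e0, kdeg = reg$kdeg[i],
         expressing_organs = enzyme_organ_weights(reg$enzyme[i]))
  })
  names(enzyme_states) <- reg$enzyme

  ind <- structure(list(age = age, weight = weight, height = height,
                        sex = sex, ethnicity = ethnicity,
                        cardiac_output = co,
                        hepatic_artery_flow = FLOW_FRACTIONS[["hepatic_artery"]] * co,
                        organs = organs, enzyme_states = enzyme_states),
                   class = "individual_physiology")
  validate_individual(ind)
  ind
}

#' Validate an individual's physiology
#'
#' Checks the structural invariants: systemic organ flows sum to cardiac
#' output (venous return conservation, relative tolerance 1e-9), all volumes
#' and the pulmonary flow positive, and total volume within 5% of the body
#' volume implied by weight at density 1 kg/L.
#'
#' @param ind individual
#' @return the individual, invisibly; errors on violation
#' @export
validate_individual <- function(ind) {
  org <- ind$organs
  if (any(org$volume <= 0)) stop("non-positive organ volume")
  if (any(org$blood_flow < 0)) stop("negative organ blood flow")
  systemic <- setdiff(ORGAN_NAMES, c("lung", "gut", "spleen",
                                     "arterial_blood", "venous_blood"))
  ret <- sum(org$blood_flow[org$name %in% systemic])
  if (abs(ret - ind$cardiac_output) > 1e-9 * ind$cardiac_output)
    stop("venous return (", ret, ") != cardiac output (", ind$cardiac_output, ")")
  lung_q <- org$blood_flow[org$name == "lung"]
  if (abs(lung_q - ind$cardiac_output) > 1e-9 * ind$cardiac_output)
    stop("pulmonary flow != cardiac output")
  if (sum(org$volume) > ind$weight * 1.05)
    stop("organ volumes exceed body volume by more than 5%")
  for (es in ind$enzyme_states) {
    if (es$E < 0 || es$E0 < 0 || es$kdeg <= 0)
      stop("invalid enzyme state for ", es$enzyme)
    if (abs(sum(es$expressing_organs) - 1) > 1e-9)
      stop("expression weights for ", es$enzyme, " do not sum to 1")
  }
  invisible(ind)
}

#' @export
print.individual_physiology <- function(x, ...) {
  cat(sprintf("<individual_physiology> %s %s, %g y, %g kg, %g cm\n",
              x$ethnicity, x$sex, x$age, x$weight, x$height))
  cat(sprintf("  cardiac output %.1f L/h, hepatic blood flow %.1f L/h\n",
              x$cardiac_output, hepatic_blood_flow(x)))
  invisible(x)
}

#' Hepatic blood flow of an individual
#'
#' Total liver perfusion (hepatic artery + portal vein), L/h.
#' @param ind individual
#' @export
hepatic_blood_flow <- function(ind) {
  ind$organs$blood_flow[ind$organs$name == "liver"]
}

organ_volume <- function(ind, organ) {
  ind$organs$volume[ind$organs$name == organ]
}

#' Assign a genotype phenotype to an enzyme
#'
#' Replaces the enzyme's baseline and current pool concentration with the
#' phenotype's reference value (e.g. CYP2C19 NM/IM/PM at 0.76/0.40/0.01
#' umol/L; CYP3A5 expresser/non-expresser at 0.68/0.04 umol/L). All other
#' fields are untouched; applying the same phenotype twice is a no-op.
#'
#' @param ind individual
#' @param enzyme enzyme id with a registered phenotype table
#' @param phenotype phenotype label
#' @return modified individual
#' @export
set_enzyme_phenotype <- function(ind, enzyme, phenotype) {
  tab <- phenotype_table(enzyme)
  if (!phenotype %in% names(tab))
    stop("unknown phenotype '", phenotype, "' for ", enzyme,
         "; valid labels: ", paste(names(tab), collapse = ", "))
  es <- ind$enzyme_states[[enzyme]]
  if (is.null(es)) stop("enzyme ", enzyme, " not present in individual")
  es$E0 <- unname(tab[[phenotype]])
  es$E <- es$E0
  es$phenotype <- phenotype
  ind$enzyme_states[[enzyme]] <- es
  ind
}
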
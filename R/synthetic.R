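## Synthetic-data generators: noisy observed-like PK datasets with known
## ground truth (stand-ins for digitized literature profiles), plus the
## printed-value fixtures used by the report-arithmetic checks. Every fixture
## number carries a source anchor string so provenance stays machine-checkable.

#' Generate a noisy observed-like concentration-time dataset
#'
#' Simulates the truth compound under the given regimen with the PBPK
#' engine, samples it at the requested times, and applies multiplicative
#' log-normal noise (`sdlog = cv`). The sidecar truth record makes the
#' dataset usable for parameter-recovery experiments.
#'
#' @param compound a `compound_record` (the generating truth)
#' @param reg a `regimen`
#' @param times sampling times, h
#' @param cv multiplicative noise CV (log-SD); 0 gives the noise-free truth
#' @param n_subjects independent noisy replicates of the profile
#' @param seed integer seed
#' @param individual physiology (default reference adult)
#' @param unit concentration unit of the dataset
#' @param dt simulation output step, h
#' @return list: `dataset` (an [observed_dataset()], with an `arm` per
#'   subject), `truth` (compound record), `truth_profile`, `result`
#' @export
generate_observed_profile <- function(compound, reg, times, cv = 0.1,
                                      n_subjects = 1, seed = 1,
                                      individual = build_individual(),
                                      unit = "ng/mL", dt = 0.25) {
  stopifnot(cv >= 0, n_subjects >= 1)
  sys <- assemble_model(individual, compound)
  t_end <- max(times)
  res <- simulate_system(sys, reg, t_end = t_end, dt = dt)
  truth <- stats::approx(res$time,
                         plasma_concentration(res, compound$name, unit),
                         xout = times, rule = 2)$y
  noisy <- with_seed(seed, {
    lapply(seq_len(n_subjects), function(s)
      truth * exp(stats::rnorm(length(times), 0, cv)))
  })
  ds <- do.call(rbind, lapply(seq_len(n_subjects), function(s)
    data.frame(time_h = times, conc = noisy[[s]], unit = unit,
               arm = sprintf("subject%02d", s), source = "synthetic",
               stringsAsFactors = FALSE)))
  list(dataset = structure(ds, class = c("observed_dataset", "data.frame")),
       truth = compound, truth_profile = truth, result = res)
}

#' Printed cyclosporine DDI table fixture
#'
#' The twelve published rows of simulated cyclosporine day-6 trough
#' concentrations (mean +/- SD, ng/mL) with different perpetrators, and the
#' published rounded Cmin ratio column. These are report fixtures for the
#' ratio-arithmetic checks, not simulation targets.
#'
#' @return data.frame with columns `victim_regimen`, `perpetrator`,
#'   `cmin_mean`, `cmin_sd`, `printed_ratio`, `baseline`, `anchor`
#' @export
table2_fixture <- function() {
  d <- data.frame(
    victim_regimen = c(rep("cyclosporine 100 mg po bid", 11),
                       "cyclosporine 150 mg po bid"),
    perpetrator = c(
      "none",
      "phenytoin 100 mg po tid",
      "letermovir 240 mg po qd",
      "fluconazole 200 mg po qd",
      "posaconazole 200 mg po tid",
      "itraconazole 200 mg po qd",
      "voriconazole 200 mg po bid (CYP2C19 NM)",
      "voriconazole 200 mg po bid (CYP2C19 IM)",
      "voriconazole 200 mg po bid (CYP2C19 PM)",
      "voriconazole (NM) + letermovir",
      "voriconazole (NM) + letermovir + phenytoin day -5 to -1",
      "voriconazole (NM) + letermovir + phenytoin day -5 to -1"),
    cmin_mean = c(104.9, 82.7, 126.3, 169.2, 208.6, 215.2, 233.8, 327.7,
                  422.7, 240.6, 173.1, 261.3),
    cmin_sd = c(32.2, 26.1, 49.7, 67.6, 113.1, 119.1, 147.7, 193.3, 227.2,
                124.6, 76.3, 109.7),
    printed_ratio = c(NA, 0.8, 1.2, 1.6, 2.0, 2.1, 2.2, 3.1, 4.0, 2.3,
                      1.7, 2.5),
    stringsAsFactors = FALSE)
  d$baseline <- seq_len(nrow(d)) == 1L
  d$anchor <- "Table 2"
  d
}

#' Printed dose-optimization discussion fixture
#'
#' Published busulfan exposures (uM*min), cyclosporine trough fold-changes
#' with five different azole/antiviral perpetrators, and percent decreases
#' under phenytoin coadministration, each with its source anchor.
#'
#' @return nested list of printed values
#' @export
discussion_fixture <- function() {
  list(
    busulfan = list(
      child_alone_08 = list(value = 979.4, sd = 76.2, unit = "uM.min",
                            anchor = "Discussion: pediatric busulfan 0.8 mg/kg"),
      child_phenytoin_08 = list(value = 847.9, sd = 68.4, unit = "uM.min",
                                anchor = "Discussion: + phenytoin"),
      child_alone_10 = list(value = 1060.7, sd = 95.5, unit = "uM.min",
                            anchor = "Discussion: 1.0 mg/kg"),
      adult_alone_08 = list(value = 1078.8, sd = 103.9, unit = "uM.min",
                            anchor = "Discussion: adults 0.8 mg/kg"),
      window = list(lower = 900, upper = 1350, unit = "uM.min",
                    anchor = "therapeutic target")),
    cyclosporine_cmin_fold_changes = list(
      values = c(voriconazole = 2.2, itraconazole = 2.1, posaconazole = 2.0,
                 fluconazole = 1.6, letermovir = 1.2),
      anchor = "Results: cyclosporine Cmin fold change by perpetrator"),
    phenytoin_percent_decreases = list(
      values = c(cyclosporine_cmin = 21.1, aprepitant_auc = 36.9,
                 fosaprepitant_auc = 8.5, busulfan_auc = 13.4,
                 voriconazole_cmin = 51.0),
      anchor = "Results: percent decrease under phenytoin"),
    cyclosporine_triple = list(
      without_phenytoin = 240.6, with_phenytoin = 173.1,
      dose_150 = 261.3, unit = "ng/mL",
      anchor = "Discussion: triple combination day-6 troughs")
  )
}
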
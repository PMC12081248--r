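#' Pharmacokinetic metrics over an interval
#'
#' AUC by trapezoid on the output grid, Cmax as the interval maximum, and
#' Cmin as the concentration at the interval end (the trough convention:
#' evaluate at the end of a dosing interval). Unit conversions are explicit;
#' `auc_unit = "uM.min"` gives AUC in micromolar-minutes regardless of
#' `conc_unit` (busulfan exposure convention).
#'
#' @param result a `simulation_result`
#' @param compound compound name
#' @param interval_start,interval_end interval bounds, h (must lie within the
#'   simulated range)
#' @param conc_unit concentration unit for Cmax/Cmin and default AUC
#' @param auc_unit `NULL` (AUC in `conc_unit * h`) or `"uM.min"`
#' @param extrapolate if `TRUE`, add the log-linear tail `C_last/k` beyond
#'   `interval_end` (AUC to infinity for single-dose profiles)
#' @return a `pk_metrics` list: `auc`, `cmax`, `cmin`, units, interval
#' @export
compute_pk_metrics <- function(result, compound = names(result$compounds)[1],
                               interval_start = 0,
                               interval_end = max(result$time),
                               conc_unit = "ng/mL", auc_unit = NULL,
                               extrapolate = FALSE) {
  if (interval_end <= interval_start) stop("empty interval")
  conc <- plasma_concentration(result, compound, conc_unit)
  tt <- result$time
  auc <- auc_interval(tt, conc, interval_start, interval_end)
  sel <- tt >= interval_start & tt <= interval_end
  cmax <- max(conc[sel])
  cmin <- stats::approx(tt, conc, xout = interval_end, rule = 2)$y
  if (extrapolate) {
    ## terminal slope from the last decade of the interval
    tail_sel <- which(sel & conc > 0 & tt >= interval_start +
                        0.8 * (interval_end - interval_start))
    if (length(tail_sel) >= 3) {
      fit <- stats::lm(log(conc[tail_sel]) ~ tt[tail_sel])
      k <- -unname(stats::coef(fit)[2])
      if (k > 0) auc <- auc + cmin / k
    }
  }
  auc_out_unit <- paste0(conc_unit, "*h")
  if (identical(auc_unit, "uM.min")) {
    um <- convert_conc(conc, conc_unit, "umol/L",
                       result$compounds[[compound]]$mw)
    auc <- auc_interval(tt, um, interval_start, interval_end) * 60
    if (extrapolate) {
      cmin_um <- convert_conc(cmin, conc_unit, "umol/L",
                              result$compounds[[compound]]$mw)
      tail_sel <- which(sel & conc > 0 & tt >= interval_start +
                          0.8 * (interval_end - interval_start))
      if (length(tail_sel) >= 3) {
        fit <- stats::lm(log(um[tail_sel]) ~ tt[tail_sel])
        k <- -unname(stats::coef(fit)[2])
        if (k > 0) auc <- auc + cmin_um / k * 60
      }
    }
    auc_out_unit <- "uM.min"
  }
  structure(list(auc = auc, cmax = cmax, cmin = cmin,
                 conc_unit = conc_unit, auc_unit = auc_out_unit,
                 interval = c(interval_start, interval_end),
                 compound = compound),
            class = "pk_metrics")
}

#' @export
print.pk_metrics <- function(x, ...) {
  cat(sprintf("<pk_metrics> %s over %g-%g h: AUC %.4g %s, Cmax %.4g, Cmin %.4g %s\n",
              x$compound, x$interval[1], x$interval[2], x$auc, x$auc_unit,
              x$cmax, x$cmin, x$conc_unit))
  invisible(x)
}

#' Detect steady state by successive interval AUCs
#'
#' Flags steady state at the first dosing interval whose AUC differs from
#' the previous interval's by less than `threshold` (relative).
#'
#' @param result a `simulation_result`
#' @param compound compound name
#' @param interval dosing interval, h
#' @param threshold relative change below which steady state is declared
#' @param start time of the first dose, h
#' @return list: `reached`, `interval_index` (1-based, NA if never),
#'   `time` (start of the flagged interval), `auc_ratio_trace`
#' @export
steady_state <- function(result, compound = names(result$compounds)[1],
                         interval, threshold = 0.01, start = 0) {
  tt <- result$time
  conc <- plasma_concentration(result, compound, "umol/L")
  n_int <- floor((max(tt) - start) / interval)
  if (n_int < 2) stop("need at least two dosing intervals")
  aucs <- vapply(seq_len(n_int), function(k)
    auc_interval(tt, conc, start + (k - 1) * interval, start + k * interval), 0)
  rel <- abs(diff(aucs)) / aucs[-length(aucs)]
  hit <- which(rel < threshold)
  list(reached = length(hit) > 0,
       interval_index = if (length(hit)) hit[1] + 1L else NA_integer_,
       time = if (length(hit)) start + hit[1] * interval else NA_real_,
       auc_ratio_trace = rel)
}

#' Mass balance of a simulation
#'
#' Verifies, at every output time, that the cumulative dosed amount equals
#' the amount in all compartments plus cumulative elimination, plus the
#' analytically known not-yet-released (Weibull), still-infusing, and
#' never-dissolvable portions. Prodrug pairs are balanced jointly.
#'
#' @param result a `simulation_result`
#' @return list with `max_rel_error` and a per-group trace data.frame
#' @export
mass_balance <- function(result) {
  sys <- result$system
  tt <- result$time
  ## balance groups: prodrug source grouped with its target
  groups <- list()
  assigned <- character()
  for (nm in names(sys$compounds)) {
    pr <- sys$compounds[[nm]]$record$prodrug
    if (!is.null(pr)) {
      groups[[nm]] <- c(nm, pr$target)
      assigned <- c(assigned, nm, pr$target)
    }
  }
  for (nm in setdiff(names(sys$compounds), assigned)) groups[[nm]] <- nm

  traces <- list()
  max_err <- 0
  for (g in names(groups)) {
    dosed <- numeric(length(tt))
    locked <- numeric(length(tt))  # unreleasable + unreleased + pending infusion
    in_body <- numeric(length(tt))
    elim <- numeric(length(tt))
    for (nm in groups[[g]]) {
      cp <- sys$compounds[[nm]]
      cols <- paste0(nm, ".", c(ORGAN_NAMES, "lumen"))
      in_body <- in_body + rowSums(result$amounts[, cols, drop = FALSE])
      elim <- elim + result$amounts[, paste0(nm, ".elim_met")] +
                     result$amounts[, paste0(nm, ".elim_ren")]
      acc <- result$dosing[[nm]]$accounting
      if (is.null(acc)) next
      for (i in seq_len(nrow(acc))) {
        ## output rows at an event time report the pre-event state
        given <- tt > acc$time[i] + 1e-12
        dosed <- dosed + given * acc$nominal[i]
        if (acc$kind[i] %in% c("first_order", "weibull"))
          locked <- locked + given * acc$nominal[i] * (1 - acc$f_eff[i])
        if (acc$kind[i] == "weibull")
          locked <- locked + given * acc$nominal[i] * acc$f_eff[i] *
            (1 - weibull_release(tt - acc$time[i], acc$shape[i], acc$scale[i]))
        if (acc$kind[i] == "iv_infusion")
          locked <- locked + given * acc$nominal[i] *
            pmax(0, 1 - (tt - acc$time[i]) / acc$duration[i])
      }
    }
    denom <- pmax(dosed, max(dosed) * 1e-6)
    rel <- ifelse(dosed > 0, abs(dosed - in_body - elim - locked) / denom, 0)
    traces[[g]] <- data.frame(time = tt, group = g, dosed = dosed,
                              in_body = in_body, eliminated = elim,
                              locked = locked, rel_error = rel)
    max_err <- max(max_err, rel)
  }
  list(max_rel_error = max_err, trace = do.call(rbind, traces))
}

#' Export a simulation to long-format data
#'
#' @param result a `simulation_result`
#' @param compound compound name
#' @param unit concentration unit for the plasma column
#' @return data.frame: time, compartment, value (amount umol; plasma row in
#'   `unit`), unit
#' @export
simulation_to_long <- function(result, compound = names(result$compounds)[1],
                               unit = "ng/mL") {
  amt <- result$amounts[, paste0(compound, ".", ORGAN_NAMES), drop = FALSE]
  long <- data.frame(
    time = rep(result$time, times = ncol(amt)),
    compartment = rep(ORGAN_NAMES, each = length(result$time)),
    value = as.vector(amt), unit = "umol")
  plasma <- data.frame(time = result$time, compartment = "venous_plasma",
                       value = plasma_concentration(result, compound, unit),
                       unit = unit)
  rbind(long, plasma)
}
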
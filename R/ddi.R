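#' DDI ratio
#'
#' Victim exposure during coadministration divided by exposure alone
#' (AUC, Cmax or Cmin, consistently). The raw ratio is returned; reporting
#' tables round half-away-from-zero to one decimal.
#'
#' @param value_combo victim metric during coadministration (> 0)
#' @param value_alone victim metric alone (> 0)
#' @return raw ratio
#' @export
ddi_ratio <- function(value_combo, value_alone) {
  if (any(value_alone <= 0) || any(value_combo <= 0))
    stop("DDI ratio needs positive exposures")
  value_combo / value_alone
}

#' Signed percent change of a victim metric
#'
#' `100 * (combo - alone) / alone`; negative for induction-driven decreases.
#'
#' @param value_alone baseline metric (> 0)
#' @param value_combo metric during coadministration
#' @export
percent_change <- function(value_alone, value_combo) {
  if (any(value_alone <= 0)) stop("baseline must be positive")
  100 * (value_combo - value_alone) / value_alone
}

#' Two-fold acceptance check
#'
#' Predicted/observed ratio with the conventional acceptance window
#' \[0.5, 2.0\], inclusive at both ends.
#'
#' @param predicted predicted metric (> 0)
#' @param observed observed metric (> 0)
#' @return data.frame with `ratio` and logical `pass`
#' @export
evaluate_twofold <- function(predicted, observed) {
  if (any(observed <= 0)) stop("observed values must be positive")
  if (any(predicted <= 0)) stop("predicted values must be positive")
  ratio <- predicted / observed
  data.frame(ratio = ratio, pass = ratio >= 0.5 & ratio <= 2.0)
}

#' Variability-scaled (Guest) acceptance limits
#'
#' For an observed DDI ratio `R >= 1` the acceptance band is
#' `(R/L, R*L)` with `L = (delta + 2*(R - 1))/R`; at `R = 1` this gives the
#' (0.8, 1.25) band for the default `delta = 1.25`, widening as the
#' interaction grows (`delta = 2` recovers \[0.5, 2\] at `R = 1`). For `R < 1` the same formula is applied
#' to `1/R` and the limits inverted, so the band is symmetric under
#' reciprocal (induction mirrors inhibition).
#'
#' @param r_obs observed DDI ratio (> 0)
#' @param delta variability factor (>= 1)
#' @return numeric length-2: lower and upper acceptance limit on the
#'   predicted ratio
#' @export
guest_limits <- function(r_obs, delta = 1.25) {
  if (r_obs <= 0) stop("r_obs must be > 0")
  if (delta < 1) stop("delta must be >= 1")
  lim_ge1 <- function(r) {
    L <- (delta + 2 * (r - 1)) / r
    c(r / L, r * L)
  }
  if (r_obs >= 1) lim_ge1(r_obs)
  else {
    l <- lim_ge1(1 / r_obs)
    sort(1 / l)
  }
}

#' Guest-criterion check of a predicted ratio
#'
#' @param r_pred predicted DDI ratio
#' @param r_obs observed DDI ratio
#' @param delta variability factor
#' @return logical
#' @export
guest_pass <- function(r_pred, r_obs, delta = 1.25) {
  lim <- guest_limits(r_obs, delta)
  r_pred >= lim[1] & r_pred <= lim[2]
}

#' DDI scenario report table
#'
#' Builds the standard victim-regimen by perpetrator-set report: mean +/- SD
#' of the metric, the DDI ratio against the baseline row rounded
#' half-away-from-zero to one decimal (raw value retained), and -- when
#' observed ratios are supplied -- the two-fold and Guest verdicts. Ratios
#' landing exactly on the 0.05 rounding boundary are flagged.
#'
#' @param results data.frame with columns `label`, `mean`, `sd` (optional),
#'   and logical `baseline` marking the victim-alone row (defaults to the
#'   first row)
#' @param observed optional data.frame with columns `label`, `r_obs`
#' @param delta Guest variability factor
#' @param digits decimals for the reported ratio
#' @return data.frame report
#' @export
ddi_report <- function(results, observed = NULL, delta = 1.25, digits = 1) {
  stopifnot(is.data.frame(results), nrow(results) >= 1,
            all(c("label", "mean") %in% names(results)))
  base_row <- if ("baseline" %in% names(results)) which(results$baseline)[1] else 1L
  base <- results$mean[base_row]
  out <- data.frame(label = results$label,
                    mean = results$mean,
                    sd = if ("sd" %in% names(results)) results$sd else NA_real_,
                    stringsAsFactors = FALSE)
  raw <- ifelse(seq_len(nrow(results)) == base_row, NA_real_,
                ddi_ratio(results$mean, base))
  out$ratio_raw <- raw
  out$ratio <- round_half_away(raw, digits)
  out$rounding_tie <- !is.na(raw) & at_rounding_tie(raw, digits)
  if (!is.null(observed)) {
    m <- match(out$label, observed$label)
    out$r_obs <- observed$r_obs[m]
    out$twofold_pass <- ifelse(is.na(out$r_obs) | is.na(raw), NA,
                               raw / out$r_obs >= 0.5 & raw / out$r_obs <= 2)
    out$guest_pass <- NA
    for (i in seq_len(nrow(out)))
      if (!is.na(out$r_obs[i]) && !is.na(raw[i]))
        out$guest_pass[i] <- guest_pass(raw[i], out$r_obs[i], delta)
  }
  out
}
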
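#' Construct a dosing regimen
#'
#' A regimen is an expanded table of dose events. Doses of 0 are dropped, so
#' `regimen(0)` is the explicit zero-dose (placebo) regimen.
#'
#' @param dose dose per event, mg (or mg/kg when `mg_per_kg = TRUE`;
#'   resolved against the individual's weight at assembly)
#' @param route `"oral"`, `"iv_bolus"` or `"iv_infusion"`
#' @param times explicit event times (h); overrides `start`/`interval`/`n`
#' @param start first dose time (h)
#' @param interval dosing interval (h)
#' @param n number of doses
#' @param duration infusion duration (h), `iv_infusion` only
#' @param formulation formulation label resolved against the compound file
#' @param fed logical; apply the formulation's fed-state modifiers
#' @param mg_per_kg logical; interpret `dose` as mg/kg
#' @return a `regimen` object
#' @export
regimen <- function(dose, route = c("oral", "iv_bolus", "iv_infusion"),
                    times = NULL, start = 0, interval = 24, n = 1,
                    duration = NULL, formulation = "default", fed = FALSE,
                    mg_per_kg = FALSE) {
  route <- match.arg(route)
  if (any(dose < 0)) stop("doses must be >= 0")
  if (is.null(times)) times <- start + (seq_len(n) - 1) * interval
  if (route == "iv_infusion") {
    if (is.null(duration) || duration <= 0)
      stop("iv_infusion requires duration > 0")
  } else duration <- NA_real_
  ev <- data.frame(time = times,
                   dose = rep_len(dose, length(times)),
                   route = route, duration = duration,
                   formulation = formulation, fed = fed,
                   mg_per_kg = mg_per_kg,
                   stringsAsFactors = FALSE)
  ev <- ev[ev$dose > 0, , drop = FALSE]
  ev <- ev[order(ev$time), , drop = FALSE]
  structure(list(events = ev), class = "regimen")
}

#' Calendar-day regimen
#'
#' Evenly spaced doses on each calendar day from `start_day` to `stop_day`
#' inclusive (`per_day` doses, the first at 00:00 of the day). Day numbers
#' follow the transplant convention: day 0 is the first day of the victim
#' course, negative days are pre-transplant conditioning.
#'
#' @inheritParams regimen
#' @param per_day doses per day (1 = qd, 2 = bid, 3 = tid)
#' @param start_day,stop_day first and last calendar day (integers, may be
#'   negative)
#' @export
daily_regimen <- function(dose, per_day = 1, start_day = 0, stop_day = 0,
                          route = "oral", formulation = "default",
                          fed = FALSE, mg_per_kg = FALSE) {
  if (stop_day < start_day) stop("stop_day must be >= start_day")
  days <- seq(start_day, stop_day)
  times <- as.vector(outer((seq_len(per_day) - 1) * (24 / per_day),
                           days * 24, `+`))
  regimen(dose, route = route, times = sort(times),
          formulation = formulation, fed = fed, mg_per_kg = mg_per_kg)
}

#' Merge regimens for one compound
#' @param ... regimen objects
#' @export
merge_regimens <- function(...) {
  evs <- do.call(rbind, lapply(list(...), `[[`, "events"))
  evs <- evs[order(evs$time), , drop = FALSE]
  structure(list(events = evs), class = "regimen")
}

#' Shift all dose times by a constant offset
#' @param reg regimen
#' @param offset_h hours to add
#' @export
shift_regimen <- function(reg, offset_h) {
  reg$events$time <- reg$events$time + offset_h
  reg
}

#' @export
print.regimen <- function(x, ...) {
  ev <- x$events
  if (!nrow(ev)) { cat("<regimen> zero-dose\n"); return(invisible(x)) }
  cat(sprintf("<regimen> %d dose(s), %s, %g-%g h\n", nrow(ev),
              paste(unique(ev$route), collapse = "/"),
              min(ev$time), max(ev$time)))
  invisible(x)
}
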
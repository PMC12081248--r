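#' @keywords internal
"_PACKAGE"

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Trapezoidal area under a curve
#'
#' Plain trapezoid rule on an ordered grid; the workhorse behind all AUC
#' calculations in the package.
#'
#' @param x ordered abscissae
#' @param y values at `x`
#' @return scalar area
#' @keywords internal
trapz <- function(x, y) {
  n <- length(x)
  if (n < 2L) return(0)
  sum((y[-1] + y[-n]) * diff(x)) / 2
}

## AUC over [start, end], interpolating the interval ends onto the grid.
auc_interval <- function(time, value, start, end) {
  if (end <= start) stop("empty interval: end must exceed start")
  if (start < min(time) - 1e-9 || end > max(time) + 1e-9)
    stop("interval [", start, ", ", end, "] outside simulated range")
  inside <- time > start & time < end
  xs <- c(start, time[inside], end)
  ys <- c(stats::approx(time, value, xout = start, rule = 2)$y,
          value[inside],
          stats::approx(time, value, xout = end, rule = 2)$y)
  trapz(xs, ys)
}

#' Round half away from zero
#'
#' Reporting convention for DDI ratio tables (1.65 -> 1.7, -1.65 -> -1.7),
#' unlike [base::round()]'s round-half-even.
#'
#' @param x numeric
#' @param digits decimal places
#' @export
round_half_away <- function(x, digits = 1) {
  p <- 10^digits
  sign(x) * floor(abs(x) * p + 0.5) / p
}

## TRUE when x*10^digits sits exactly on the .5 rounding boundary.
at_rounding_tie <- function(x, digits = 1, eps = 1e-9) {
  f <- abs(x) * 10^digits
  abs(f - floor(f) - 0.5) < eps
}

#' Evaluate code with a temporary RNG seed
#'
#' Restores the caller's `.Random.seed` on exit so seeded sampling inside the
#' package never perturbs the user's RNG stream.
#'
#' @param seed integer seed
#' @param code expression
#' @export
with_seed <- function(seed, code) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(code)
}

## Derived per-individual stream seed (kept below 2^31).
stream_seed <- function(seed, index) {
  as.integer((as.numeric(seed) + as.numeric(index) * 9973) %% 2147483647)
}

#' Convert a concentration between units
#'
#' Supported units: `"umol/L"` (micromolar), `"ng/mL"`, `"ug/mL"`, `"mg/L"`
#' (same as ug/mL). Molecular weight is required whenever mass and molar
#' units are mixed.
#'
#' @param value numeric concentrations
#' @param from,to unit strings
#' @param mw molecular weight, g/mol
#' @export
convert_conc <- function(value, from, to, mw = NULL) {
  canon <- function(u) {
    u <- gsub("µ", "u", u)
    switch(u,
      "uM" = "umol/L", "umol/L" = "umol/L",
      "ng/mL" = "ng/mL", "ug/mL" = "ug/mL", "mg/L" = "ug/mL",
      stop("unknown concentration unit: ", u))
  }
  from <- canon(from); to <- canon(to)
  if (from == to) return(value)
  need_mw <- (from == "umol/L") != (to == "umol/L")
  if (need_mw && is.null(mw)) stop("molecular weight needed to convert ", from, " to ", to)
  ## route through umol/L
  um <- switch(from,
    "umol/L" = value,
    "ng/mL"  = value / mw,        # ng/mL = ug/L; /mw g/mol -> umol/L
    "ug/mL"  = value * 1000 / mw)
  switch(to,
    "umol/L" = um,
    "ng/mL"  = um * mw,
    "ug/mL"  = um * mw / 1000)
}

mg_to_umol <- function(mg, mw) mg / mw * 1000

assert_scalar_pos <- function(x, name, strict = TRUE) {
  if (!is.numeric(x) || length(x) != 1L || is.na(x) ||
      (strict && x <= 0) || (!strict && x < 0))
    stop("'", name, "' must be a ", if (strict) "positive" else "non-negative",
         " number", call. = FALSE)
  invisible(x)
}
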
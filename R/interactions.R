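## Interaction mechanisms: the five reversible inhibition types,
## mechanism-based inactivation (MBI), and Emax/EC50 induction, plus the
## composition rules for multiple simultaneous perpetrators at one target.
##
## Conventions: all inhibitor/inducer driver concentrations I are unbound
## (umol/L) at the relevant site; Ki/KI/EC50 are on the same scale. For
## mixed-type inhibition `alpha` scales the uncompetitive-site constant
## (Ki' = alpha * Ki); alpha = 1 reduces mixed to non-competitive.

REVERSIBLE_TYPES <- c("competitive", "uncompetitive", "non-competitive", "mixed")

#' Construct an inhibition spec
#'
#' @param perpetrator compound name
#' @param target enzyme/transporter id
#' @param type one of `"competitive"`, `"uncompetitive"`, `"non-competitive"`,
#'   `"mixed"`, `"irreversible"`
#' @param Ki reversible inhibition constant, umol/L (reversible types)
#' @param alpha mixed-type uncompetitive-site factor (> 0)
#' @param kinact maximum inactivation rate, 1/h (irreversible)
#' @param KI inhibitor concentration at half-maximal inactivation, umol/L
#' @export
inhibition_spec <- function(perpetrator, target, type, Ki = NULL, alpha = 1,
                            kinact = NULL, KI = NULL) {
  type <- match.arg(type, c(REVERSIBLE_TYPES, "irreversible"))
  if (type == "irreversible") {
    if (is.null(kinact) || is.null(KI) || kinact <= 0 || KI <= 0)
      stop("irreversible inhibition requires kinact > 0 and KI > 0")
    spec <- list(perpetrator = perpetrator, target = target,
                 mechanism = "inhibition", type = type,
                 kinact = kinact, ki_half = KI)
  } else {
    if (is.null(Ki) || Ki <= 0) stop("reversible inhibition requires Ki > 0")
    if (alpha <= 0) stop("alpha must be > 0")
    spec <- list(perpetrator = perpetrator, target = target,
                 mechanism = "inhibition", type = type, ki = Ki,
                 alpha = alpha)
  }
  structure(spec, class = c("inhibition_spec", "interaction_spec"))
}

#' Construct an induction spec
#'
#' @param perpetrator compound name
#' @param target enzyme id
#' @param emax maximum fold-increase minus 1 of the synthesis rate (>= 0)
#' @param ec50 inducer concentration at half-maximal effect, umol/L
#' @export
induction_spec <- function(perpetrator, target, emax, ec50) {
  if (emax < 0) stop("emax must be >= 0")
  if (ec50 <= 0) stop("ec50 must be > 0")
  structure(list(perpetrator = perpetrator, target = target,
                 mechanism = "induction", emax = emax, ec50 = ec50),
            class = c("induction_spec", "interaction_spec"))
}

#' Reversible inhibition of a Michaelis-Menten rate
#'
#' Returns the inhibited rate `v = f(S, I)` for one spec, following the
#' standard forms: competitive multiplies Km by (1 + I/Ki); uncompetitive
#' divides both Vmax and Km by (1 + I/Ki); non-competitive divides Vmax by
#' (1 + I/Ki); mixed uses `v = Vmax*S / (Km*(1 + I/Ki) + S*(1 + I/(alpha*Ki)))`.
#'
#' @param S substrate concentration, umol/L
#' @param I unbound inhibitor concentration, umol/L
#' @param spec an [inhibition_spec()] of a reversible type
#' @param vmax,km uninhibited Michaelis-Menten constants
#' @return inhibited rate (same units as `vmax`)
#' @export
reversible_rate <- function(S, I, spec, vmax = 1, km = 1) {
  stopifnot(all(S >= 0), all(I >= 0))
  if (!inherits(spec, "inhibition_spec") || spec$type == "irreversible")
    stop("irreversible specs act on enzyme turnover, not on the rate equation")
  r <- I / spec$ki
  switch(spec$type,
    competitive       = vmax * S / (km * (1 + r) + S),
    uncompetitive     = (vmax / (1 + r)) * S / (km / (1 + r) + S),
    `non-competitive` = (vmax / (1 + r)) * S / (km + S),
    mixed             = vmax * S / (km * (1 + r) + S * (1 + I / (spec$alpha * spec$ki))))
}

#' Ratio of inhibited to uninhibited rate
#'
#' Convenience wrapper around [reversible_rate()]: the multiplicative factor
#' the inhibitor applies to `v = Vmax*S/(Km+S)`. Equals 1 at `I = 0`.
#'
#' @inheritParams reversible_rate
#' @export
reversible_factor <- function(S, I, spec, vmax = 1, km = 1) {
  reversible_rate(S, I, spec, vmax, km) / (vmax * S / (km + S))
}

#' Compose simultaneous perpetrators at one target
#'
#' Reduces any mixture of reversible inhibition, MBI and induction specs
#' sharing one target, at given unbound perpetrator concentrations, to the
#' net modifiers used by the engine:
#' \itemize{
#'   \item `a`: competitive-site denominator `1 + sum(I/Ki)` over competitive
#'     and mixed specs (additive within one denominator),
#'   \item `b`: uncompetitive-site denominator over uncompetitive and mixed
#'     (`I/(alpha*Ki)`) specs,
#'   \item `c`: non-competitive Vmax denominator,
#'   \item `lambda`: total inactivation hazard `sum(kinact*I/(KI+I))` (1/h),
#'   \item `induction`: total synthesis stimulus `sum(Emax*I/(EC50+I))`.
#' }
#' The inhibited saturable rate is `Vmax*S / (c * (Km*a + S*b))`; in the
#' linear range the rate factor is `1/(a*c)`.
#'
#' @param specs list of interaction specs sharing one target
#' @param I named (by perpetrator) or positional vector of unbound
#'   concentrations, umol/L
#' @return list with `a`, `b`, `c`, `lambda`, `induction`
#' @export
combine_perpetrators <- function(specs, I) {
  if (length(specs)) {
    tg <- unique(vapply(specs, `[[`, "", "target"))
    if (length(tg) != 1L) stop("specs must share one target, got: ",
                               paste(tg, collapse = ", "))
  }
  conc <- function(i, spec) {
    if (!is.null(names(I))) {
      ci <- I[[spec$perpetrator]]
      if (is.null(ci) || is.na(ci)) stop("no concentration for perpetrator ",
                                         spec$perpetrator)
      ci
    } else I[[i]]
  }
  a <- 1; b <- 1; cc <- 1; lambda <- 0; ind <- 0
  for (i in seq_along(specs)) {
    sp <- specs[[i]]
    ci <- conc(i, sp)
    stopifnot(ci >= 0)
    if (sp$mechanism == "induction") {
      ind <- ind + sp$emax * ci / (sp$ec50 + ci)
    } else if (sp$type == "irreversible") {
      lambda <- lambda + sp$kinact * ci / (sp$ki_half + ci)
    } else {
      switch(sp$type,
        competitive       = a <- a + ci / sp$ki,
        `non-competitive` = cc <- cc + ci / sp$ki,
        uncompetitive     = b <- b + ci / sp$ki,
        mixed             = { a <- a + ci / sp$ki
                              b <- b + ci / (sp$alpha * sp$ki) })
    }
  }
  list(a = a, b = b, c = cc, lambda = lambda, induction = ind)
}

#' Enzyme-pool turnover derivative
#'
#' `dE/dt = kdeg*E0*(1 + sum(Emax_j*I_j/(EC50_j+I_j)))
#'          - E*(kdeg + sum(kinact_m*I_m/(KI_m+I_m)))`.
#' At baseline (`E = E0`, no perpetrators) the pool is at steady state. Under
#' constant MBI exposure the steady state is
#' `E/E0 = kdeg/(kdeg + kinact*I/(KI+I))`; under constant induction
#' `E/E0 = 1 + Emax*I/(EC50+I)`.
#'
#' @param E current pool concentration, umol/L
#' @param E0 baseline pool concentration, umol/L
#' @param kdeg degradation rate, 1/h
#' @param mbi list of irreversible [inhibition_spec()]s
#' @param induction list of [induction_spec()]s
#' @param I named vector of unbound perpetrator concentrations, umol/L
#' @return dE/dt, umol/L/h
#' @export
enzyme_turnover_rhs <- function(E, E0, kdeg, mbi = list(), induction = list(),
                                I = numeric()) {
  m <- combine_perpetrators(c(mbi, induction), I)
  kdeg * E0 * (1 + m$induction) - E * (kdeg + m$lambda)
}

#' Unbound interaction driver concentration
#'
#' Extracts the unbound concentration time-course of a simulated perpetrator
#' at an interaction site: `fu * C_tissue/Kp` for tissue sites (the
#' plasma-equivalent unbound concentration) or `fu * C_blood/BP` for
#' `"venous_plasma"`.
#'
#' @param result a `simulation_result`
#' @param perpetrator compound name present in the result
#' @param site organ name or `"venous_plasma"`
#' @return numeric vector along `result$time`, umol/L
#' @export
interaction_driver_concentration <- function(result, perpetrator,
                                             site = "liver") {
  cp <- result$compounds[[perpetrator]]
  if (is.null(cp)) stop("perpetrator '", perpetrator, "' not in simulation")
  if (site == "venous_plasma")
    return(cp$fu * result$amounts[, paste0(perpetrator, ".venous_blood")] /
             cp$volumes[["venous_blood"]] / cp$bp)
  col <- paste0(perpetrator, ".", site)
  if (!col %in% colnames(result$amounts)) stop("site not simulated: ", site)
  cp$fu * result$amounts[, col] / cp$volumes[[site]] / cp$kp[[site]]
}
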
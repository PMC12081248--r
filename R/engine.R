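## Whole-body PBPK ODE engine.
##
## Structure: venous blood -> lung -> arterial blood -> systemic organs ->
## venous blood, with the portal chain gut/spleen -> liver. All tissues are
## perfusion-limited; amounts are tracked in umol. Elimination happens in the
## expressing organs of each clearance pathway (scaled by fu, the local
## enzyme pool E(t) and any interaction modifiers) and in the kidney for
## renal clearance. Enzyme pools become ODE states when a bound perpetrator
## carries MBI or induction specs for them; otherwise they stay static.

#' Fraction released by a Weibull dissolution profile
#'
#' `1 - exp(-(t/scale)^shape)`; monotone non-decreasing, 0 at t = 0.
#'
#' @param t time since dose, h
#' @param shape Weibull shape (beta, > 0)
#' @param scale Weibull scale (tau, h)
#' @export
weibull_release <- function(t, shape, scale) {
  stopifnot(shape > 0, scale > 0)
  ifelse(t <= 0, 0, 1 - exp(-(t / scale)^shape))
}

## release-rate density (dW/dt), guarded at t = 0 for shape < 1
weibull_flux <- function(t, shape, scale) {
  dt <- pmax(t, 1e-9)
  ifelse(t <= 0, 0,
         shape / scale * (dt / scale)^(shape - 1) * exp(-(dt / scale)^shape))
}

#' Assemble a multi-compound PBPK ODE system
#'
#' Resolves compounds against an individual's physiology and couples them
#' through their interaction specs: every spec whose perpetrator is among the
#' simulated compounds is bound to the matching enzyme state. Enzymes
#' targeted by MBI or induction become dynamic pool states.
#'
#' @param individual an `individual_physiology`
#' @param compounds a `compound_record` or list of them
#' @param interactions `TRUE` (bind all specs of the included compounds) or
#'   `FALSE` (simulate compounds independently)
#' @return a `pbpk_system`
#' @export
assemble_model <- function(individual, compounds, interactions = TRUE) {
  validate_individual(individual)
  if (inherits(compounds, "compound_record")) compounds <- list(compounds)
  names(compounds) <- vapply(compounds, `[[`, "", "name")

  for (cmp in compounds) {
    for (p in cmp$pathways)
      if (is.null(individual$enzyme_states[[p$enzyme]]))
        stop("assembly error: compound ", cmp$name, " pathway enzyme ",
             p$enzyme, " missing from individual")
    for (ix in cmp$interactions)
      if (is.null(individual$enzyme_states[[ix$target]]))
        stop("assembly error: compound ", cmp$name, " interaction target ",
             ix$target, " missing from individual")
    if (!is.null(cmp$prodrug) && !cmp$prodrug$target %in% names(compounds))
      stop("prodrug target ", cmp$prodrug$target, " of ", cmp$name,
           " not among simulated compounds")
  }

  ## interaction bindings by target enzyme
  specs_by_target <- list()
  if (isTRUE(interactions)) {
    for (cmp in compounds)
      for (ix in cmp$interactions)
        specs_by_target[[ix$target]] <- c(specs_by_target[[ix$target]],
                                          list(ix))
  }
  dynamic_enzymes <- unique(unlist(lapply(specs_by_target, function(specs) {
    tg <- vapply(specs, `[[`, "", "target")
    dyn <- vapply(specs, function(s)
      s$mechanism == "induction" || identical(s$type, "irreversible"), TRUE)
    tg[dyn]
  }))) %||% character()

  org <- individual$organs
  V <- setNames(org$volume, org$name)
  Q <- setNames(org$blood_flow, org$name)
  co <- individual$cardiac_output
  q_ha <- individual$hepatic_artery_flow

  n_cs <- 18L  # 14 organs + lumen + elim_met + elim_ren + conv
  comp_info <- list()
  for (j in seq_along(compounds)) {
    cmp <- compounds[[j]]
    kp <- compute_kp(cmp$logp, cmp$fu, cmp$blood_plasma_ratio)
    offset <- (j - 1L) * n_cs
    paths <- lapply(cmp$pathways, function(p) {
      es <- individual$enzyme_states[[p$enzyme]]
      w <- es$expressing_organs
      p$organ_idx <- IDX[names(w)]
      p$weights <- unname(w)
      p$E0_eff <- es$E0
      p
    })
    comp_info[[cmp$name]] <- list(
      record = cmp, kp = kp, fu = cmp$fu, bp = cmp$blood_plasma_ratio,
      mw = cmp$mw, renal = cmp$renal_clearance,
      paths = paths, offset = offset,
      organ_idx = offset + 1:14, lumen = offset + 15L,
      elim_met = offset + 16L, elim_ren = offset + 17L, conv = offset + 18L,
      v_liv = unname(V["liver"]))
  }

  state_names <- c(
    unlist(lapply(names(compounds), function(nm)
      paste0(nm, ".", c(ORGAN_NAMES, "lumen", "elim_met", "elim_ren", "conv")))),
    if (length(dynamic_enzymes)) paste0("enz.", dynamic_enzymes))
  enz_idx <- setNames(length(compounds) * n_cs + seq_along(dynamic_enzymes),
                      dynamic_enzymes)

  structure(list(individual = individual, compounds = comp_info,
                 specs_by_target = specs_by_target,
                 dynamic_enzymes = dynamic_enzymes, enz_idx = enz_idx,
                 state_names = state_names, n_per_compound = n_cs,
                 V = V, Q = Q, co = co, q_ha = q_ha),
            class = "pbpk_system")
}

#' Number of ODE states of an assembled system
#'
#' @param system a `pbpk_system`
#' @param what `"total"`, `"compartment"` (organ amounts), `"absorption"`
#'   (lumen states) or `"enzyme"` (dynamic enzyme pools)
#' @export
n_states <- function(system, what = c("total", "compartment", "absorption",
                                      "enzyme")) {
  what <- match.arg(what)
  nc <- length(system$compounds)
  switch(what,
    total = length(system$state_names),
    compartment = 14L * nc,
    absorption = nc,
    enzyme = length(system$dynamic_enzymes))
}

## resolve a compound's absorption definition for a formulation label
resolve_formulation <- function(cmp, label) {
  f <- cmp$formulations[[label]]
  if (is.null(f) && label == "default" && length(cmp$formulations) == 1L)
    f <- cmp$formulations[[1L]]
  if (is.null(f))
    stop("compound ", cmp$name, ": unknown formulation '", label, "'")
  f
}

## expand a regimen into solver events, infusion windows, Weibull forcings
## and the dose-accounting table
build_dosing <- function(system, name, reg) {
  cp <- system$compounds[[name]]
  cmp <- cp$record
  ev <- reg$events
  out <- list(events = NULL, infusions = NULL, weibull = NULL,
              accounting = NULL, ka = NA_real_)
  if (is.null(ev) || !nrow(ev)) return(out)
  if (any(ev$time < 0)) stop("dose events must have non-negative times ",
                             "(shift the calendar before simulating)")
  dose_mg <- ev$dose * ifelse(ev$mg_per_kg, system$individual$weight, 1)
  dose_um <- mg_to_umol(dose_mg, cmp$mw)

  evd <- list(); infs <- list(); wbs <- list(); acc <- list()
  oral <- which(ev$route == "oral")
  if (length(oral)) {
    labs <- unique(ev$formulation[oral])
    if (length(labs) > 1L)
      stop("mixed oral formulations within one simulation are not supported")
    form <- resolve_formulation(cmp, labs[[1L]])
    fed1 <- unique(ev$fed[oral])
    if (length(fed1) > 1L) stop("mixed fed states within one simulation")
    f_eff <- form$fraction_dissolvable *
      (if (isTRUE(fed1)) form$fed$bioavailable_fraction else 1)
    if (f_eff > 1) stop("effective bioavailable fraction > 1 for ", cmp$name)
    out$ka <- form$ka
    for (i in oral) {
      if (form$model == "first_order") {
        evd[[length(evd) + 1L]] <- data.frame(
          var = paste0(name, ".lumen"), time = ev$time[i],
          value = f_eff * dose_um[i], method = "add")
      } else {
        scale_eff <- form$scale *
          (if (isTRUE(fed1)) form$fed$dissolution_scale else 1)
        wbs[[length(wbs) + 1L]] <- c(t0 = ev$time[i],
                                     amount = f_eff * dose_um[i],
                                     shape = form$shape, scale = scale_eff)
        evd[[length(evd) + 1L]] <- data.frame(
          var = paste0(name, ".lumen"), time = ev$time[i],
          value = 0, method = "add")
      }
      acc[[length(acc) + 1L]] <- data.frame(
        time = ev$time[i], nominal = dose_um[i], f_eff = f_eff,
        kind = form$model, shape = form$shape %||% NA_real_,
        scale = if (form$model == "weibull") form$scale *
          (if (isTRUE(fed1)) form$fed$dissolution_scale else 1) else NA_real_,
        duration = NA_real_)
    }
  }
  for (i in which(ev$route == "iv_bolus")) {
    evd[[length(evd) + 1L]] <- data.frame(
      var = paste0(name, ".venous_blood"), time = ev$time[i],
      value = dose_um[i], method = "add")
    acc[[length(acc) + 1L]] <- data.frame(time = ev$time[i],
      nominal = dose_um[i], f_eff = 1, kind = "iv_bolus",
      shape = NA_real_, scale = NA_real_, duration = NA_real_)
  }
  for (i in which(ev$route == "iv_infusion")) {
    infs[[length(infs) + 1L]] <- c(start = ev$time[i],
                                   end = ev$time[i] + ev$duration[i],
                                   rate = dose_um[i] / ev$duration[i])
    for (tt in c(ev$time[i], ev$time[i] + ev$duration[i]))
      evd[[length(evd) + 1L]] <- data.frame(
        var = paste0(name, ".venous_blood"), time = tt, value = 0,
        method = "add")
    acc[[length(acc) + 1L]] <- data.frame(time = ev$time[i],
      nominal = dose_um[i], f_eff = 1, kind = "iv_infusion",
      shape = NA_real_, scale = NA_real_, duration = ev$duration[i])
  }
  out$events <- if (length(evd)) do.call(rbind, evd)
  out$infusions <- if (length(infs)) do.call(rbind, infs)
  out$weibull <- if (length(wbs)) do.call(rbind, wbs)
  out$accounting <- if (length(acc)) do.call(rbind, acc)
  out
}

#' Simulate a PBPK system
#'
#' Integrates the assembled system under the given regimens with a
#' stiff-capable solver. Bolus doses are state discontinuities (the
#' integrator restarts at every event time); infusions and Weibull
#' dissolution enter as forcing terms.
#'
#' @param system a `pbpk_system` from [assemble_model()]
#' @param regimens a `regimen` (single-compound systems) or named list of
#'   regimens by compound name; compounds without a regimen receive no doses
#' @param t_end end of integration, h
#' @param dt output grid step, h (dose times are always included)
#' @param times optional explicit output grid (overrides `dt`); useful for
#'   resolving fast early distribution phases with a non-uniform grid
#' @param rtol,atol solver tolerances
#' @param method deSolve method
#' @return a `simulation_result`
#' @export
simulate_system <- function(system, regimens, t_end, dt = 0.25, times = NULL,
                            rtol = 1e-6, atol = 1e-9, method = "lsoda") {
  stopifnot(inherits(system, "pbpk_system"))
  if (inherits(regimens, "regimen")) {
    if (length(system$compounds) != 1L)
      stop("multi-compound systems need a named list of regimens")
    regimens <- setNames(list(regimens), names(system$compounds)[1L])
  }
  unknown <- setdiff(names(regimens), names(system$compounds))
  if (length(unknown)) stop("regimen for unknown compound: ",
                            paste(unknown, collapse = ", "))

  dosing <- lapply(names(system$compounds), function(nm) {
    reg <- regimens[[nm]]
    if (is.null(reg)) reg <- regimen(0)
    build_dosing(system, nm, reg)
  })
  names(dosing) <- names(system$compounds)

  all_events <- do.call(rbind, Filter(Negate(is.null),
                                      lapply(dosing, `[[`, "events")))
  if (!is.null(all_events)) {
    if (any(all_events$time > t_end))
      stop("t_end (", t_end, " h) does not cover all dose events")
    ## deSolve applies one event per var/time; aggregate coincident doses
    all_events <- stats::aggregate(value ~ var + time + method,
                                   data = all_events, FUN = sum)
  }

  y0 <- setNames(numeric(length(system$state_names)), system$state_names)
  for (e in system$dynamic_enzymes)
    y0[paste0("enz.", e)] <- system$individual$enzyme_states[[e]]$E0

  grid <- if (!is.null(times)) times[times <= t_end] else seq(0, t_end, by = dt)
  times <- sort(unique(c(0, grid, t_end,
                         if (!is.null(all_events)) all_events$time)))
  rhs <- make_rhs(system, dosing)
  sol <- deSolve::ode(y = y0, times = times, func = rhs, parms = NULL,
                      method = method, rtol = rtol, atol = atol,
                      events = if (!is.null(all_events))
                        list(data = all_events) else NULL,
                      maxsteps = 50000)
  if (attr(sol, "istate")[1L] < 0)
    stop("solver failed to converge; last accepted time ",
         max(sol[, "time"], na.rm = TRUE), " h")

  amounts <- sol[, -1L, drop = FALSE]
  comp_meta <- lapply(system$compounds, function(cp)
    list(fu = cp$fu, bp = cp$bp, mw = cp$mw, kp = as.list(cp$kp),
         volumes = as.list(system$V)))
  structure(list(time = sol[, 1L], amounts = amounts,
                 compounds = comp_meta, system = system, dosing = dosing,
                 t_end = t_end),
            class = "simulation_result")
}

## ---------------------------------------------------------------- rhs ----
make_rhs <- function(system, dosing) {
  V <- unname(system$V); Q <- unname(system$Q)
  co <- system$co; q_ha <- system$q_ha
  i_lung <- IDX[["lung"]]; i_liv <- IDX[["liver"]]; i_gut <- IDX[["gut"]]
  i_spl <- IDX[["spleen"]]; i_kid <- IDX[["kidney"]]
  i_art <- IDX[["arterial_blood"]]; i_ven <- IDX[["venous_blood"]]
  ## organs fed by arterial blood with venous (non-portal) return
  direct <- IDX[c("kidney", "muscle", "adipose", "skin", "brain", "heart",
                  "bone", "rest")]
  q_liv_out <- Q[i_liv]
  cps <- system$compounds
  ncomp <- length(cps)
  specs_by_target <- system$specs_by_target
  enz_idx <- system$enz_idx
  enz_states <- system$individual$enzyme_states
  nstate <- length(system$state_names)

  ## per-compound static pieces
  kps <- lapply(cps, function(cp) unname(cp$kp[ORGAN_NAMES]))
  fus <- vapply(cps, `[[`, 0, "fu")
  kas <- vapply(names(cps), function(nm) {
    ka <- dosing[[nm]]$ka
    if (is.na(ka)) 0 else ka
  }, 0)

  function(t, y, parms) {
    dy <- numeric(nstate)
    ## unbound plasma-equivalent concentration per compound per organ
    U <- vector("list", ncomp)
    Cs <- vector("list", ncomp)
    for (j in seq_len(ncomp)) {
      A <- y[cps[[j]]$organ_idx]
      C <- A / V
      Cs[[j]] <- C
      U[[j]] <- fus[j] * C / kps[[j]]
    }
    names(U) <- names(cps)

    ## current enzyme pools
    Eval <- function(enzyme, e0) {
      k <- enz_idx[enzyme]
      if (!is.na(k)) unname(y[k]) else e0
    }

    for (j in seq_len(ncomp)) {
      cp <- cps[[j]]
      C <- Cs[[j]]
      kp <- kps[[j]]
      CBout <- cp$bp * C / kp  # blood pools carry kp = BP, so CBout = C there
      oi <- cp$organ_idx

      d <- numeric(14)
      d[i_lung] <- co * (C[i_ven] - CBout[i_lung])
      d[i_art]  <- co * (CBout[i_lung] - C[i_art])
      d[i_gut]  <- Q[i_gut] * (C[i_art] - CBout[i_gut])
      d[i_spl]  <- Q[i_spl] * (C[i_art] - CBout[i_spl])
      d[i_liv]  <- q_ha * C[i_art] + Q[i_gut] * CBout[i_gut] +
                   Q[i_spl] * CBout[i_spl] - q_liv_out * CBout[i_liv]
      d[direct] <- Q[direct] * (C[i_art] - CBout[direct])
      d[i_ven]  <- sum(Q[direct] * CBout[direct]) +
                   q_liv_out * CBout[i_liv] - co * C[i_ven]

      ## absorption
      lum <- y[cp$lumen]
      flux_in <- 0
      wb <- dosing[[j]]$weibull
      if (!is.null(wb))
        flux_in <- sum(wb[, "amount"] *
                       weibull_flux(t - wb[, "t0"], wb[, "shape"],
                                    wb[, "scale"]))
      abs_flux <- kas[j] * lum
      dy[cp$lumen] <- flux_in - abs_flux
      d[i_gut] <- d[i_gut] + abs_flux

      ## infusions
      inf <- dosing[[j]]$infusions
      if (!is.null(inf)) {
        on <- inf[, "start"] <= t & t < inf[, "end"]
        if (any(on)) d[i_ven] <- d[i_ven] + sum(inf[on, "rate"])
      }

      ## metabolic elimination
      met <- 0
      for (p in cp$paths) {
        E_t <- Eval(p$enzyme, p$E0_eff)
        specs <- specs_by_target[[p$enzyme]]
        for (k in seq_along(p$organ_idx)) {
          o <- p$organ_idx[k]
          S <- U[[j]][o]
          if (S <= 0) next
          a <- 1; b <- 1; cc <- 1
          if (!is.null(specs)) {
            for (sp in specs) {
              if (sp$mechanism != "inhibition" || sp$type == "irreversible")
                next
              I <- U[[sp$perpetrator]][o]  # local (organ-site) driver
              if (I <= 0) next
              switch(sp$type,
                competitive       = a <- a + I / sp$ki,
                `non-competitive` = cc <- cc + I / sp$ki,
                uncompetitive     = b <- b + I / sp$ki,
                mixed             = { a <- a + I / sp$ki
                                      b <- b + I / (sp$alpha * sp$ki) })
            }
          }
          w <- p$weights[k]
          rate <- if (p$type == "linear") {
            clint <- p$clint_specific * E_t * cp$v_liv * 6e-5  # L/h
            clint * w * S / (a * cc)
          } else {
            vmax <- p$vmax_specific * E_t * cp$v_liv * 60      # umol/h
            vmax * w * S / ((p$km * a + S * b) * cc)
          }
          d[o] <- d[o] - rate
          met <- met + rate
        }
      }
      dy[cp$elim_met] <- met

      ## renal elimination (plasma-referenced clearance on kidney tissue)
      if (cp$renal > 0) {
        rr <- cp$renal * C[i_kid] / kp[i_kid]
        d[i_kid] <- d[i_kid] - rr
        dy[cp$elim_ren] <- rr
      }

      ## prodrug conversion (systemic, mol-to-mol, all compartments)
      pr <- cp$record$prodrug
      if (!is.null(pr)) {
        tgt <- cps[[pr$target]]
        conv <- pr$kconv * y[oi]
        d <- d - conv
        dy[tgt$organ_idx] <- dy[tgt$organ_idx] + conv
        dy[cp$conv] <- sum(conv)
      }
      dy[oi] <- dy[oi] + d
    }

    ## enzyme-pool dynamics (liver-site driver)
    for (e in system$dynamic_enzymes) {
      es <- enz_states[[e]]
      E <- y[enz_idx[e]]
      lambda <- 0; ind <- 0
      for (sp in specs_by_target[[e]]) {
        I <- U[[sp$perpetrator]][i_liv]
        if (I <= 0) next
        if (sp$mechanism == "induction")
          ind <- ind + sp$emax * I / (sp$ec50 + I)
        else if (sp$type == "irreversible")
          lambda <- lambda + sp$kinact * I / (sp$ki_half + I)
      }
      dy[enz_idx[e]] <- es$kdeg * es$E0 * (1 + ind) - E * (es$kdeg + lambda)
    }
    list(dy)
  }
}

#' Venous plasma concentration profile
#'
#' @param result a `simulation_result`
#' @param compound compound name
#' @param unit output unit (`"umol/L"`, `"ng/mL"`, `"ug/mL"`)
#' @return numeric vector along `result$time`
#' @export
plasma_concentration <- function(result, compound, unit = "ng/mL") {
  cp <- result$compounds[[compound]]
  if (is.null(cp)) stop("compound not in result: ", compound)
  um <- result$amounts[, paste0(compound, ".venous_blood")] /
    cp$volumes[["venous_blood"]] / cp$bp
  convert_conc(um, "umol/L", unit, cp$mw)
}

#' Enzyme-pool trajectory
#'
#' @param result a `simulation_result`
#' @param enzyme enzyme id; static pools return their constant baseline
#' @export
enzyme_trajectory <- function(result, enzyme) {
  col <- paste0("enz.", enzyme)
  if (col %in% colnames(result$amounts)) return(result$amounts[, col])
  es <- result$system$individual$enzyme_states[[enzyme]]
  if (is.null(es)) stop("unknown enzyme: ", enzyme)
  rep(es$E0, length(result$time))
}

#' @export
print.simulation_result <- function(x, ...) {
  cat(sprintf("<simulation_result> %d compound(s), t = 0..%g h, %d points\n",
              length(x$compounds), x$t_end, length(x$time)))
  invisible(x)
}
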
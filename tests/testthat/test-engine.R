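test_that("weibull release: boundary values and the shape-1 analytic point", {
  expect_equal(weibull_release(0, 1.2, 2), 0)
  expect_gt(weibull_release(100, 1.2, 2), 0.999999)
  expect_equal(weibull_release(2, 1, 2), 1 - exp(-1), tolerance = 1e-12)
  tt <- seq(0, 20, by = 0.1)
  expect_true(all(diff(weibull_release(tt, 0.8, 3)) >= 0))
})

test_that("state bookkeeping: static pools without interactions, dynamic
           pools under MBI coupling", {
  ind <- reference_individual()
  sys1 <- assemble_model(ind, probe_compound())
  expect_equal(n_states(sys1, "enzyme"), 0L)
  lib <- load_library()
  sys2 <- assemble_model(ind, lib[c("cyclosporine", "voriconazole")])
  expect_true("CYP3A4" %in% sys2$dynamic_enzymes)
  expect_equal(n_states(sys2, "compartment"), 28L)
  expect_equal(n_states(sys2, "absorption"), 2L)
})

test_that("assembly rejects unknown enzymes naming compound and pathway", {
  ind <- reference_individual()
  bad <- probe_compound()
  bad$pathways[[1]]$enzyme <- "CYP9Z9"
  expect_error(assemble_model(ind, bad), "CYP9Z9")
})

test_that("zero-dose regimen gives identically zero concentrations", {
  ind <- reference_individual()
  sys <- assemble_model(ind, probe_compound(ka = 1))
  res <- simulate_system(sys, regimen(0), t_end = 24, dt = 1)
  expect_true(all(res$amounts == 0))
})

test_that("a linear model is exactly dose-proportional", {
  ind <- reference_individual()
  sys <- assemble_model(ind, probe_compound(ka = 1))
  reg1 <- regimen(50, "oral", times = c(0, 12))
  reg2 <- regimen(100, "oral", times = c(0, 12))
  r1 <- simulate_system(sys, reg1, t_end = 36, dt = 0.5)
  r2 <- simulate_system(sys, reg2, t_end = 36, dt = 0.5)
  c1 <- plasma_concentration(r1, "probe")
  c2 <- plasma_concentration(r2, "probe")
  keep <- c1 > max(c1) * 1e-6
  expect_lt(max(abs(c2[keep] / c1[keep] - 2)), 2e-3)
})

test_that("iv-bolus AUC matches the well-stirred closed form", {
  ind <- reference_individual()
  cl <- 60; fu <- 0.4
  cmp <- probe_compound(clint_lh = cl, fu = fu)
  sys <- assemble_model(ind, cmp)
  res <- simulate_system(sys, regimen(100, "iv_bolus"), t_end = 300,
                         times = auc_grid(300))
  m <- compute_pk_metrics(res, "probe", 0, 300, conc_unit = "umol/L",
                          extrapolate = TRUE)
  qh <- hepatic_blood_flow(ind)
  cl_ws <- qh * fu * cl / (qh + fu * cl)
  expect_equal(m$auc, (100 / 300 * 1000) / cl_ws, tolerance = 0.02)
})

test_that("binding a perpetrator for an enzyme the victim does not use is a
           no-op on the victim", {
  ind <- reference_individual()
  victim <- probe_compound(enzyme = "CYP2C9", ka = 1)
  perp <- constant_perpetrator(list(list(target = "CYP1A2",
                                         mechanism = "inhibition",
                                         type = "competitive", ki = 0.1)))
  regs <- list(probe = regimen(100, "oral"), perp = regimen(100, "iv_bolus"))
  r_alone <- simulate_system(assemble_model(ind, victim),
                             regimen(100, "oral"), t_end = 24, dt = 0.5)
  r_bound <- simulate_system(assemble_model(ind, list(victim, perp)), regs,
                             t_end = 24, dt = 0.5)
  expect_equal(plasma_concentration(r_bound, "probe"),
               plasma_concentration(r_alone, "probe"), tolerance = 1e-6)
})

test_that("grid refinement changes AUC by less than 1%", {
  ind <- reference_individual()
  sys <- assemble_model(ind, probe_compound(ka = 0.8))
  r_coarse <- simulate_system(sys, regimen(100, "oral"), t_end = 48, dt = 0.5)
  r_fine <- simulate_system(sys, regimen(100, "oral"), t_end = 48, dt = 0.25)
  a1 <- compute_pk_metrics(r_coarse, "probe")$auc
  a2 <- compute_pk_metrics(r_fine, "probe")$auc
  expect_lt(abs(a1 - a2) / a2, 0.01)
})

test_that("pk metrics: analytic constant profile, unit identities, interval
           validation", {
  ## constant concentration: AUC = c*T, Cmax = Cmin = c
  fake <- structure(list(
    time = seq(0, 10, 0.5),
    amounts = matrix(2 * 3.9, nrow = 21, ncol = 1,
                     dimnames = list(NULL, "x.venous_blood")),
    compounds = list(x = list(fu = 1, bp = 1, mw = 246.3,
                              kp = list(), volumes = list(venous_blood = 3.9)))),
    class = "simulation_result")
  m <- compute_pk_metrics(fake, "x", 0, 10, conc_unit = "umol/L")
  expect_equal(m$auc, 20)
  expect_equal(m$cmax, 2)
  expect_equal(m$cmin, 2)
  ## uM.min identity vs a ug/mL-based AUC for busulfan's molecular weight
  m2 <- compute_pk_metrics(fake, "x", 0, 10, conc_unit = "ug/mL",
                           auc_unit = "uM.min")
  aug <- compute_pk_metrics(fake, "x", 0, 10, conc_unit = "ug/mL")$auc
  expect_equal(m2$auc, aug * 60 * 1000 / 246.3)
  expect_error(compute_pk_metrics(fake, "x", 5, 5), "empty interval")
  expect_error(compute_pk_metrics(fake, "x", 0, 99), "outside")
})

test_that("steady-state detection agrees with the one-compartment
           accumulation oracle", {
  ## slow-clearance, even-partitioning probe behaves near one-compartment
  ind <- reference_individual()
  cmp <- probe_compound(clint_lh = 5, fu = 1, logp = -2)
  sys <- assemble_model(ind, cmp)
  tau <- 24
  res <- simulate_system(sys, regimen(100, "iv_bolus", times = seq(0, 240, tau)),
                         t_end = 264, dt = 0.25)
  ## effective k from the model's own constants
  qh <- hepatic_blood_flow(ind)
  cl_ws <- qh * 5 / (qh + 5)
  kp <- compute_kp(-2, 1, 1)
  vss <- sum(ind$organs$volume * kp[ind$organs$name])
  k <- cl_ws / vss
  ## accumulation ratio of troughs matches 1/(1 - exp(-k*tau))
  conc <- plasma_concentration(res, "probe", "umol/L")
  trough <- function(d) conc[which.min(abs(res$time - (d * 24 - 0.25)))]
  racc_sim <- trough(10) / trough(1)
  racc <- (1 - exp(-10 * k * tau)) / (1 - exp(-k * tau))
  expect_equal(racc_sim, racc, tolerance = 0.05)
  ## detection interval within one of the closed-form prediction
  ss <- steady_state(res, "probe", interval = tau)
  rel_change <- function(n) exp(-n * k * tau) * (1 - exp(-k * tau)) /
    (1 - exp(-n * k * tau))
  n_star <- which(vapply(1:9, rel_change, 0) < 0.01)[1] + 1L
  expect_true(ss$reached)
  expect_lte(abs(ss$interval_index - n_star), 1L)
})

test_that("fed-state bioavailability modifier scales suspension exposure into
           the published 2.5-3x band", {
  ind <- reference_individual()
  lib <- load_library()
  posa <- lib[["posaconazole"]]
  sys <- assemble_model(ind, posa)
  fasted <- simulate_system(sys, regimen(200, "oral"), t_end = 96, dt = 0.25)
  fed <- simulate_system(sys, regimen(200, "oral", fed = TRUE), t_end = 96,
                         dt = 0.25)
  r <- compute_pk_metrics(fed, "posaconazole")$auc /
       compute_pk_metrics(fasted, "posaconazole")$auc
  expect_gte(r, 2.5)
  expect_lte(r, 3.0)
})

test_that("interaction driver concentrations follow fu scaling and first-pass
           liver excess", {
  ind <- reference_individual()
  cmp <- probe_compound(fu = 0.1, ka = 1)
  sys <- assemble_model(ind, cmp)
  res <- simulate_system(sys, regimen(100, "oral"), t_end = 24, dt = 0.1)
  iv <- interaction_driver_concentration(res, "probe", "venous_plasma")
  expect_equal(iv, 0.1 * plasma_concentration(res, "probe", "umol/L") / 1,
               tolerance = 1e-12)
  il <- interaction_driver_concentration(res, "probe", "liver")
  ## during oral absorption the liver sees more drug than the systemic side
  absorb <- res$time > 0.2 & res$time < 4
  expect_true(all(il[absorb] > iv[absorb]))
  expect_error(interaction_driver_concentration(res, "probe", "tumour"),
               "site")
})

test_that("infusions conserve mass and t_end must cover all doses", {
  ind <- reference_individual()
  sys <- assemble_model(ind, probe_compound())
  res <- simulate_system(sys, regimen(100, "iv_infusion", duration = 2),
                         t_end = 24, dt = 0.1)
  expect_lt(mass_balance(res)$max_rel_error, 0.005)
  expect_error(simulate_system(sys, regimen(100, "iv_bolus", times = 48),
                               t_end = 24), "cover")
})
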
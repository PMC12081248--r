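## Scenario tests use synthetic probe compounds (cheap to integrate)
## wherever library realism is not the point. The toy victim's window
## brackets its own steady-state trough (~200-800 ng/mL at 100 mg bid).

toy_lib <- local({
  victim <- probe_compound(clint_lh = 20, fu = 0.3, name = "victim", ka = 1)
  victim$therapeutic_window <- list(metric = "Cmin", lower = 200, upper = 800,
                                    unit = "ng/mL")
  ## non-cleared inhibitor/inducer: a single iv bolus holds exposure constant
  inhib <- constant_perpetrator(list(list(target = "CYP2C9",
                                          mechanism = "inhibition",
                                          type = "competitive", ki = 0.5)),
                                name = "inhib")
  inducer <- constant_perpetrator(list(list(target = "CYP2C9",
                                            mechanism = "induction",
                                            emax = 5, ec50 = 0.5)),
                                  name = "inducer")
  ## cleared inducer (t1/2 ~ 1.3 h) for discontinuation/washout timelines
  wash <- validate_compound(list(
    name = "inducer_cleared", mw = 400, logp = 0, fu = 1,
    blood_plasma_ratio = 1,
    absorption = list(model = "first_order", ka = 1,
                      fraction_dissolvable = 1),
    pathways = list(list(enzyme = "CYP1A2", type = "linear",
                         clint_specific = 100 / (1.8 * 1.8 * 6e-5))),
    interactions = list(list(target = "CYP2C9", mechanism = "induction",
                             emax = 5, ec50 = 0.5))))
  list(victim = victim, inhib = inhib, inducer = inducer,
       inducer_cleared = wash)
})

test_that("an empty (or zero-dose) perpetrator set reproduces victim-alone", {
  sc0 <- ddi_scenario("victim", daily_regimen(100, 2, 0, 3), eval_day = 3)
  sc1 <- ddi_scenario("victim", daily_regimen(100, 2, 0, 3),
                      perpetrators = list(inhib = regimen(0)), eval_day = 3)
  s0 <- run_scenario(sc0, lib = toy_lib, dt = 0.5)
  s1 <- run_scenario(sc1, lib = toy_lib, dt = 0.5)
  expect_equal(s1$mean, s0$mean, tolerance = 1e-9)
})

test_that("shifting the whole calendar leaves the metric unchanged", {
  base <- ddi_scenario("victim", daily_regimen(100, 2, 0, 3),
                       perpetrators = list(
                         inhib = daily_regimen(50, 1, -2, 2)),
                       eval_day = 3)
  shifted <- ddi_scenario("victim", daily_regimen(100, 2, 2, 5),
                          perpetrators = list(
                            inhib = daily_regimen(50, 1, 0, 4)),
                          eval_day = 5)
  s0 <- run_scenario(base, lib = toy_lib, dt = 0.5)
  s1 <- run_scenario(shifted, lib = toy_lib, dt = 0.5)
  expect_equal(s1$mean, s0$mean, tolerance = 1e-9)
})

test_that("degenerate population: identical individuals, zero SD", {
  sc <- ddi_scenario("victim", daily_regimen(100, 2, 0, 2),
                     population = population_spec(n = 3,
                                                  age_range = c(30, 30),
                                                  seed = 1),
                     eval_day = 2)
  s <- run_scenario(sc, lib = toy_lib, dt = 0.5)
  expect_equal(s$n, 3)
  expect_equal(s$sd, 0)
  expect_equal(length(unique(s$values)), 1L)
})

test_that("victim exposure is monotone in perpetrator dose (both signs)", {
  doses <- c(0, 25, 50, 100, 200)
  cmin_under <- function(perp_name) vapply(doses, function(d) {
    sc <- ddi_scenario("victim", daily_regimen(100, 2, 0, 2),
                       perpetrators = setNames(list(
                         regimen(d, "iv_bolus")), perp_name),
                       eval_day = 2)
    run_scenario(sc, lib = toy_lib, dt = 0.5)$mean
  }, 0)
  expect_true(all(diff(cmin_under("inhib")) > 0))
  expect_true(all(diff(cmin_under("inducer")) < 0))
})

test_that("residual induction from a stopped pre-treatment lowers the victim
           trough; stopping much earlier restores it", {
  kdeg <- enzyme_registry()$kdeg[1]
  run_with_stop <- function(start_day, stop_day) {
    sc <- ddi_scenario("victim", daily_regimen(100, 2, 0, 3),
                       perpetrators = list(
                         inducer_cleared = daily_regimen(200, 2, start_day,
                                                         stop_day)),
                       eval_day = 3)
    run_scenario(sc, lib = toy_lib, dt = 0.5)$mean
  }
  alone <- run_scenario(ddi_scenario("victim", daily_regimen(100, 2, 0, 3),
                                     eval_day = 3),
                        lib = toy_lib, dt = 0.5)$mean
  recent <- run_with_stop(-5, -1)
  expect_lt(recent, 0.95 * alone)
  ## stop earlier by >= 5/kdeg hours: effect shrinks most of the way back
  shift_days <- ceiling(5 / kdeg / 24)
  remote <- run_with_stop(-5 - shift_days, -1 - shift_days)
  expect_gt(remote, recent)
  expect_lt(abs(remote - alone) / alone, 0.15)
})

test_that("dose search returns the current dose when the window is already
           satisfied and reports failure otherwise", {
  win <- toy_lib$victim$therapeutic_window
  sc <- ddi_scenario("victim", daily_regimen(100, 2, 0, 2), eval_day = 2)
  base <- run_scenario(sc, lib = toy_lib, dt = 0.5)
  expect_true(base$mean >= win$lower && base$mean <= win$upper)
  rec <- optimize_dose(sc, win, c(100, 200), lib = toy_lib, dt = 0.5)
  expect_equal(rec$dose, 100)
  none <- optimize_dose(sc, list(lower = 1e6, upper = 2e6), c(50, 100),
                        lib = toy_lib, dt = 0.5)
  expect_false(none$satisfied)
  expect_true(is.na(none$dose))
  expect_equal(nrow(none$candidates), 2)
  expect_error(optimize_dose(sc, win, numeric()), "empty")
})

test_that("attainment criterion is no more permissive than the mean criterion
           at the window edge", {
  ## wide-spread population: the mean can sit inside the window while many
  ## individuals fall outside it
  sc <- ddi_scenario("victim", daily_regimen(100, 2, 0, 2),
                     population = population_spec(
                       n = 6, age_range = c(30, 30),
                       variability = list(E0 = list(CYP2C9 = 1.2)),
                       seed = 21),
                     eval_day = 2)
  win <- toy_lib$victim$therapeutic_window
  by_mean <- optimize_dose(sc, win, c(50, 100), lib = toy_lib, dt = 0.5)
  by_att <- optimize_dose(sc, win, c(50, 100), lib = toy_lib,
                          criterion = "attainment",
                          attainment_threshold = 0.99, dt = 0.5)
  expect_lte(sum(by_att$candidates$satisfies),
             sum(by_mean$candidates$satisfies))
})

test_that("fold-change tables delegate to the ratio arithmetic", {
  s1 <- structure(list(metric = "Cmin", mean = 100, sd = 5, n = 3,
                       values = c(95, 100, 105), unit = "ng/mL"),
                  class = "population_summary")
  s2 <- s1; s2$mean <- 220
  tab <- fold_change_table(list(alone = s1, combo = s2), baseline = "alone")
  expect_equal(tab$fold_change[tab$scenario == "combo"], 2.2)
  s3 <- s2; s3$metric <- "AUC"
  expect_error(fold_change_table(list(alone = s1, combo = s3), "alone"),
               "metric")
})

test_that("scenario and population specs round-trip through YAML", {
  td <- tempfile(); dir.create(td)
  on.exit(unlink(td, recursive = TRUE))
  yaml::write_yaml(list(n = 4, ethnicity = "Japanese", seed = 9,
                        age_range = c(25, 45),
                        variability = list(E0 = list(CYP3A4 = 0.3)),
                        phenotype_frequencies = list(
                          CYP2C19 = list(NM = 0.6, IM = 0.3, PM = 0.1))),
                  file.path(td, "pop.yaml"))
  ps <- load_population_spec(file.path(td, "pop.yaml"))
  expect_equal(ps$n, 4L)
  expect_length(sample_population(ps), 4)
  expect_error(load_population_spec({
    yaml::write_yaml(list(n = 2, bogus = 1), file.path(td, "bad.yaml"))
    file.path(td, "bad.yaml")
  }), "bogus")

  yaml::write_yaml(list(
    victim = "cyclosporine",
    victim_regimen = list(dose = 100, per_day = 2, start_day = 0, stop_day = 6),
    perpetrators = list(
      phenytoin = list(dose = 100, per_day = 3, start_day = -5, stop_day = -1)),
    phenotypes = list(CYP2C19 = "NM"),
    eval_day = 6), file.path(td, "sc.yaml"))
  sc <- load_scenario(file.path(td, "sc.yaml"))
  expect_s3_class(sc, "ddi_scenario")
  expect_equal(sc$victim, "cyclosporine")
  expect_equal(min(sc$perpetrators$phenytoin$events$time), -5 * 24)
  expect_equal(sc$eval_day, 6)
})
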
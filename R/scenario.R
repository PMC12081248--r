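## Clinical timeline scenarios over virtual populations, and dose search
## against therapeutic windows.
##
## Day convention: day 0 is the first victim dose day; perpetrator courses
## may start on negative days (pre-transplant conditioning). Internally the
## whole calendar is shifted so integration starts at the earliest dose.

#' Define a DDI scenario
#'
#' @param victim compound name
#' @param victim_regimen a `regimen` in calendar hours (day 0 = victim start)
#' @param perpetrators named list of regimens by compound name (calendar
#'   hours, negative allowed)
#' @param population a [population_spec()], or `NULL` for one default
#'   individual
#' @param phenotypes named list enzyme -> phenotype label applied to every
#'   individual (deterministic stratification)
#' @param eval_day calendar day of evaluation
#' @param metric `"Cmin"` (trough at 24h*eval_day, i.e. pre-dose) or
#'   `"AUC"` (over the dosing interval ending there)
#' @param interval_h dosing interval used for the AUC metric
#' @param conc_unit unit for Cmin
#' @param auc_unit `NULL` or `"uM.min"`
#' @param individual optional explicit individual (overrides `population`)
#' @return a `ddi_scenario`
#' @export
ddi_scenario <- function(victim, victim_regimen, perpetrators = list(),
                         population = NULL, phenotypes = list(),
                         eval_day = 6, metric = c("Cmin", "AUC"),
                         interval_h = 24, conc_unit = "ng/mL",
                         auc_unit = NULL, individual = NULL) {
  metric <- match.arg(metric)
  if (!is.null(names(perpetrators)) && victim %in% names(perpetrators))
    stop("victim cannot also appear as perpetrator regimen")
  structure(list(victim = victim, victim_regimen = victim_regimen,
                 perpetrators = perpetrators, population = population,
                 phenotypes = phenotypes, eval_day = eval_day,
                 metric = metric, interval_h = interval_h,
                 conc_unit = conc_unit, auc_unit = auc_unit,
                 individual = individual),
            class = "ddi_scenario")
}

scenario_individuals <- function(scenario) {
  if (!is.null(scenario$individual)) list(scenario$individual)
  else if (!is.null(scenario$population)) sample_population(scenario$population)
  else list(build_individual())
}

#' Run a DDI scenario over its population
#'
#' Simulates every individual through the full calendar (perpetrator
#' pre-treatment and washout are captured by the enzyme-turnover states) and
#' evaluates the victim metric at the evaluation day. Returns the population
#' summary: mean, SD, per-individual values, and -- when a window is given --
#' the attainment fraction.
#'
#' @param scenario a [ddi_scenario()]
#' @param lib compound library list
#' @param window optional therapeutic window (list with `lower`/`upper`)
#' @param dt output grid step, h
#' @return a `population_summary`
#' @export
run_scenario <- function(scenario, lib = load_library(), window = NULL,
                         dt = 0.25) {
  stopifnot(inherits(scenario, "ddi_scenario"))
  drugs <- c(scenario$victim, names(scenario$perpetrators))
  missing <- setdiff(drugs, names(lib))
  if (length(missing)) stop("drug(s) not in library: ",
                            paste(missing, collapse = ", "))
  ## include prodrug targets
  for (d in drugs) {
    pr <- lib[[d]]$prodrug
    if (!is.null(pr)) drugs <- union(drugs, pr$target)
  }
  regs <- c(setNames(list(scenario$victim_regimen), scenario$victim),
            scenario$perpetrators)

  ## shift calendar so the earliest dose is at t = 0
  all_times <- unlist(lapply(regs, function(r) r$events$time))
  t0 <- if (length(all_times)) min(c(all_times, 0)) else 0
  regs <- lapply(regs, shift_regimen, offset_h = -t0)
  eval_time <- scenario$eval_day * 24 - t0
  if (eval_time <= -t0) stop("evaluation before the first victim dose")
  t_end <- max(eval_time,
               max(vapply(regs, function(r)
                 if (nrow(r$events)) max(r$events$time) else 0, 0))) + 1

  inds <- scenario_individuals(scenario)
  values <- vapply(inds, function(ind) {
    for (e in names(scenario$phenotypes))
      ind <- set_enzyme_phenotype(ind, e, scenario$phenotypes[[e]])
    sys <- assemble_model(ind, lib[drugs])
    res <- simulate_system(sys, regs, t_end = t_end, dt = dt)
    if (scenario$metric == "Cmin") {
      unname(stats::approx(res$time,
                           plasma_concentration(res, scenario$victim,
                                                scenario$conc_unit),
                           xout = eval_time, rule = 2)$y)
    } else {
      compute_pk_metrics(res, scenario$victim,
                         interval_start = eval_time - scenario$interval_h,
                         interval_end = eval_time,
                         conc_unit = scenario$conc_unit,
                         auc_unit = scenario$auc_unit)$auc
    }
  }, 0)

  summ <- list(metric = scenario$metric, values = values,
               mean = mean(values), sd = stats::sd(values),
               n = length(values), unit = scenario$auc_unit %||%
                 scenario$conc_unit)
  if (!is.null(window)) {
    lo <- window$lower %||% -Inf
    hi <- window$upper %||% Inf
    summ$attainment <- mean(values >= lo & values <= hi)
  }
  structure(summ, class = "population_summary")
}

#' @export
print.population_summary <- function(x, ...) {
  cat(sprintf("<population_summary> %s = %.4g +/- %.4g %s (n = %d)\n",
              x$metric, x$mean, if (is.na(x$sd)) 0 else x$sd, x$unit, x$n))
  if (!is.null(x$attainment))
    cat(sprintf("  window attainment: %.0f%%\n", 100 * x$attainment))
  invisible(x)
}

#' Search candidate doses against a therapeutic window
#'
#' Re-runs the scenario at each candidate victim dose (ascending) and
#' recommends the smallest one whose population criterion falls inside the
#' window: the population mean by default, or the attainment fraction under
#' `criterion = "attainment"`.
#'
#' @param scenario a [ddi_scenario()]; its victim regimen supplies route,
#'   schedule and formulation, only the dose amount is replaced
#' @param window therapeutic window (list with `lower`/`upper`)
#' @param candidate_doses ascending numeric vector of dose amounts (mg, or
#'   mg/kg if the victim regimen is weight-based)
#' @param lib compound library
#' @param criterion `"mean"` or `"attainment"`
#' @param attainment_threshold minimum attainment fraction under the
#'   attainment criterion
#' @param dt output grid step, h
#' @return a `dose_recommendation`: `dose` (NA when no candidate satisfies),
#'   `satisfied`, and the per-candidate summary table
#' @export
optimize_dose <- function(scenario, window, candidate_doses,
                          lib = load_library(),
                          criterion = c("mean", "attainment"),
                          attainment_threshold = 0.8, dt = 0.25) {
  criterion <- match.arg(criterion)
  if (!length(candidate_doses)) stop("candidate dose list is empty")
  if (is.unsorted(candidate_doses)) stop("candidate doses must be ascending")
  lo <- window$lower %||% -Inf
  hi <- window$upper %||% Inf

  rows <- list(); chosen <- NA_real_; summaries <- list()
  for (d in candidate_doses) {
    sc <- scenario
    sc$victim_regimen$events$dose <- d
    s <- run_scenario(sc, lib = lib, window = window, dt = dt)
    ok <- if (criterion == "mean") s$mean >= lo && s$mean <= hi
          else s$attainment >= attainment_threshold
    rows[[length(rows) + 1L]] <- data.frame(
      dose = d, mean = s$mean, sd = s$sd,
      attainment = s$attainment %||% NA_real_, satisfies = ok)
    summaries[[as.character(d)]] <- s
    if (ok && is.na(chosen)) chosen <- d
  }
  structure(list(dose = chosen, satisfied = !is.na(chosen),
                 criterion = criterion, window = window,
                 candidates = do.call(rbind, rows), summaries = summaries),
            class = "dose_recommendation")
}

#' @export
print.dose_recommendation <- function(x, ...) {
  if (x$satisfied) cat("<dose_recommendation> recommended dose:", x$dose, "\n")
  else cat("<dose_recommendation> no candidate satisfies the window\n")
  print(x$candidates)
  invisible(x)
}

#' Fold changes of scenario summaries against a baseline
#'
#' @param summaries named list of `population_summary`
#' @param baseline name of the baseline entry
#' @return data.frame with mean ratios (delegating to [ddi_ratio()])
#' @export
fold_change_table <- function(summaries, baseline) {
  stopifnot(baseline %in% names(summaries))
  base <- summaries[[baseline]]
  rows <- lapply(names(summaries), function(nm) {
    s <- summaries[[nm]]
    if (!identical(s$metric, base$metric))
      stop("metric mismatch between ", nm, " and baseline")
    data.frame(scenario = nm, mean = s$mean, sd = s$sd,
               fold_change = if (nm == baseline) NA_real_
                             else ddi_ratio(s$mean, base$mean))
  })
  do.call(rbind, rows)
}

#' Read a population spec from YAML/JSON
#'
#' Fields mirror [population_spec()]; unknown fields are rejected.
#'
#' @param path YAML (or JSON, via yaml) file path
#' @export
load_population_spec <- function(path) {
  raw <- yaml::read_yaml(path)
  known <- c("n", "ethnicity", "sex", "age_range", "weight_source",
             "variability", "phenotype_frequencies", "seed")
  bad <- setdiff(names(raw), known)
  if (length(bad)) stop("unknown population spec field(s): ",
                        paste(bad, collapse = ", "))
  raw$age_range <- as.numeric(raw$age_range %||% c(20, 50))
  raw$phenotype_frequencies <- lapply(raw$phenotype_frequencies %||% list(),
                                      unlist)
  do.call(population_spec, raw)
}

#' Read a DDI scenario from YAML
#'
#' The file carries the victim drug and regimen, perpetrator regimens with
#' calendar start/stop days, an optional population spec (inline), phenotype
#' stratification, and the evaluation day/metric. Regimen blocks use the
#' [daily_regimen()] fields: `dose`, `per_day`, `start_day`, `stop_day`,
#' plus optional `route`, `formulation`, `fed`, `mg_per_kg`.
#'
#' @param path YAML file path
#' @export
load_scenario <- function(path) {
  raw <- yaml::read_yaml(path)
  reg_of <- function(r) daily_regimen(
    as.numeric(r$dose), per_day = r$per_day %||% 1,
    start_day = r$start_day %||% 0, stop_day = r$stop_day %||% 0,
    route = r$route %||% "oral", formulation = r$formulation %||% "default",
    fed = isTRUE(r$fed), mg_per_kg = isTRUE(r$mg_per_kg))
  perps <- lapply(raw$perpetrators %||% list(), reg_of)
  pop <- if (!is.null(raw$population)) do.call(population_spec, c(
    raw$population[setdiff(names(raw$population), "age_range")],
    list(age_range = as.numeric(raw$population$age_range %||% c(20, 50)))))
  ddi_scenario(victim = raw$victim, victim_regimen = reg_of(raw$victim_regimen),
               perpetrators = perps, population = pop,
               phenotypes = raw$phenotypes %||% list(),
               eval_day = raw$eval_day %||% 6,
               metric = raw$metric %||% "Cmin",
               interval_h = raw$interval_h %||% 24,
               conc_unit = raw$conc_unit %||% "ng/mL",
               auc_unit = raw$auc_unit)
}
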
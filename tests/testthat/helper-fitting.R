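## Shared fitting machinery: oral probe model with free whole-liver CLint
## (L/h) and absorption rate ka (1/h), predicted at given sampling times.

fit_sample_times <- c(0.5, 1, 1.5, 2, 3, 4, 6, 8, 10, 12, 18, 24)

make_builder <- function(ind, times) {
  force(ind); force(times)
  function(params) {
    cmp <- probe_compound(clint_lh = params[["clint"]], fu = 0.5,
                          ka = params[["ka"]])
    sys <- assemble_model(ind, cmp)
    res <- simulate_system(sys, regimen(100, "oral"), t_end = max(times),
                           times = times, rtol = 1e-5, atol = 1e-8)
    stats::approx(res$time, plasma_concentration(res, "probe", "ng/mL"),
                  xout = times, rule = 2)$y
  }
}

## one replicate of the recovery experiment: noisy dataset -> fit -> errors
recovery_replicate <- function(ind, builder, cv, seed,
                               truth = c(clint = 30, ka = 1.0),
                               n_starts = 3) {
  g <- generate_observed_profile(
    probe_compound(clint_lh = truth[["clint"]], fu = 0.5, ka = truth[["ka"]]),
    regimen(100, "oral"), fit_sample_times, cv = cv, seed = seed)
  fit <- fit_parameters(g$dataset, builder,
                        bounds = list(clint = c(6, 150), ka = c(0.1, 10)),
                        seed = seed, n_starts = n_starts)
  pred <- builder(fit$par)
  auc_pred <- trapz_simple(fit_sample_times, pred)
  auc_true <- trapz_simple(fit_sample_times, g$truth_profile)
  list(rel_err = abs(fit$par - truth) / truth,
       auc_ratio = auc_pred / auc_true)
}

trapz_simple <- function(x, y) sum((y[-1] + y[-length(y)]) * diff(x)) / 2
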
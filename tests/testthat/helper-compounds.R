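## Shared fixtures: small synthetic probe compounds built in code, and
## output-grid helpers for resolving the fast initial distribution phase.

`%||%` <- function(a, b) if (is.null(a)) b else a

## linear hepatic probe: one CYP2C9 pathway with whole-liver CLint clint_lh
## (L/h at reference expression), BP = 1
probe_compound <- function(clint_lh = 20, fu = 0.3, name = "probe",
                           logp = 1.0, mw = 300, ka = NULL,
                           renal = 0, enzyme = "CYP2C9") {
  e0 <- enzyme_registry()$E0[enzyme_registry()$enzyme == enzyme]
  def <- list(
    name = name, mw = mw, logp = logp, fu = fu, blood_plasma_ratio = 1,
    renal_clearance = renal,
    pathways = list(list(enzyme = enzyme, type = "linear",
                         clint_specific = clint_lh / (e0 * 1.8 * 6e-5))))
  if (!is.null(ka))
    def$absorption <- list(model = "first_order", ka = ka,
                           fraction_dissolvable = 0.8)
  validate_compound(def)
}

## non-cleared perpetrator: constant exposure after an iv bolus
constant_perpetrator <- function(interactions, name = "perp", fu = 1) {
  validate_compound(list(
    name = name, mw = 400, logp = 0.0, fu = fu, blood_plasma_ratio = 1,
    absorption = list(model = "first_order", ka = 1,
                      fraction_dissolvable = 1),
    pathways = list(), interactions = interactions))
}

## log-spaced early grid + linear tail, resolves the iv mixing transient
auc_grid <- function(t_end, n_tail = 1200) {
  unique(c(exp(seq(log(1e-4), 0, length.out = 150)),
           seq(1, t_end, length.out = n_tail)))
}

reference_individual <- function() build_individual()

liver_volume <- function(ind) ind$organs$volume[ind$organs$name == "liver"]

## whole-liver intrinsic clearance (L/h) of a linear pathway for an individual
scaled_clint <- function(cmp, ind, pathway = 1) {
  p <- cmp$pathways[[pathway]]
  e0 <- ind$enzyme_states[[p$enzyme]]$E0
  p$clint_specific * e0 * liver_volume(ind) * 6e-5
}
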
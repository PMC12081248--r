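#' Define a virtual population
#'
#' A population spec bundles demography, inter-individual variability and
#' genotype phenotype frequencies. Variability is independent log-normal per
#' parameter: a geometric CV `cv` corresponds to `sdlog = sqrt(log(1+cv^2))`.
#'
#' @param n number of individuals (>= 1)
#' @param ethnicity demographic label
#' @param sex `"male"` or `"female"`
#' @param age_range numeric length-2, years; individuals sampled uniformly
#' @param weight_source `"fixed_mean"` or `"sampled"` (log-normal around the
#'   demographic mean with CV `variability$weight`)
#' @param variability named list of geometric CVs. Recognised names:
#'   `weight`, `height`, and `E0` — a named list of per-enzyme CVs on the
#'   baseline enzyme concentration.
#' @param phenotype_frequencies named list: enzyme -> named numeric vector of
#'   phenotype probabilities (must sum to 1)
#' @param seed integer; the sole source of randomness
#' @return a `population_spec` object
#' @export
population_spec <- function(n = 100, ethnicity = "Japanese", sex = "male",
                            age_range = c(20, 50),
                            weight_source = c("fixed_mean", "sampled"),
                            variability = list(),
                            phenotype_frequencies = list(),
                            seed = 1L) {
  weight_source <- match.arg(weight_source)
  if (n < 1) stop("n must be >= 1")
  cvs <- unlist(variability)
  if (length(cvs) && any(cvs < 0)) stop("variability CVs must be >= 0")
  for (e in names(phenotype_frequencies)) {
    p <- phenotype_frequencies[[e]]
    if (abs(sum(p) - 1) > 1e-9)
      stop("phenotype frequencies for ", e, " must sum to 1")
    tab <- phenotype_table(e)
    bad <- setdiff(names(p), names(tab))
    if (length(bad)) stop("unknown phenotype(s) for ", e, ": ",
                          paste(bad, collapse = ", "))
  }
  structure(list(n = as.integer(n), ethnicity = ethnicity, sex = sex,
                 age_range = age_range, weight_source = weight_source,
                 variability = variability,
                 phenotype_frequencies = phenotype_frequencies,
                 seed = as.integer(seed)),
            class = "population_spec")
}

#' Sample a virtual population
#'
#' Pure function of the spec (including its seed): each individual draws from
#' its own derived RNG stream, so the population is reproducible and
#' independent of evaluation order. Log-normal perturbations have median 1
#' (the mean individual is the median individual); all sampled quantities are
#' strictly positive by construction.
#'
#' @param spec a [population_spec()]
#' @return list of `individual_physiology`
#' @export
sample_population <- function(spec) {
  stopifnot(inherits(spec, "population_spec"))
  lapply(seq_len(spec$n), function(i) sample_individual(spec, i))
}

sample_individual <- function(spec, index) {
  with_seed(stream_seed(spec$seed, index), {
    age <- stats::runif(1, spec$age_range[1], spec$age_range[2])
    ref <- ref_anthropometrics(spec$ethnicity, spec$sex)
    wt <- unname(ref["weight"]); ht <- unname(ref["height"])
    if (spec$weight_source == "sampled") {
      wt <- wt * geo_lognormal(1, spec$variability$weight %||% 0)
      ht <- ht * geo_lognormal(1, spec$variability$height %||% 0)
    }
    ind <- build_individual(age = age, weight = wt, height = ht,
                            sex = spec$sex, ethnicity = spec$ethnicity)
    ## genotype assignment
    for (e in names(spec$phenotype_frequencies)) {
      p <- spec$phenotype_frequencies[[e]]
      lab <- names(p)[findInterval(stats::runif(1), cumsum(p),
                                   rightmost.closed = TRUE) + 1L]
      ind <- set_enzyme_phenotype(ind, e, lab)
    }
    ## log-normal enzyme-expression variability (median-1 factors)
    e0cv <- spec$variability$E0
    for (e in names(e0cv)) {
      es <- ind$enzyme_states[[e]]
      if (is.null(es)) stop("variability on unknown enzyme ", e)
      f <- geo_lognormal(1, e0cv[[e]])
      es$E0 <- es$E0 * f; es$E <- es$E0
      ind$enzyme_states[[e]] <- es
    }
    ind
  })
}

## median-1 log-normal multiplicative factor with geometric CV cv
geo_lognormal <- function(n, cv) {
  if (is.null(cv) || cv <= 0) return(rep(1, n))
  exp(stats::rnorm(n, 0, sqrt(log(1 + cv^2))))
}

#' Tabulate a population
#'
#' One row per individual: demographics plus sampled enzyme baselines, ready
#' for CSV export.
#'
#' @param pop list of individuals from [sample_population()]
#' @param enzymes which enzyme baselines to include as columns
#' @export
population_table <- function(pop, enzymes = c("CYP3A4", "CYP2C19", "CYP3A5")) {
  rows <- lapply(seq_along(pop), function(i) {
    ind <- pop[[i]]
    row <- data.frame(id = i, age = ind$age, weight = ind$weight,
                      height = ind$height, sex = ind$sex,
                      ethnicity = ind$ethnicity,
                      cardiac_output = ind$cardiac_output)
    for (e in enzymes) row[[paste0(e, "_E0")]] <- ind$enzyme_states[[e]]$E0
    row
  })
  do.call(rbind, rows)
}
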
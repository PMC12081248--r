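## Compound records: schema-validated drug parameter files.
##
## Canonical internal units (documented contract of the schema, version 1):
##   mw g/mol; clearances L/h (plasma-referenced); clint_specific uL/min per
##   umol enzyme; vmax_specific umol/min per umol enzyme; Km, Ki, KI, EC50
##   umol/L on the unbound-plasma scale; kinact, ka, kconv 1/h; Weibull scale
##   h; doses mg; therapeutic windows in the unit stated in the file.

SCHEMA_VERSION <- 1L

#' Load a compound record from YAML
#'
#' Parses and validates a drug parameter file: physicochemistry, absorption
#' model (first-order or Weibull dissolution, with optional named
#' formulations and fed-state modifiers), clearance pathways (linear or
#' saturable, referenced to registered enzymes/transporters), renal
#' clearance, interaction specs (the five reversible inhibition types,
#' mechanism-based inactivation, Emax/EC50 induction), an optional prodrug
#' link, and an optional therapeutic window.
#'
#' @param path YAML file path
#' @return a `compound_record`
#' @export
load_compound <- function(path) {
  if (!file.exists(path)) stop("compound file not found: ", path)
  raw <- yaml::read_yaml(path)
  validate_compound(raw, src = path)
}

#' Validate a compound definition list
#'
#' @param raw named list following the schema
#' @param src label used in error messages
#' @return a `compound_record`
#' @export
validate_compound <- function(raw, src = raw$name %||% "<list>") {
  err <- function(...) stop("compound '", src, "': ", ..., call. = FALSE)
  ## coerce numerics defensively (YAML 1.1 reads "1e6" as a string)
  num <- function(x, field) {
    if (is.null(x)) return(NULL)
    v <- suppressWarnings(as.numeric(x))
    if (is.na(v)) err("field '", field, "' is not numeric: ", x)
    v
  }
  for (f in c("mw", "logp", "fu", "blood_plasma_ratio", "renal_clearance"))
    raw[[f]] <- num(raw[[f]], f)
  if (!identical(as.integer(raw$schema %||% SCHEMA_VERSION), SCHEMA_VERSION))
    err("unsupported schema version ", raw$schema)
  for (f in c("name", "mw", "logp", "fu"))
    if (is.null(raw[[f]])) err("missing field '", f, "'")
  if (raw$mw <= 0) err("mw must be positive")
  if (raw$fu <= 0 || raw$fu > 1) err("fu must be in (0, 1]")
  raw$blood_plasma_ratio <- raw$blood_plasma_ratio %||% 1
  raw$renal_clearance <- raw$renal_clearance %||% 0
  if (raw$renal_clearance < 0) err("renal_clearance must be >= 0")

  raw$pathways <- lapply(raw$pathways %||% list(), function(p) {
    if (is.null(p$enzyme) || !p$enzyme %in% ENZYME_IDS)
      err("pathway enzyme '", p$enzyme %||% "?", "' not in enzyme registry")
    kin <- p$kinetics %||% p
    kin$clint_specific <- num(kin$clint_specific, "clint_specific")
    kin$vmax_specific <- num(kin$vmax_specific, "vmax_specific")
    kin$km <- num(kin$km, "km")
    if (!is.null(kin$clint_specific)) {
      if (kin$clint_specific <= 0) err("pathway ", p$enzyme, ": clint_specific <= 0")
      if (!is.null(kin$vmax_specific))
        err("pathway ", p$enzyme, ": exactly one kinetics form allowed")
      list(enzyme = p$enzyme, type = "linear",
           clint_specific = kin$clint_specific)
    } else if (!is.null(kin$vmax_specific)) {
      if (is.null(kin$km) || kin$km <= 0 || kin$vmax_specific <= 0)
        err("pathway ", p$enzyme, ": saturable kinetics need vmax_specific > 0 and km > 0")
      list(enzyme = p$enzyme, type = "saturable",
           vmax_specific = kin$vmax_specific, km = kin$km)
    } else err("pathway ", p$enzyme, ": no kinetics given")
  })

  raw$interactions <- lapply(raw$interactions %||% list(), function(x) {
    if (is.null(x$target) || !x$target %in% ENZYME_IDS)
      err("interaction target '", x$target %||% "?", "' not registered")
    for (f in c("ki", "alpha", "kinact", "ki_half", "emax", "ec50"))
      x[[f]] <- num(x[[f]], f)
    mech <- x$mechanism %||% "inhibition"
    if (mech == "induction") {
      if (is.null(x$emax) || is.null(x$ec50) || x$emax < 0 || x$ec50 <= 0)
        err("induction of ", x$target, " needs emax >= 0 and ec50 > 0")
      induction_spec(raw$name, x$target, x$emax, x$ec50)
    } else {
      type <- x$type %||% "competitive"
      if (type == "irreversible") {
        if (is.null(x$kinact) || is.null(x$ki_half) ||
            x$kinact <= 0 || x$ki_half <= 0)
          err("irreversible inhibition of ", x$target,
              " needs kinact > 0 and ki_half (KI) > 0")
        inhibition_spec(raw$name, x$target, "irreversible",
                        kinact = x$kinact, KI = x$ki_half)
      } else {
        if (is.null(x$ki) || x$ki <= 0)
          err(type, " inhibition of ", x$target, " declared without ki > 0")
        inhibition_spec(raw$name, x$target, type, Ki = x$ki,
                        alpha = x$alpha %||% 1)
      }
    }
  })

  ## absorption / formulations
  norm_abs <- function(a, label) {
    if (is.null(a)) return(NULL)
    for (f in c("ka", "shape", "scale", "fraction_dissolvable"))
      a[[f]] <- num(a[[f]], f)
    if (!is.null(a$fed))
      for (f in c("dissolution_scale", "bioavailable_fraction"))
        a$fed[[f]] <- num(a$fed[[f]], f)
    model <- a$model %||% if (!is.null(a$ka)) "first_order" else "weibull"
    fd <- a$fraction_dissolvable %||% 1
    if (fd <= 0 || fd > 1) err("formulation ", label, ": fraction_dissolvable in (0,1]")
    out <- list(model = model, fraction_dissolvable = fd,
                ka = a$ka %||% 1,
                fed = list(dissolution_scale = a$fed$dissolution_scale %||% 1,
                           bioavailable_fraction = a$fed$bioavailable_fraction %||% 1))
    if (model == "weibull") {
      if (is.null(a$shape) || is.null(a$scale) || a$shape <= 0 || a$scale <= 0)
        err("formulation ", label, ": weibull needs shape > 0 and scale > 0")
      out$shape <- a$shape; out$scale <- a$scale
    }
    out
  }
  forms <- list()
  if (!is.null(raw$absorption)) forms$default <- norm_abs(raw$absorption, "default")
  for (fn in names(raw$formulations %||% list()))
    forms[[fn]] <- norm_abs(raw$formulations[[fn]], fn)
  raw$formulations <- forms

  if (!is.null(raw$prodrug)) {
    raw$prodrug$kconv <- num(raw$prodrug$kconv, "kconv")
    if (is.null(raw$prodrug$target) || is.null(raw$prodrug$kconv) ||
        raw$prodrug$kconv <= 0)
      err("prodrug link needs target and kconv > 0")
  }
  if (!is.null(raw$therapeutic_window)) {
    tw <- raw$therapeutic_window
    tw$lower <- num(tw$lower, "window lower"); tw$upper <- num(tw$upper, "window upper")
    if (is.null(tw$metric) || !tw$metric %in% c("Cmin", "AUC"))
      err("therapeutic_window metric must be Cmin or AUC")
    if (!is.null(tw$lower) && !is.null(tw$upper) && tw$lower >= tw$upper)
      err("therapeutic_window lower must be < upper")
    raw$therapeutic_window <- list(metric = tw$metric, lower = tw$lower,
                                   upper = tw$upper, unit = tw$unit %||% "ng/mL",
                                   interval = tw$interval %||% NULL)
  }
  structure(raw, class = "compound_record")
}

#' Write a compound record back to YAML
#'
#' Inverse of [load_compound()]; a write/read round trip reproduces the
#' record.
#'
#' @param record compound record
#' @param path output path
#' @export
write_compound <- function(record, path) {
  x <- unclass(record)
  yaml::write_yaml(x, path)
  invisible(path)
}

#' @export
print.compound_record <- function(x, ...) {
  cat(sprintf("<compound_record> %s (MW %.1f, logP %.2f, fu %.3f)\n",
              x$name, x$mw, x$logp, x$fu))
  cat("  pathways:", paste(vapply(x$pathways, `[[`, "", "enzyme"),
                           collapse = ", "), "\n")
  if (length(x$interactions))
    cat("  interactions:", length(x$interactions), "spec(s)\n")
  invisible(x)
}

#' Path of the shipped drug library
#' @export
library_path <- function() system.file("library", package = "pbpkddi")

#' Load the full drug library
#'
#' Reads every compound YAML in a directory (by default the shipped 13-drug
#' library) into a named list.
#'
#' @param dir directory of compound YAML files
#' @export
load_library <- function(dir = library_path()) {
  files <- list.files(dir, pattern = "\\.ya?ml$", full.names = TRUE)
  if (!length(files)) stop("no compound files found in ", dir)
  recs <- lapply(files, load_compound)
  names(recs) <- vapply(recs, `[[`, "", "name")
  recs
}

#' Therapeutic window of a library drug
#'
#' @param drug drug name
#' @param lib library list from [load_library()]
#' @return the window (list with metric/lower/upper/unit) or `NULL` for
#'   drugs without a monitoring target
#' @export
therapeutic_window <- function(drug, lib = load_library()) {
  if (!drug %in% names(lib)) stop("unknown drug: ", drug)
  lib[[drug]]$therapeutic_window
}

#' Interaction network of a library
#'
#' Cross-joins every interaction spec against every compound's clearance
#' pathways: an edge is emitted per (perpetrator, mechanism, target) with the
#' victims whose clearance runs through the target. Self-edges
#' (autoinhibition/-induction) are excluded from the victim list and flagged
#' in the `auto` column.
#'
#' @param lib library list
#' @return data.frame edge list
#' @export
interaction_network <- function(lib = load_library()) {
  substrates <- lapply(lib, function(r) vapply(r$pathways, `[[`, "", "enzyme"))
  rows <- list()
  for (r in lib) {
    for (ix in r$interactions) {
      mech <- if (inherits(ix, "induction_spec")) "induction"
              else paste0("inhibition/", ix$type)
      vict <- names(lib)[vapply(names(lib), function(v)
        ix$target %in% substrates[[v]], TRUE)]
      auto <- r$name %in% vict
      vict <- setdiff(vict, r$name)
      rows[[length(rows) + 1L]] <- data.frame(
        perpetrator = r$name, mechanism = mech, target = ix$target,
        victims = paste(vict, collapse = ";"),
        n_victims = length(vict), auto = auto,
        stringsAsFactors = FALSE)
    }
  }
  do.call(rbind, rows)
}
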
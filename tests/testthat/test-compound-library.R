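lib <- load_library()

test_that("all 13 drugs load and validate", {
  expect_setequal(names(lib),
                  c("busulfan", "phenytoin", "voriconazole", "posaconazole",
                    "itraconazole", "fluconazole", "letermovir",
                    "fosaprepitant", "aprepitant", "omeprazole",
                    "cyclosporine", "tacrolimus", "sirolimus"))
  for (r in lib) expect_s3_class(r, "compound_record")
})

test_that("write/read round trip reproduces a record", {
  tmp <- tempfile(fileext = ".yaml")
  on.exit(unlink(tmp))
  for (nm in c("cyclosporine", "phenytoin", "posaconazole", "fosaprepitant")) {
    write_compound(lib[[nm]], tmp)
    back <- load_compound(tmp)
    expect_equal(back, lib[[nm]], tolerance = 1e-9)
  }
})

test_that("interaction mechanisms match the published drug characterisation", {
  targets <- function(nm, mech = NULL) {
    ix <- lib[[nm]]$interactions
    if (!is.null(mech))
      ix <- Filter(function(s) s$mechanism == mech, ix)
    vapply(ix, `[[`, "", "target")
  }
  ## cyclosporine: CYP3A4 and efflux-transporter inhibitor
  expect_true(all(c("CYP3A4", "P-gp") %in% targets("cyclosporine")))
  ## letermovir: CYP2C9/2C19 inducer; CYP3A, OATP1B1/3, P-gp, BCRP inhibitor
  expect_true(all(c("CYP2C9", "CYP2C19") %in% targets("letermovir", "induction")))
  expect_true(all(c("CYP3A4", "OATP1B1", "OATP1B3", "P-gp", "BCRP") %in%
                    targets("letermovir", "inhibition")))
  ## mechanism-based inactivation assignments
  mbi_of <- function(nm) vapply(Filter(function(s)
    identical(s$type, "irreversible"), lib[[nm]]$interactions), `[[`, "", "target")
  expect_true("CYP3A4" %in% mbi_of("voriconazole"))
  expect_true("CYP3A4" %in% mbi_of("tacrolimus"))
  expect_true("CYP2C19" %in% mbi_of("omeprazole"))
  ## phenytoin induces CYP2C9, CYP2C19, CYP3A4, UGT1A4 and GSTA1
  expect_setequal(targets("phenytoin", "induction"),
                  c("CYP2C9", "CYP2C19", "CYP3A4", "UGT1A4", "GSTA1"))
  ## azole inhibitors of CYP3A4
  for (nm in c("posaconazole", "itraconazole", "fluconazole"))
    expect_true("CYP3A4" %in% targets(nm, "inhibition"))
  ## fluconazole is predominantly renally cleared
  expect_gt(lib[["fluconazole"]]$renal_clearance, 0)
  ## fosaprepitant converts to aprepitant
  expect_equal(lib[["fosaprepitant"]]$prodrug$target, "aprepitant")
})

test_that("therapeutic windows match the published targets", {
  w <- therapeutic_window("cyclosporine", lib)
  expect_equal(c(w$lower, w$upper), c(200, 400))
  expect_equal(w$unit, "ng/mL")
  expect_equal(c(therapeutic_window("tacrolimus", lib)$lower,
                 therapeutic_window("tacrolimus", lib)$upper), c(5, 15))
  expect_equal(c(therapeutic_window("sirolimus", lib)$lower,
                 therapeutic_window("sirolimus", lib)$upper), c(3, 8))
  posa <- therapeutic_window("posaconazole", lib)
  expect_equal(posa$lower, 0.7)
  expect_null(posa$upper)
  bus <- therapeutic_window("busulfan", lib)
  expect_equal(c(bus$lower, bus$upper), c(900, 1350))
  expect_equal(bus$metric, "AUC")
  for (nm in c("fluconazole", "letermovir", "fosaprepitant", "aprepitant",
               "omeprazole"))
    expect_null(therapeutic_window(nm, lib))
  expect_error(therapeutic_window("aspirin", lib), "unknown drug")
})

test_that("schema errors name the offending interaction", {
  bad <- list(name = "x", mw = 100, logp = 1, fu = 0.5,
              interactions = list(list(target = "CYP3A4",
                                       mechanism = "inhibition",
                                       type = "competitive")))
  expect_error(validate_compound(bad), "CYP3A4.*ki", ignore.case = TRUE)
  bad$interactions <- list(list(target = "CYP2C19",
                                mechanism = "inhibition",
                                type = "irreversible", kinact = 1))
  expect_error(validate_compound(bad), "CYP2C19.*KI|KI.*CYP2C19")
  bad$interactions <- list(list(target = "CYP3A4", mechanism = "induction",
                                emax = 2))
  expect_error(validate_compound(bad), "emax|ec50")
})

test_that("interaction network edges follow pathway membership", {
  net <- interaction_network(lib)
  edge_victims <- function(perp, target) {
    row <- net[net$perpetrator == perp & net$target == target, ]
    unlist(strsplit(row$victims[1], ";"))
  }
  ## phenytoin -> busulfan via GSTA1 induction
  expect_true("busulfan" %in% edge_victims("phenytoin", "GSTA1"))
  ## voriconazole CYP3A4 inactivation reaches the three immunosuppressants
  expect_true(all(c("cyclosporine", "tacrolimus", "sirolimus") %in%
                    edge_victims("voriconazole", "CYP3A4")))
  ## no self-edges in victim lists; auto-effects flagged instead
  for (i in seq_len(nrow(net)))
    expect_false(net$perpetrator[i] %in%
                   unlist(strsplit(net$victims[i], ";")))
  expect_true(any(net$auto))
})

test_that("network edge and victim counts equal a brute-force cross-join of
           the shipped files", {
  files <- list.files(library_path(), pattern = "\\.ya?ml$", full.names = TRUE)
  raw <- lapply(files, yaml::read_yaml)
  names(raw) <- vapply(raw, `[[`, "", "name")
  substrates <- lapply(raw, function(r)
    vapply(r$pathways %||% list(), `[[`, "", "enzyme"))
  n_edges <- 0L; n_victims <- 0L
  for (r in raw) for (ix in r$interactions %||% list()) {
    n_edges <- n_edges + 1L
    for (v in names(raw))
      if (v != r$name && ix$target %in% substrates[[v]])
        n_victims <- n_victims + 1L
  }
  net <- interaction_network(lib)
  expect_equal(nrow(net), n_edges)
  expect_equal(sum(net$n_victims), n_victims)
})

test_that("a standard dose of a library drug produces positive exposure", {
  ind <- build_individual()
  sys <- assemble_model(ind, lib[["voriconazole"]])
  res <- simulate_system(sys, regimen(200, "oral"), t_end = 24, dt = 0.5)
  expect_gt(compute_pk_metrics(res, "voriconazole")$auc, 0)
})
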
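## hand-assembled EnsembleDescriptors for term-by-term checks
toy_ed <- function(Rwat = c(mean = 2, sd = 0.1), Rmem = c(mean = 1.8, sd = 0.05),
                   logD = -0.7) {
  st <- list(maccs = rep(c(0L, 1L), 83), q_OH = 0.41, q_NH = 0,
             N_atom = 9L, N_rot = 0L, N_HA = 1L, N_HD = 1L)
  asa <- stats::setNames(numeric(length(permeaR:::.SYBYL_TYPES)),
                         permeaR:::.SYBYL_TYPES)
  asa["C.3"] <- 100; asa["O.3"] <- 20; asa["H"] <- 80
  out <- list(id = "toy", logd_conf = c(mean = -0.5, sd = 0.2),
              logD = logD,
              R = list(wat = Rwat, mem = Rmem),
              B = list(wat = c(mean = 0.25, sd = 0.1),
                       mem = c(mean = 1, sd = 0)),
              asa = list(wat = asa, mem = asa * 0.9),
              static = st, mw = 46, rings = list(n_cycle = 0L, n_ring = 0L),
              nConformers = 2L)
  class(out) <- "EnsembleDescriptors"
  out
}

test_that("Model A terms equal their independently computed pieces", {
  ed <- toy_ed()
  v <- featuresModelA(ed)
  expect_identical(attr(v, "model"), "A")
  expect_equal(v[["LogDconf_mean"]], -0.5)
  expect_equal(v[["LogDconf_sd"]], 0.2)
  expect_equal(v[["B_wat"]], 0.25)
  expect_equal(v[["R_wat"]], 2)
  expect_equal(v[["R2_wat"]], 4)
  expect_equal(v[["R3_wat"]], 8)
  expect_equal(v[["sigmaR_wat"]], 0.1)
  expect_equal(v[["logR_wat"]], log10(2))
  expect_equal(v[["ASAwat_C.3"]], 100)
  expect_equal(v[["ASAmem_C.3"]], 90)
  expect_equal(v[["q_OH"]], 0.41)
  expect_equal(v[["N_HD"]], 1)
  expect_equal(unname(v[sprintf("MACCS_%03d", 1:166)]),
               as.numeric(ed$static$maccs))
})

test_that("Model B uses membrane statistics and the ensemble LogD", {
  ed <- toy_ed()
  v <- featuresModelB(ed)
  expect_equal(v[["LogD"]], -0.7)
  expect_equal(v[["B_mem"]], 1)
  expect_equal(v[["R_mem"]], 1.8)
  expect_equal(v[["sigmaR_mem"]], 0.05)
  ## gauge case: identical phase energies -> LogD term 0, R terms nonzero
  ed0 <- toy_ed(logD = 0)
  v0 <- featuresModelB(ed0)
  expect_identical(v0[["LogD"]], 0)
  expect_gt(v0[["R_mem"]], 0)
})

test_that("Model AB is the union with shared terms appearing once", {
  ed <- toy_ed()
  a <- featuresModelA(ed)
  b <- featuresModelB(ed)
  ab <- featuresModelAB(a, b)
  expect_identical(attr(ab, "model"), "AB")
  expect_true(all(c("sigmaR_wat", "sigmaR_mem") %in% names(ab)))
  shared <- intersect(names(a), names(b))
  expect_identical(length(ab), length(a) + length(b) - length(shared))
  expect_false(any(duplicated(names(ab))))
  ## shared-term disagreement is an error
  b2 <- b
  b2[["q_OH"]] <- 0.9
  expect_error(featuresModelAB(a, b2), "disagree")
})

test_that("rigid molecules zero the deviation terms in Model A", {
  ed <- ensembleDescriptors(ens_of("benzene", 50, 1))
  v <- featuresModelA(ed)
  expect_identical(v[["LogDconf_sd"]], 0)
  expect_identical(v[["sigmaR_wat"]], 0)
  vb <- featuresModelB(ed)
  expect_identical(vb[["sigmaR_mem"]], 0)
  ## rigid: water and membrane R blocks coincide in AB
  ab <- featuresModelAB(v, vb)
  expect_equal(ab[["R_wat"]], ab[["R_mem"]])
})

test_that("feature schemas are constant across molecules", {
  eds <- list(ensembleDescriptors(ens_of("benzene", 20, 1)),
              ensembleDescriptors(ens_of("ethanol", 20, 1)))
  X <- featureMatrix(eds, "AB")
  expect_identical(nrow(X), 2L)
  expect_false(any(duplicated(colnames(X))))
  XA <- featureMatrix(eds, "A")
  expect_identical(ncol(XA), length(featuresModelA(eds[[1]])))
})

test_that("ablation flags drop the requested diffusion terms", {
  eds <- list(ensembleDescriptors(ens_of("ethanol", 20, 1)))
  X <- featureMatrix(eds, "AB", ablate = "sigmaR")
  expect_false(any(grepl("^sigmaR", colnames(X))))
  X4 <- featureMatrix(eds, "B", ablate = "R4")
  expect_true("R4_mem" %in% colnames(X4))
})

test_that("cumulant expansion: order 2 beats order 1 against the log-sum", {
  ## degenerate and zero-variance cases are exact
  one <- cumulantLogAverage(0.7, 1, order = 1)
  expect_equal(one$approx, one$exact, tolerance = 1e-12)
  same <- cumulantLogAverage(c(1.2, 1.2), c(0.3, 0.7), order = 2)
  expect_equal(same$approx, same$exact, tolerance = 1e-12)

  ## worked two-point example
  cx <- cumulantLogAverage(c(0, 1), c(0.5, 0.5), order = 1)
  expect_equal(cx$exact, log10(5.5), tolerance = 1e-12)
  expect_equal(cx$approx, 0.5, tolerance = 1e-12)
  c2 <- cumulantLogAverage(c(0, 1), c(0.5, 0.5), order = 2)
  expect_lt(abs(c2$exact - c2$approx), abs(cx$exact - cx$approx))

  ## property over random two-value ensembles; the expansion is an
  ## asymptotic series, so draws stay inside its domain (two-point gaps
  ## up to 1.2 Log10 units, the scale of per-conformer property spreads)
  set.seed(11)
  for (k in 1:100) {
    L <- rnorm(1) + c(0, runif(1, 0.05, 1.2))
    w <- runif(1, 0.05, 0.95)
    o1 <- cumulantLogAverage(L, c(w, 1 - w), order = 1)
    o2 <- cumulantLogAverage(L, c(w, 1 - w), order = 2)
    expect_lte(abs(o2$exact - o2$approx), abs(o1$exact - o1$approx) + 1e-12)
  }
  expect_error(cumulantLogAverage(numeric(0), numeric(0)), "empty")
})
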
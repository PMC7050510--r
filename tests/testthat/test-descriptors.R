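test_that("conformer radius obeys closed forms and rigid-motion invariance", {
  expect_identical(conformerRadius(matrix(c(1, 2, 3), 1, 3)), 0)
  two <- rbind(c(0, 0, 0), c(3, 0, 0))
  expect_equal(conformerRadius(two), 1.5, tolerance = 1e-12)

  m <- prep_smi("n_hexane")
  heavy <- which(atoms(m)$element != "H")
  r0 <- conformerRadius(coords(m), heavy)
  moved <- permeaR:::.rotate_about(coords(m), c(1, 2, 3), c(2, 1, 7), 0.9)
  moved <- sweep(moved, 2, c(10, -4, 2), `+`)
  expect_equal(conformerRadius(moved, heavy), r0, tolerance = 1e-9)
})

test_that("isolated-atom ASA matches the sphere closed form within 1%", {
  r <- permeaR:::.VDW_RADIUS[["C"]]
  asa <- permeaR:::asa_cpp(matrix(0, 1, 3), r, probe = 1.4, npoints = 960)
  expect_equal(asa[1], 4 * pi * (r + 1.4)^2, tolerance = 0.01)
})

test_that("atom-typed ASA partitions the molecular total and is invariant", {
  m <- prep_smi("ethanol")
  per <- permeaR:::asa_cpp(coords(m),
                           permeaR:::.VDW_RADIUS[atoms(m)$element],
                           1.4, 240)
  byType <- atomtypeAsa(m)
  expect_equal(sum(byType), sum(per), tolerance = 1e-9)
  expect_identical(names(byType), permeaR:::.SYBYL_TYPES)
  moved <- sweep(coords(m) %*% diag(3), 2, c(5, 5, 5), `+`)
  expect_equal(sum(atomtypeAsa(m, moved)), sum(byType), tolerance = 1e-9)
})

test_that("a caged atom has near-zero ASA versus a high-resolution oracle", {
  ## central C surrounded by an icosahedral shell of C at 2.2 A
  gr <- (1 + sqrt(5)) / 2
  ico <- rbind(c(0, 1, gr), c(0, -1, gr), c(0, 1, -gr), c(0, -1, -gr),
               c(1, gr, 0), c(-1, gr, 0), c(1, -gr, 0), c(-1, -gr, 0),
               c(gr, 0, 1), c(-gr, 0, 1), c(gr, 0, -1), c(-gr, 0, -1))
  shell <- ico / sqrt(rowSums(ico^2)) * 2.2
  xyz <- rbind(c(0, 0, 0), shell)
  radii <- rep(permeaR:::.VDW_RADIUS[["C"]], 13)
  lo <- permeaR:::asa_cpp(xyz, radii, 1.4, 240)
  hi <- permeaR:::asa_cpp(xyz, radii, 1.4, 3840)
  expect_lt(hi[1], 1)          # high-resolution oracle: enclosed
  expect_lt(abs(lo[1] - hi[1]), 1)
})

test_that("hydrogen bonds need donors, geometry and bond separation", {
  expect_identical(countIntramolecularHbonds(prep_smi("methane")), 0L)
  expect_identical(countIntramolecularHbonds(prep_smi("ethanol")), 0L)

  ## constructed HO-CH2-C(=O)H with H...O=C contact at 1.9 A, 160 deg
  at <- data.frame(
    element = c("O", "H", "C", "C", "O"),
    type = c("O.3", "H", "C.3", "C.2", "O.2"),
    charge = c(-0.4, 0.3, 0.05, 0.2, -0.15),
    x = 0, y = 0, z = 0, stringsAsFactors = FALSE)
  bd <- data.frame(i = c(1, 1, 3, 4), j = c(2, 3, 4, 5),
                   order = c("1", "1", "1", "2"),
                   stringsAsFactors = FALSE)
  ## geometry: acceptor O5 at 1.9 A from H2, O1-H2...O5 angle 160 deg
  ang <- 160 * pi / 180
  xyz <- rbind(
    c(0, 0, 0),                               # O1 donor
    c(0.96, 0, 0),                            # H2
    c(-0.7, 1.2, 0),                          # C3
    c(0.6, 1.9, 0),                           # C4
    c(0.96, 0, 0) + 1.9 * c(-cos(ang), sin(ang), 0)) # O5 acceptor
  at$x <- xyz[, 1]; at$y <- xyz[, 2]; at$z <- xyz[, 3]
  mol <- new("Molecule", id = "toy", atoms = at, bonds = bd,
             formalCharge = 0, meta = list())
  expect_identical(countIntramolecularHbonds(mol), 1L)
  ## tighter distance cutoff removes it
  expect_identical(countIntramolecularHbonds(mol, distCut = 1.5), 0L)
  ## stricter angle cutoff removes it
  expect_identical(countIntramolecularHbonds(mol, angleCut = 175), 0L)
})

test_that("static descriptors match chemical expectations", {
  bz <- staticDescriptors(prep_smi("benzene"))
  expect_identical(bz$N_rot, 0L)
  expect_identical(bz$N_HD, 0L)
  expect_identical(bz$q_OH, 0)
  expect_length(bz$maccs, 166)

  et <- staticDescriptors(prep_smi("ethanol"))
  expect_identical(et$N_HD, 1L)
  expect_identical(et$N_HA, 1L)
  expect_gt(et$q_OH, 0)
  expect_identical(et$q_NH, 0)
  expect_length(et$maccs, 166)
  expect_true(all(et$maccs %in% c(0L, 1L)))
  ## triethylene glycol: flexible, 2 OH donors, 4 O acceptors
  tg <- staticDescriptors(prep_smi("teg"))
  expect_identical(tg$N_HD, 2L)
  expect_identical(tg$N_HA, 4L)
  expect_gt(tg$N_rot, 4L)
})

test_that("ensemble statistics implement the weighted mean and deviation", {
  expect_equal(ensembleStats(5, 1), c(mean = 5, sd = 0))
  expect_equal(ensembleStats(c(1, 3), c(0.5, 0.5)), c(mean = 2, sd = 1))
  ## degeneracy 3:1 at equal energies -> weights 0.75/0.25
  expect_equal(ensembleStats(c(1, 3), c(0.75, 0.25))[["mean"]], 1.5)
  expect_error(ensembleStats(1:3, c(0.5, 0.5)), "length")
  ## duplicating a value with its weight split leaves both moments fixed
  s1 <- ensembleStats(c(1, 3), c(0.4, 0.6))
  s2 <- ensembleStats(c(1, 1, 3), c(0.2, 0.2, 0.6))
  expect_equal(s1, s2, tolerance = 1e-12)
})

test_that("diffusion feature block matches the series layout", {
  f <- diffusionFeatures(1, 0)
  expect_equal(unname(f), c(1, 1, 1, 0, 0))
  expect_identical(names(f), c("R", "R2", "R3", "logR", "sigmaR"))
  f2 <- diffusionFeatures(2, 0.1)
  expect_true(all(f2[c("R", "R2", "R3")] > f[c("R", "R2", "R3")]))
  expect_error(diffusionFeatures(0, 0), "positive")
  expect_error(diffusionFeatures(-1, 0), "positive")
  f3 <- diffusionFeatures(2, 0.1, ablate = c("sigmaR", "R4"))
  expect_false("sigmaR" %in% names(f3))
  expect_equal(f3[["R4"]], 16)
})

test_that("the fitted diffusion block reproduces the exact log-diffusion", {
  ## -Log10(fv*R + fi*R^2) over R in [2, 7] with fi/fv*R <= 0.1
  R <- seq(2, 7, by = 0.05)
  fv <- 1; fi <- 0.1 / 7
  target <- -log10(fv * R + fi * R^2)
  Xb <- cbind(R, R^2, R^3, log10(R))
  fit <- stats::lm.fit(cbind(1, Xb), target)
  expect_lt(max(abs(fit$residuals)), 1e-3)
})

test_that("rigid ensembles have zero deviations; flexible ones do not", {
  edb <- ensembleDescriptors(ens_of("benzene", 100, 1))
  expect_identical(unname(edb$R$wat["sd"]), 0)
  expect_identical(unname(edb$R$mem["sd"]), 0)
  expect_identical(unname(edb$logd_conf["sd"]), 0)
  edh <- ensembleDescriptors(ens_of("n_hexane", 100, 1))
  expect_gt(edh$R$wat["sd"], edb$R$wat["sd"])
})
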
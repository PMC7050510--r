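test_that("ring opening removes one breakable bond per cycle", {
  ch <- openRings(prep_smi("cyclohexane"))
  expect_identical(nrow(ch$drop), 1L)
  expect_identical(ch$rigidRings, 0L)

  bu <- openRings(prep_smi("n_butane"))
  expect_identical(nrow(bu$drop), 0L)

  expect_warning(bz <- openRings(prep_smi("benzene")), "no breakable bond")
  expect_identical(nrow(bz$drop), 0L)
  expect_identical(bz$rigidRings, 1L)
})

test_that("sampling is fully determined by the seed", {
  m <- prep_smi("n_butane")
  s1 <- sampleConformers(m, nSamples = 15, seed = 42)
  s2 <- sampleConformers(m, nSamples = 15, seed = 42)
  expect_identical(s1$coords, s2$coords)
  expect_identical(s1$eVac, s2$eVac)
  s3 <- sampleConformers(m, nSamples = 15, seed = 43)
  expect_false(identical(s1$coords, s3$coords))
})

test_that("rigid molecules yield one minimized conformer regardless of n", {
  s <- suppressWarnings(sampleConformers(prep_smi("benzene"),
                                         nSamples = 25, seed = 1))
  expect_identical(s$nAccepted, 1L)
  ens <- ens_of("benzene", n = 100, seed = 1)
  expect_length(degeneracy(ens), 1)
})

test_that("force-field energy is deterministic and minimization non-increasing", {
  m <- prep_smi("ethanol")
  e1 <- ffEnergy(m)
  expect_identical(e1, ffEnergy(m))
  ## distorted geometry relaxes downhill
  xyz <- coords(m)
  xyz[1, ] <- xyz[1, ] + 0.3
  e_dist <- ffEnergy(m, xyz)
  ff <- permeaR:::.ff_terms(m)
  res <- permeaR:::.minimize(xyz, ff)
  expect_lte(res$energy, e_dist)
})

test_that("analytic gradient matches a numeric gradient", {
  m <- prep_smi("ethanol")
  ff <- permeaR:::.ff_terms(m)
  x0 <- as.numeric(t(coords(m))) + 0.05
  ev <- function(x) permeaR:::ff_eval_cpp(x, ff$bonds, ff$angles,
                                          ff$torsions, ff$pairs,
                                          ff$restraints)
  g <- ev(x0)$gradient
  gn <- vapply(seq_along(x0), function(i) {
    h <- 1e-6
    xp <- x0; xp[i] <- xp[i] + h
    xm <- x0; xm[i] <- xm[i] - h
    (ev(xp)$energy - ev(xm)$energy) / (2 * h)
  }, 0)
  expect_lt(max(abs(g - gn)), 1e-4)
})

test_that("ethane eclipsed conformation lies above staggered", {
  m <- prep_smi("ethane")
  ff <- permeaR:::.ff_terms(m)
  xyz <- permeaR:::.minimize(coords(m), ff)$coords # staggered minimum
  e_stag <- permeaR:::.ff_eval(xyz, ff)$energy
  ## rotate one methyl by 60 degrees about the C-C axis -> eclipsed
  at <- atoms(m); bd <- bonds(m)
  h_on_c2 <- intersect(which(at$element == "H"),
                       c(bd$j[bd$i == 2], bd$i[bd$j == 2]))
  rot <- permeaR:::.rotate_about(xyz[h_on_c2, , drop = FALSE],
                                 xyz[1, ], xyz[2, ], pi / 3)
  xyz2 <- xyz; xyz2[h_on_c2, ] <- rot
  e_ecl <- permeaR:::.ff_eval(xyz2, ff)$energy
  expect_gt(e_ecl, e_stag + 1)
})

test_that("overlapping atoms give a large finite capped repulsion", {
  m <- prep_smi("ethanol")
  xyz <- coords(m)
  xyz[9, ] <- xyz[1, ] + c(0.05, 0, 0) # H almost on top of C1
  e <- ffEnergy(m, xyz)
  expect_true(is.finite(e))
  expect_gt(e, 1e3)
})

test_that("cyclohexane rings reclose within tolerance without clashes", {
  m <- prep_smi("cyclohexane")
  op <- openRings(m)
  s <- sampleConformers(m, nSamples = 40, seed = 7)
  expect_gte(s$nAccepted / (s$nAccepted + s$nFailed), 0.9)
  heavy <- which(atoms(m)$element != "H")
  ff <- permeaR:::.ff_terms(m)
  for (xyz in s$coords) {
    dl <- sqrt(rowSums((xyz[op$drop[, 1], , drop = FALSE] -
                          xyz[op$drop[, 2], , drop = FALSE])^2))
    expect_true(all(abs(dl - op$r0) / op$r0 <= 0.10))
    expect_gte(permeaR:::.min_nonbonded_heavy(xyz, ff, heavy), 1.5)
  }
})

test_that("clustering conserves counts and separates distant geometries", {
  m <- prep_smi("n_butane")
  xyz <- coords(m)
  ## four exact copies -> one cluster of degeneracy 4
  s <- list(coords = replicate(4, xyz, simplify = FALSE),
            eVac = rep(1, 4), nAccepted = 4L, nFailed = 0L,
            opened = list(rigidRings = 0L))
  ens <- clusterDegeneracy(s, m, seed = 1)
  expect_identical(degeneracy(ens), 4L)

  ## an internally distorted copy (one end atom pulled 8 A away) stays
  ## separate: superposition cannot hide a distortion this large
  far <- permeaR:::.rotate_about(xyz, c(0, 0, 0), c(0, 0, 1), 1.2)
  heavy <- which(atoms(m)$element != "H")
  far[heavy[4], ] <- far[heavy[4], ] + c(8, 0, 0)
  s2 <- list(coords = list(xyz, far), eVac = c(0, 5), nAccepted = 2L,
             nFailed = 0L, opened = list(rigidRings = 0L))
  ens2 <- clusterDegeneracy(s2, m, seed = 1)
  expect_identical(degeneracy(ens2), c(1L, 1L))

  big <- sampleConformers(m, nSamples = 50, seed = 2)
  ens3 <- clusterDegeneracy(big, m, seed = 2)
  expect_identical(sum(degeneracy(ens3)), big$nAccepted)
})

test_that("butane dihedrals concentrate at the torsion-scan minima", {
  m <- prep_smi("n_butane")
  heavy <- which(atoms(m)$element != "H")
  ## 1-degree torsion scan of the same force field: rotate the C3-side
  ## subtree, minimize nothing, record the energy profile
  ff <- permeaR:::.ff_terms(m)
  xyz0 <- permeaR:::.minimize(coords(m), ff)$coords
  bd <- bonds(m)
  cc <- which(bd$i %in% heavy & bd$j %in% heavy)
  central <- cc[2] # C2-C3
  adj <- lapply(seq_len(nrow(atoms(m))), function(v)
    c(bd$j[bd$i == v], bd$i[bd$j == v]))
  side <- permeaR:::.subtree_atoms(adj, bd$i[central], bd$j[central])
  side <- setdiff(side, bd$j[central])
  base <- dihedral_deg(xyz0, heavy)
  scan <- vapply(0:359, function(a) {
    x <- xyz0
    x[side, ] <- permeaR:::.rotate_about(x[side, , drop = FALSE],
                                         xyz0[bd$i[central], ],
                                         xyz0[bd$j[central], ],
                                         a * pi / 180)
    permeaR:::.ff_eval(x, ff)$energy
  }, 0)
  minima_offsets <- which(scan < c(scan[-1], scan[1]) &
                            scan < c(scan[360], scan[-360])) - 1
  minima <- sort(((base + minima_offsets) %% 360 + 360) %% 360)
  expect_length(minima, 3) # anti + two gauche of the implemented torsion

  s <- sampleConformers(m, nSamples = 150, seed = 5)
  angs <- vapply(s$coords, dihedral_deg, 0, idx = heavy) %% 360
  near_min <- vapply(angs, function(a)
    min(pmin(abs(a - minima), 360 - abs(a - minima))) < 25, TRUE)
  expect_gte(mean(near_min), 0.9)
  ## minima themselves sit near anti (180) and gauche (+-60)
  canon <- c(60, 180, 300)
  expect_true(all(vapply(minima, function(mm)
    min(pmin(abs(mm - canon), 360 - abs(mm - canon))) < 20, TRUE)))
})

test_that("flexibility ordering: benzene has no more clusters than hexane", {
  nb <- length(degeneracy(ens_of("benzene", 100, 1)))
  nh <- length(degeneracy(ens_of("n_hexane", 100, 1)))
  expect_lte(nb, nh)
})
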
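## Implicit solvation: pairwise-descreening generalized Born electrostatics
## plus an atomic-solvation-parameter x ASA nonpolar term, for a
## high-dielectric water phase and a low-dielectric membrane phase.
## Solvated conformer energies drive Boltzmann ensemble weights and the
## partition-function LogD.

## HCT-style descreening scale factors by element
.GB_SCALE <- c(H = 0.85, C = 0.72, N = 0.79, O = 0.85, S = 0.96,
               P = 0.86, F = 0.88, Cl = 0.80, Br = 0.80, I = 0.80)
.GB_OFFSET <- 0.09
.COULOMB <- 332.0637 # kcal*Angstrom/(mol*e^2)

#' Solvation model parameters
#'
#' Atomic solvation parameters follow the two-phase GB/SA convention:
#' +10 cal/mol/A^2 for water and -5 cal/mol/A^2 for the membrane, applied
#' uniformly to all atoms; the membrane is modeled as a single
#' low-dielectric phase (the same phase plays the role of octanol in the
#' partition-function LogD).
#'
#' @param temperature temperature in K (k_B*T = 0.5925 kcal/mol at the
#'   default 298.15).
#' @param sigmaWater,sigmaMembrane per-area solvation parameters in
#'   cal/mol/A^2.
#' @param dielectricWater,dielectricMembrane solvent dielectric constants.
#' @param probe solvent probe radius (Angstrom) for the ASA term.
#' @param asaPoints sphere points per atom for the numeric ASA.
#' @return named list of parameters.
#' @export
solvationParams <- function(temperature = 298.15,
                            sigmaWater = 10, sigmaMembrane = -5,
                            dielectricWater = 78.5,
                            dielectricMembrane = 2.0,
                            probe = 1.4, asaPoints = 240) {
  stopifnot(temperature > 0)
  list(temperature = temperature,
       sigmaWater = sigmaWater, sigmaMembrane = sigmaMembrane,
       dielectricWater = dielectricWater,
       dielectricMembrane = dielectricMembrane,
       probe = probe, asaPoints = asaPoints)
}

## HCT pairwise-descreening effective Born radii
.born_radii <- function(xyz, element) {
  rho <- .VDW_RADIUS[element] - .GB_OFFSET
  sc <- .GB_SCALE[element]
  sc[is.na(sc)] <- 0.8
  n <- nrow(xyz)
  D <- as.matrix(stats::dist(xyz))
  I <- numeric(n)
  srho <- sc * rho
  for (i in seq_len(n)) {
    r <- D[i, -i]
    sj <- srho[-i]
    L <- pmax(rho[i], abs(r - sj))
    U <- r + sj
    term <- 0.5 * (1 / L - 1 / U + (r / 4) * (1 / U^2 - 1 / L^2) +
                     (1 / (2 * r)) * log(L / U) +
                     (sj^2 / (4 * r)) * (1 / L^2 - 1 / U^2))
    term[rho[i] >= U] <- 0
    I[i] <- sum(term)
  }
  inv <- 1 / rho - I
  R <- ifelse(inv > 1e-3, 1 / inv, 1000)
  pmax(R, rho)
}

## GB polar solvation free energy (kcal/mol) for one conformation
.gb_polar <- function(xyz, charge, element, dielectric) {
  if (all(charge == 0)) return(0)
  R <- .born_radii(xyz, element)
  D2 <- as.matrix(stats::dist(xyz))^2
  RR <- outer(R, R)
  fgb <- sqrt(D2 + RR * exp(-D2 / (4 * RR)))
  qq <- outer(charge, charge)
  -0.5 * .COULOMB * (1 - 1 / dielectric) * sum(qq / fgb)
}

#' GB/SA solvation free energy of a conformation
#'
#' Returns the solvation free energy: the generalized Born polar term at
#' the solvent's dielectric constant plus the uniform
#' atomic-solvation-parameter times total accessible surface area. With
#' all-zero partial charges the polar term vanishes and the result is
#' exactly sigma x ASA.
#'
#' @param mol a prepared, charged \code{Molecule}.
#' @param xyz n x 3 coordinate matrix of the conformation.
#' @param solvent \code{"wat"} or \code{"mem"}.
#' @param params see \code{\link{solvationParams}}.
#' @param asaPerAtom optional precomputed per-atom ASA (A^2) to reuse.
#' @return solvation free energy in kcal/mol.
#' @export
gbsaEnergy <- function(mol, xyz = NULL, solvent = c("wat", "mem"),
                       params = solvationParams(), asaPerAtom = NULL) {
  solvent <- match.arg(solvent)
  xyz <- xyz %||% coords(mol)
  charge <- mol@atoms$charge
  if (any(!is.finite(charge)))
    .stopf("molecule '%s' has missing partial charges", mol@id)
  el <- mol@atoms$element
  if (is.null(asaPerAtom)) {
    radii <- .VDW_RADIUS[el]
    if (anyNA(radii))
      .stopf("no vdW radius for element(s): %s",
             paste(unique(el[is.na(radii)]), collapse = ", "))
    asaPerAtom <- asa_cpp(xyz, radii, probe = params$probe,
                          npoints = params$asaPoints)
  }
  sigma <- if (solvent == "wat") params$sigmaWater else params$sigmaMembrane
  eps <- if (solvent == "wat") params$dielectricWater else
    params$dielectricMembrane
  .gb_polar(xyz, charge, el, eps) + sigma / 1000 * sum(asaPerAtom)
}

#' Fill water and membrane energies of an ensemble
#'
#' For each cluster representative computes E_solv = E_vac + dG_GBSA in
#' water and in membrane. The per-atom ASA (shared by both phases) is
#' cached in the ensemble metadata for descriptor reuse.
#'
#' @param ens a \code{\linkS4class{ConformerEnsemble}}.
#' @param params see \code{\link{solvationParams}}.
#' @return the ensemble with \code{eWat}/\code{eMem} filled.
#' @export
addSolvationEnergies <- function(ens, params = solvationParams()) {
  mol <- ens@molecule
  el <- mol@atoms$element
  radii <- .VDW_RADIUS[el]
  asa <- lapply(ens@coords, function(xyz)
    asa_cpp(xyz, radii, probe = params$probe, npoints = params$asaPoints))
  ens@eWat <- vapply(seq_along(ens@coords), function(k)
    ens@eVac[k] + gbsaEnergy(mol, ens@coords[[k]], "wat", params,
                             asaPerAtom = asa[[k]]), 0)
  ens@eMem <- vapply(seq_along(ens@coords), function(k)
    ens@eVac[k] + gbsaEnergy(mol, ens@coords[[k]], "mem", params,
                             asaPerAtom = asa[[k]]), 0)
  ens@meta$asaPerAtom <- asa
  ens@meta$solvation <- params
  ens
}

#' Boltzmann conformer fractions in a solvent
#'
#' d(a) = n(a) exp(-E(a)/kT) / sum_b n(b) exp(-E(b)/kT), computed with the
#' maximum energy subtracted so that it is overflow-safe for arbitrary
#' energy scales. Degeneracies act as prefactors; \code{forceN1 = TRUE}
#' replaces all degeneracies by 1 (ablation of the degeneracy estimate).
#'
#' @param ens a solvated \code{\linkS4class{ConformerEnsemble}}.
#' @param solvent \code{"wat"} or \code{"mem"}.
#' @param params see \code{\link{solvationParams}}.
#' @param forceN1 ignore degeneracies.
#' @return numeric probability vector summing to 1.
#' @export
boltzmannFractions <- function(ens, solvent = c("wat", "mem"),
                               params = solvationParams(),
                               forceN1 = FALSE) {
  solvent <- match.arg(solvent)
  E <- if (solvent == "wat") ens@eWat else ens@eMem
  if (length(E) == 0) .stopf("empty ensemble")
  if (any(!is.finite(E)))
    .stopf("solvent energies not filled; call addSolvationEnergies() first")
  n <- if (forceN1) rep(1, length(E)) else as.numeric(ens@degeneracy)
  kt <- .kbt(params$temperature)
  w <- log(n) - E / kt
  w <- exp(w - max(w))
  w / sum(w)
}

.logsumexp10 <- function(loge) {
  ## log10 of sum(exp(loge)) with loge in natural-log domain
  m <- max(loge)
  (m + log(sum(exp(loge - m)))) / log(10)
}

#' Partition-function LogD between membrane and water
#'
#' LogD = Log10[ sum_b n(b) exp(-E_mem(b)/kT) / sum_b n(b) exp(-E_wat(b)/kT) ],
#' the ratio of the conformer partition functions in the low-dielectric
#' (membrane/octanol) and water phases. Overflow-safe; invariant under a
#' constant shift applied to all energies in both phases.
#'
#' @inheritParams boltzmannFractions
#' @return unitless Log10 distribution coefficient.
#' @export
computeLogD <- function(ens, params = solvationParams(), forceN1 = FALSE) {
  if (length(ens@eWat) == 0) .stopf("empty ensemble")
  if (any(!is.finite(ens@eWat)) || any(!is.finite(ens@eMem)))
    .stopf("solvent energies not filled; call addSolvationEnergies() first")
  n <- if (forceN1) rep(1, length(ens@eVac)) else as.numeric(ens@degeneracy)
  kt <- .kbt(params$temperature)
  .logsumexp10(log(n) - ens@eMem / kt) -
    .logsumexp10(log(n) - ens@eWat / kt)
}
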
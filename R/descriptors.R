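## Descriptor computation: per-conformer properties (radius of gyration,
## atom-typed ASA, intramolecular hydrogen bonds), conformer-independent
## descriptors (MACCS keys, hydrogen charges, counts), Boltzmann ensemble
## statistics and the diffusion feature block.

#' Radius of a conformation
#'
#' The solute radius entering the diffusion features is the heavy-atom
#' radius of gyration about the heavy-atom centroid: rotation- and
#' translation-invariant and monotone with molecular size.
#'
#' @param xyz n x 3 coordinate matrix.
#' @param heavy logical or integer index of heavy atoms (default: all rows).
#' @return radius in Angstrom.
#' @export
conformerRadius <- function(xyz, heavy = NULL) {
  if (!is.null(heavy)) xyz <- xyz[heavy, , drop = FALSE]
  ctr <- colMeans(xyz)
  sqrt(mean(rowSums(sweep(xyz, 2, ctr)^2)))
}

#' Accessible surface area aggregated by Sybyl atom type
#'
#' Numeric (Shrake-Rupley) solvent-accessible surface area per atom with a
#' deterministic sphere-point set, summed over a fixed Sybyl atom-type
#' inventory so that every molecule yields the same named layout; types
#' outside the inventory fall into \code{"Other"}.
#'
#' @param mol a prepared \code{Molecule}.
#' @param xyz conformation (default: the molecule's coordinates).
#' @param probe probe radius in Angstrom.
#' @param npoints sphere points per atom.
#' @param perAtom optional precomputed per-atom ASA to aggregate.
#' @return named numeric vector over the type inventory (A^2); its sum is
#'   the total molecular ASA.
#' @export
atomtypeAsa <- function(mol, xyz = NULL, probe = 1.4, npoints = 240,
                        perAtom = NULL) {
  xyz <- xyz %||% coords(mol)
  el <- mol@atoms$element
  if (is.null(perAtom)) {
    radii <- .VDW_RADIUS[el]
    if (anyNA(radii))
      .stopf("no vdW radius for element(s): %s",
             paste(unique(el[is.na(radii)]), collapse = ", "))
    perAtom <- asa_cpp(xyz, radii, probe = probe, npoints = npoints)
  }
  ct <- .canon_type(mol@atoms$type)
  out <- stats::setNames(numeric(length(.SYBYL_TYPES)), .SYBYL_TYPES)
  agg <- tapply(perAtom, ct, sum)
  out[names(agg)] <- agg
  out
}

#' Count intramolecular hydrogen bonds in a conformation
#'
#' Donors are hydrogens bound to O or N; acceptors are O, N and S atoms
#' (lone-pair carriers). A hydrogen bond is counted when the H...acceptor
#' distance is at most \code{distCut}, the donor-H...acceptor angle at the
#' hydrogen is at least \code{angleCut}, and the donor heavy atom and the
#' acceptor are at least three bonds apart (which excludes an atom
#' accepting from its own hydrogen).
#'
#' @param mol a prepared \code{Molecule} with explicit hydrogens.
#' @param xyz conformation (default: the molecule's coordinates).
#' @param distCut H...acceptor cutoff in Angstrom (default 2.5).
#' @param angleCut donor-H...acceptor angle cutoff in degrees (default 120).
#' @return integer count.
#' @export
countIntramolecularHbonds <- function(mol, xyz = NULL, distCut = 2.5,
                                      angleCut = 120) {
  xyz <- xyz %||% coords(mol)
  at <- mol@atoms
  bd <- mol@bonds
  ## hydrogen -> its single heavy neighbor
  hyd <- which(at$element == "H")
  if (length(hyd) == 0) return(0L)
  partner <- integer(nrow(at))
  for (e in seq_len(nrow(bd))) {
    if (at$element[bd$i[e]] == "H") partner[bd$i[e]] <- bd$j[e]
    if (at$element[bd$j[e]] == "H") partner[bd$j[e]] <- bd$i[e]
  }
  donors <- hyd[at$element[partner[hyd]] %in% c("O", "N")]
  acceptors <- which(at$element %in% c("O", "N", "S"))
  if (length(donors) == 0 || length(acceptors) == 0) return(0L)
  sep <- .bond_separation(mol)
  count <- 0L
  for (h in donors) {
    d <- partner[h]
    for (a in acceptors) {
      if (a == d || sep[d, a] < 3) next
      v_ha <- xyz[a, ] - xyz[h, ]
      r <- sqrt(sum(v_ha^2))
      if (r > distCut) next
      v_hd <- xyz[d, ] - xyz[h, ]
      cosang <- sum(v_ha * v_hd) / (r * sqrt(sum(v_hd^2)))
      ang <- acos(pmin(1, pmax(-1, cosang))) * 180 / pi
      if (ang >= angleCut) count <- count + 1L
    }
  }
  count
}

## MACCS 166 keys through OpenBabel
.maccs_keys <- function(mol) {
  fin <- tempfile(fileext = ".mol2")
  on.exit(unlink(fin), add = TRUE)
  .write_mol2(mol, fin)
  txt <- paste(readLines(fin, warn = FALSE), collapse = "\n")
  obm <- ChemmineOB::forEachMol("MOL2", txt, identity)
  fp <- ChemmineOB::fingerprint_OB(obm, "MACCS")
  as.integer(fp[1:166] != 0)
}

#' Conformer-independent descriptors
#'
#' MACCS 166 structural keys; q(OH) and q(NH), the maximum hydrogen partial
#' charge over O-H and N-H hydrogens (0 when the group is absent); and the
#' atom, rotatable-bond, hydrogen-donor and hydrogen-acceptor counts.
#' Donors are O/N atoms bearing at least one hydrogen; acceptors are O, N
#' and S atoms excluding quaternary nitrogen.
#'
#' @param mol a prepared, charged \code{Molecule}.
#' @return list with \code{maccs} (integer vector of length 166),
#'   \code{q_OH}, \code{q_NH}, \code{N_atom}, \code{N_rot}, \code{N_HA},
#'   \code{N_HD}.
#' @export
staticDescriptors <- function(mol) {
  at <- mol@atoms
  bd <- mol@bonds
  partner <- integer(nrow(at))
  for (e in seq_len(nrow(bd))) {
    if (at$element[bd$i[e]] == "H") partner[bd$i[e]] <- bd$j[e]
    if (at$element[bd$j[e]] == "H") partner[bd$j[e]] <- bd$i[e]
  }
  hyd <- which(at$element == "H")
  oh <- hyd[at$element[partner[hyd]] == "O"]
  nh <- hyd[at$element[partner[hyd]] == "N"]
  q_OH <- if (length(oh)) max(at$charge[oh]) else 0
  q_NH <- if (length(nh)) max(at$charge[nh]) else 0
  donors <- unique(partner[c(oh, nh)])
  acceptors <- which(at$element %in% c("O", "N", "S") & at$type != "N.4")
  list(maccs = .maccs_keys(mol),
       q_OH = q_OH, q_NH = q_NH,
       N_atom = nrow(at),
       N_rot = countRotatableBonds(mol),
       N_HA = length(acceptors),
       N_HD = length(donors))
}

#' Boltzmann-weighted ensemble mean and deviation
#'
#' <A> = sum_a d(a) A(a); sigma(A) = sqrt(sum_a d(a) (A(a) - <A>)^2). The
#' square root is applied so that sigma carries the units of A (a
#' deviation, not a variance).
#'
#' @param values per-conformer property values.
#' @param weights normalized ensemble weights (see
#'   \code{\link{boltzmannFractions}}).
#' @return c(mean, sd).
#' @export
ensembleStats <- function(values, weights) {
  if (length(values) != length(weights))
    .stopf("values (%d) and weights (%d) differ in length",
           length(values), length(weights))
  m <- sum(weights * values)
  s <- sqrt(max(0, sum(weights * (values - m)^2)))
  c(mean = m, sd = s)
}

#' Diffusion feature block from the ensemble radius
#'
#' The total diffusion resistance combines a viscous part (proportional to
#' the radius R) and an inertial part (proportional to the cross-section,
#' R^2); the log of the combined diffusion expands into a series in R whose
#' truncation gives the feature block <R>, <R>^2, <R>^3, Log10<R> plus the
#' ensemble deviation sigma(R). Ablation flags drop any subset, and
#' \code{"R4"} extends the series with <R>^4.
#'
#' @param meanR ensemble mean radius (Angstrom, > 0).
#' @param sdR ensemble radius deviation.
#' @param ablate character subset of \code{c("R", "R2", "R3", "logR",
#'   "sigmaR")} to drop, optionally plus \code{"R4"} to add the
#'   fourth-order term.
#' @return named numeric vector.
#' @export
diffusionFeatures <- function(meanR, sdR, ablate = character()) {
  if (!is.finite(meanR) || meanR <= 0)
    .stopf("mean radius must be positive (got %s)", format(meanR))
  out <- c(R = meanR, R2 = meanR^2, R3 = meanR^3,
           logR = log10(meanR), sigmaR = sdR)
  if ("R4" %in% ablate) out <- c(out, R4 = meanR^4)
  drop <- setdiff(ablate, "R4")
  out[setdiff(names(out), drop)]
}

#' Ensemble descriptors of a solvated conformer ensemble
#'
#' Computes, for both the water and the membrane weighting, the Boltzmann
#' mean and deviation of the conformer radius, the mean intramolecular
#' hydrogen-bond count and the mean atom-typed ASA; the per-conformer
#' LogD(a) = -(E_mem(a) - E_wat(a)) / (kT ln 10) averaged under water
#' weights; the ensemble partition-function LogD; and the
#' conformer-independent descriptors. This is the complete input for the
#' QSPR feature layouts.
#'
#' @param ens a solvated \code{\linkS4class{ConformerEnsemble}}.
#' @param params see \code{\link{solvationParams}}.
#' @param hbondDist,hbondAngle hydrogen-bond cutoffs.
#' @param forceN1 ignore degeneracies in all ensemble weights.
#' @return object of class \code{"EnsembleDescriptors"}: a named list with
#'   elements \code{id}, \code{logd_conf} (mean/sd of per-conformer LogD
#'   under water weights), \code{logD}, per-solvent statistics \code{R},
#'   \code{B}, \code{asa}, and \code{static}.
#' @export
ensembleDescriptors <- function(ens, params = solvationParams(),
                                hbondDist = 2.5, hbondAngle = 120,
                                forceN1 = FALSE) {
  mol <- ens@molecule
  if (any(!is.finite(ens@eWat))) ens <- addSolvationEnergies(ens, params)
  heavy <- which(mol@atoms$element != "H")
  kt <- .kbt(params$temperature)

  dwat <- boltzmannFractions(ens, "wat", params, forceN1 = forceN1)
  dmem <- boltzmannFractions(ens, "mem", params, forceN1 = forceN1)

  ## Property statistics are evaluated over every accepted sample: each
  ## cluster member inherits an equal share d(a)/n(a) of its cluster's
  ## Boltzmann weight. This is the cluster-mean reading of the ensemble
  ## averages and keeps the intra-cluster geometric spread visible (a
  ## flexible chain whose conformers all fall inside one 1.5 A cluster
  ## still shows sigma(R) > 0), while rigid molecules give exactly 0.
  cl <- ens@memberCluster
  wwat <- dwat[cl] / ens@degeneracy[cl]
  wmem <- dmem[cl] / ens@degeneracy[cl]

  R <- vapply(ens@members, conformerRadius, 0, heavy = heavy)
  B <- vapply(ens@members, function(xyz)
    as.numeric(countIntramolecularHbonds(mol, xyz, hbondDist, hbondAngle)),
    0)
  asaList <- lapply(ens@members, function(xyz)
    asa_cpp(xyz, .VDW_RADIUS[mol@atoms$element], probe = params$probe,
            npoints = params$asaPoints))
  asaMat <- vapply(seq_along(ens@members), function(k)
    atomtypeAsa(mol, perAtom = asaList[[k]]),
    numeric(length(.SYBYL_TYPES)))

  ## per-conformer LogD: single-conformer closed form of the partition ratio
  logd_a <- -(ens@eMem - ens@eWat) / (kt * log(10))

  asa_mean <- function(w) drop(asaMat %*% w)

  out <- list(
    id = mol@id,
    logd_conf = ensembleStats(logd_a, dwat),
    logD = computeLogD(ens, params, forceN1 = forceN1),
    R = list(wat = ensembleStats(R, wwat), mem = ensembleStats(R, wmem)),
    B = list(wat = ensembleStats(B, wwat), mem = ensembleStats(B, wmem)),
    asa = list(wat = asa_mean(wwat), mem = asa_mean(wmem)),
    static = staticDescriptors(mol),
    mw = molecularWeight(mol),
    rings = .ring_stats(mol),
    nConformers = length(ens@coords)
  )
  class(out) <- "EnsembleDescriptors"
  out
}

#' @export
print.EnsembleDescriptors <- function(x, ...) {
  cat(sprintf(
    "EnsembleDescriptors '%s': %d clusters, LogD %.2f, <R>_wat %.2f A (sd %.2f)\n",
    x$id, x$nConformers, x$logD, x$R$wat["mean"], x$R$wat["sd"]))
  invisible(x)
}
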
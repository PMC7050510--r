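## Simplified AMBER-like force field keyed on Sybyl atom types.
##
## Purpose-built for conformer generation: harmonic bonds/angles, one
## cosine torsion per rotatable central bond, and 12-6 Lennard-Jones over
## all pairs >= 3 bonds apart (1-4 scaled by 0.5). There is deliberately no
## electrostatic term: the same conformer energies are reused in water and
## membrane whose dielectrics differ, so polarity enters only through the
## GB/SA solvation model. Parameters are generic (relative energies only).

## reference bond lengths (Angstrom) for common element pairs by order;
## fallback is the sum of single-bond covalent radii.
.BOND_R0 <- c(
  "C-C|1" = 1.526, "C-C|2" = 1.330, "C-C|3" = 1.200, "C-C|ar" = 1.390,
  "C-N|1" = 1.470, "C-N|2" = 1.280, "C-N|ar" = 1.340, "C-N|am" = 1.335,
  "C-O|1" = 1.410, "C-O|2" = 1.220, "C-O|ar" = 1.360,
  "C-S|1" = 1.810, "C-H|1" = 1.090, "N-H|1" = 1.010, "O-H|1" = 0.960,
  "S-H|1" = 1.340, "N-N|1" = 1.420, "N-N|ar" = 1.350, "N-O|1" = 1.400,
  "N-O|2" = 1.210, "O-S|2" = 1.450, "C-F|1" = 1.350, "C-Cl|1" = 1.770,
  "C-Br|1" = 1.940, "C-I|1" = 2.140, "C-P|1" = 1.830, "O-P|1" = 1.600,
  "O-P|2" = 1.480, "S-S|1" = 2.050
)

.BOND_K <- c("1" = 350, "2" = 550, "3" = 600, "ar" = 450, "am" = 450)

## per-element Lennard-Jones: rmin/2 (Angstrom) and epsilon (kcal/mol)
.LJ_RMH <- c(H = 1.387, C = 1.908, N = 1.824, O = 1.661, F = 1.75,
             P = 2.10, S = 2.00, Cl = 1.948, Br = 2.22, I = 2.35)
.LJ_EPS <- c(H = 0.0157, C = 0.1094, N = 0.17, O = 0.21, F = 0.061,
             P = 0.20, S = 0.25, Cl = 0.265, Br = 0.32, I = 0.40)

.SP3_TYPES <- c("C.3", "N.3", "N.4", "O.3", "S.3", "P.3")
.SP2_TYPES <- c("C.2", "C.ar", "C.cat", "N.2", "N.ar", "N.am", "N.pl3",
                "O.co2", "S.2")
.SP1_TYPES <- c("C.1", "N.1")

.bond_r0 <- function(e1, e2, order) {
  key <- paste0(pmin(e1, e2), "-", pmax(e1, e2), "|", order)
  r0 <- .BOND_R0[key]
  fb <- .COV_RADIUS[e1] + .COV_RADIUS[e2]
  ifelse(is.na(r0), fb, r0)
}

.angle_theta0 <- function(type) {
  ifelse(type %in% .SP1_TYPES, pi,
         ifelse(type %in% .SP2_TYPES, 120 * pi / 180,
                109.47 * pi / 180))
}

## one torsion parameter set per central bond, from the hybridization of
## the two central atoms (and the bond order for amide/aromatic)
.torsion_par <- function(t1, t2, order) {
  if (order %in% c("ar", "am", "2"))
    return(c(V = 8, n = 2, gamma = pi))
  sp3a <- t1 %in% .SP3_TYPES; sp3b <- t2 %in% .SP3_TYPES
  if (sp3a && sp3b) return(c(V = 1.4, n = 3, gamma = 0))
  sp2a <- t1 %in% .SP2_TYPES; sp2b <- t2 %in% .SP2_TYPES
  if (sp2a && sp2b) return(c(V = 4, n = 2, gamma = pi))
  if ((sp3a && sp2b) || (sp2a && sp3b)) return(c(V = 0.3, n = 6, gamma = 0))
  NULL
}

.empty_mat <- function(k) matrix(numeric(0), 0, k)

## Build force-field term tables for a molecule. `drop` is an m x 2 matrix
## of opened (removed) bonds: their bond terms and any angle/torsion using
## them are omitted and harmonic closure restraints (force constant
## `restraintK`, equilibrium = reference bond length) are emitted instead.
## Nonbonded exclusions always come from the FULL graph, so atoms across an
## opened bond keep their 1-2/1-3 exclusions and ring closure is possible.
.ff_terms <- function(mol, drop = NULL, restraintK = 100) {
  at <- mol@atoms
  bd <- mol@bonds
  n <- nrow(at)
  el <- at$element
  ty <- at$type

  key <- paste(pmin(bd$i, bd$j), pmax(bd$i, bd$j))
  dropped <- rep(FALSE, nrow(bd))
  if (!is.null(drop) && nrow(drop) > 0) {
    dk <- paste(pmin(drop[, 1], drop[, 2]), pmax(drop[, 1], drop[, 2]))
    dropped <- key %in% dk
  }

  r0 <- .bond_r0(el[bd$i], el[bd$j], bd$order)
  kb <- .BOND_K[bd$order]
  kb[is.na(kb)] <- 350
  bonds <- cbind(bd$i, bd$j, kb, r0)[!dropped, , drop = FALSE]
  restraints <- if (any(dropped))
    cbind(bd$i[dropped], bd$j[dropped], restraintK, r0[dropped])
  else .empty_mat(4)

  ## adjacency of the working (possibly opened) graph
  adj <- vector("list", n)
  wi <- bd$i[!dropped]; wj <- bd$j[!dropped]
  for (e in seq_along(wi)) {
    adj[[wi[e]]] <- c(adj[[wi[e]]], wj[e])
    adj[[wj[e]]] <- c(adj[[wj[e]]], wi[e])
  }

  ## angles: every pair of neighbors around each center
  ang <- vector("list", n)
  for (c0 in seq_len(n)) {
    nb <- adj[[c0]]
    if (length(nb) < 2) next
    cmb <- utils::combn(sort(nb), 2)
    kth <- if (el[c0] == "H") 35 else
      ifelse(el[cmb[1, ]] == "H" | el[cmb[2, ]] == "H", 35, 63)
    ang[[c0]] <- cbind(cmb[1, ], c0, cmb[2, ], kth, .angle_theta0(ty[c0]))
  }
  angles <- do.call(rbind, ang) %||% .empty_mat(5)
  if (is.null(angles)) angles <- .empty_mat(5)

  ## torsions: one per central working bond with >= 1 extra neighbor on
  ## each side; reference path = lowest-index heavy neighbor (else H)
  tor <- list()
  pick_ref <- function(center, other) {
    nb <- setdiff(adj[[center]], other)
    if (length(nb) == 0) return(NA_integer_)
    heavy <- nb[el[nb] != "H"]
    if (length(heavy)) min(heavy) else min(nb)
  }
  worder <- bd$order[!dropped]
  for (e in seq_along(wi)) {
    a <- pick_ref(wi[e], wj[e])
    b <- pick_ref(wj[e], wi[e])
    if (is.na(a) || is.na(b)) next
    par <- .torsion_par(ty[wi[e]], ty[wj[e]], worder[e])
    if (is.null(par)) next
    tor[[length(tor) + 1]] <- c(a, wi[e], wj[e], b, par)
  }
  torsions <- if (length(tor)) do.call(rbind, tor) else .empty_mat(7)

  ## nonbonded pairs from FULL-graph separations
  sep <- .bond_separation(mol)
  idx <- which(upper.tri(sep) & (sep >= 3 | is.infinite(sep)), arr.ind = TRUE)
  if (nrow(idx) > 0) {
    scale <- ifelse(sep[idx] == 3, 0.5, 1.0)
    rm <- .LJ_RMH[el[idx[, 1]]] + .LJ_RMH[el[idx[, 2]]]
    eps <- sqrt(.LJ_EPS[el[idx[, 1]]] * .LJ_EPS[el[idx[, 2]]]) * scale
    pairs <- cbind(idx[, 1], idx[, 2], rm, eps)
  } else pairs <- .empty_mat(4)

  list(bonds = bonds, angles = angles, torsions = torsions, pairs = pairs,
       restraints = restraints, n = n)
}

.ff_eval <- function(xyz, ff) {
  ff_eval_cpp(as.numeric(t(xyz)), ff$bonds, ff$angles, ff$torsions,
              ff$pairs, ff$restraints)
}

#' Force-field energy of a conformation
#'
#' Evaluates the package's simplified AMBER-like potential: bonds, angles,
#' torsions and 12-6 van der Waals over all pairs separated by at least
#' three bonds (1-4 pairs scaled by 0.5). There is no electrostatic term.
#' Overlapping atoms receive a large but finite capped repulsion.
#'
#' @param mol a prepared \code{Molecule}.
#' @param xyz optional n x 3 coordinate matrix (default: the molecule's own
#'   coordinates).
#' @return energy in kcal/mol.
#' @export
ffEnergy <- function(mol, xyz = NULL) {
  xyz <- xyz %||% coords(mol)
  stopifnot(all(is.finite(xyz)))
  .ff_eval(xyz, .ff_terms(mol))$energy
}

## L-BFGS-B minimization; convergence when the largest gradient component
## falls below `pgtol` (kcal/mol/Angstrom) or after `maxit` iterations.
.minimize <- function(xyz, ff, maxit = 2000, pgtol = 0.05) {
  fn <- function(par) ff_eval_cpp(par, ff$bonds, ff$angles, ff$torsions,
                                  ff$pairs, ff$restraints)$energy
  gr <- function(par) ff_eval_cpp(par, ff$bonds, ff$angles, ff$torsions,
                                  ff$pairs, ff$restraints)$gradient
  res <- stats::optim(as.numeric(t(xyz)), fn, gr, method = "L-BFGS-B",
                      control = list(maxit = maxit, pgtol = pgtol,
                                     factr = 1e5))
  list(coords = matrix(res$par, ncol = 3, byrow = TRUE),
       energy = res$value, convergence = res$convergence)
}
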
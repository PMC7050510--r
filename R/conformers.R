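## Conformer-ensemble generation: Monte-Carlo dihedral sampling with ring
## opening/closure under the package force field, and degeneracy estimation
## by greedy heavy-atom-RMSD clustering.

#' Open ring systems for dihedral sampling
#'
#' Transforms ring systems into open chains by removing one bond per
#' independent ring cycle, so that random dihedral sampling can reach ring
#' conformations; a restrained energy minimization recloses the rings
#' afterwards. Only plain single bonds are broken: aromatic, double, triple
#' and amide bonds are protected, and a ring containing no breakable bond
#' is kept intact (it contributes no sampled dihedrals) with a warning.
#' Among breakable bonds the one whose atoms carry the fewest heavy
#' substituents is chosen, ties resolved by lowest atom-index pair.
#'
#' @param mol a prepared \code{Molecule}.
#' @return list with \code{drop} (m x 2 matrix of removed bonds, m >= 0),
#'   \code{r0} (their reference lengths, for the closure restraint and
#'   check) and \code{rigidRings} (count of unbreakable rings).
#' @export
openRings <- function(mol) {
  bd <- mol@bonds
  hdeg <- .heavy_degree(mol)
  el <- mol@atoms$element
  drop <- matrix(integer(0), 0, 2)
  given_up <- character(0)
  rigid <- 0L
  repeat {
    cyc <- .ring_bonds_opened(mol, drop)
    if (length(cyc) == 0) break
    progressed <- FALSE
    for (edges in cyc) {
      ckey <- paste(sort(edges$key), collapse = ";")
      if (ckey %in% given_up) next
      ok <- edges$order == "1" & el[edges$i] != "H" & el[edges$j] != "H"
      if (!any(ok)) {
        given_up <- c(given_up, ckey)
        rigid <- rigid + 1L
        next
      }
      cand <- which(ok)
      score <- hdeg[edges$i[cand]] + hdeg[edges$j[cand]]
      cand <- cand[order(score, pmin(edges$i[cand], edges$j[cand]),
                         pmax(edges$i[cand], edges$j[cand]))]
      e <- cand[1]
      drop <- rbind(drop, c(edges$i[e], edges$j[e]))
      progressed <- TRUE
      break
    }
    if (!progressed) break
  }
  if (rigid > 0)
    .warnf("molecule '%s': %d ring(s) have no breakable bond; kept rigid",
           mol@id, rigid)
  r0 <- if (nrow(drop)) .bond_r0(el[drop[, 1]], el[drop[, 2]], "1")
        else numeric(0)
  list(drop = drop, r0 = unname(r0), rigidRings = rigid)
}

## cycle basis of the working graph (mol bonds minus `drop`), described per
## cycle by the member bonds' endpoints/orders/keys
.ring_bonds_opened <- function(mol, drop) {
  work <- mol
  if (nrow(drop) > 0) {
    key <- paste(pmin(work@bonds$i, work@bonds$j),
                 pmax(work@bonds$i, work@bonds$j))
    dk <- paste(pmin(drop[, 1], drop[, 2]), pmax(drop[, 1], drop[, 2]))
    work@bonds <- work@bonds[!key %in% dk, , drop = FALSE]
  }
  cyc <- .ring_bonds(work)
  lapply(cyc, function(e) list(
    i = work@bonds$i[e], j = work@bonds$j[e],
    order = work@bonds$order[e],
    key = paste(pmin(work@bonds$i[e], work@bonds$j[e]),
                pmax(work@bonds$i[e], work@bonds$j[e]))))
}

## Rodrigues rotation of `pts` (k x 3) about the axis a -> b by angle phi.
.rotate_about <- function(pts, a, b, phi) {
  u <- b - a
  u <- u / sqrt(sum(u^2))
  cph <- cos(phi); sph <- sin(phi)
  rel <- sweep(pts, 2, a)
  dotp <- drop(rel %*% u)
  crossp <- cbind(u[2] * rel[, 3] - u[3] * rel[, 2],
                  u[3] * rel[, 1] - u[1] * rel[, 3],
                  u[1] * rel[, 2] - u[2] * rel[, 1])
  rot <- rel * cph + crossp * sph +
    outer(dotp * (1 - cph), u)
  sweep(rot, 2, a, `+`)
}

## atoms on the j-side of working bond (i, j): BFS from j never crossing i
.subtree_atoms <- function(adj, i, j) {
  seen <- c(i, j)
  queue <- j
  out <- j
  while (length(queue)) {
    v <- queue[[1]]; queue <- queue[-1]
    nb <- setdiff(adj[[v]], seen)
    seen <- c(seen, nb)
    out <- c(out, nb)
    queue <- c(queue, nb)
  }
  unique(out)
}

#' Sample conformers by Monte-Carlo dihedral randomization
#'
#' Each sample draws every rotatable dihedral (including those freed by
#' ring opening) uniformly on [0, 360) degrees, then energy-minimizes:
#' first under harmonic ring-closure restraints ramped over three stages,
#' then under the full force field with the real ring bonds restored. A
#' sample is accepted when every reopened bond is within 10 percent of its
#' reference length and no heavy-atom nonbonded pair is closer than 1.5
#' Angstrom; failures are discarded and counted. A molecule with no
#' rotatable dihedrals returns its single minimized conformation
#' regardless of \code{nSamples}.
#'
#' @param mol a prepared \code{Molecule}.
#' @param nSamples number of Monte-Carlo samples (>= 1).
#' @param seed integer seed; together with \code{nSamples} it fully
#'   determines the output.
#' @return list with \code{coords} (list of n x 3 matrices), \code{eVac}
#'   (kcal/mol), \code{nAccepted}, \code{nFailed}, \code{opened} (the
#'   \code{\link{openRings}} result).
#' @export
sampleConformers <- function(mol, nSamples = 100, seed = 1) {
  stopifnot(nSamples >= 1)
  opened <- openRings(mol)
  drop <- opened$drop
  dih <- .sampling_dihedrals(mol, if (nrow(drop)) drop else NULL)
  ff_full <- .ff_terms(mol)
  start <- coords(mol)

  if (length(dih) == 0 && nrow(drop) == 0) {
    res <- .minimize(start, ff_full)
    return(list(coords = list(res$coords), eVac = res$energy,
                nAccepted = 1L, nFailed = 0L, opened = opened))
  }

  bd <- mol@bonds
  ## working-graph adjacency for subtree extraction
  key <- paste(pmin(bd$i, bd$j), pmax(bd$i, bd$j))
  keep <- rep(TRUE, nrow(bd))
  if (nrow(drop) > 0) {
    dk <- paste(pmin(drop[, 1], drop[, 2]), pmax(drop[, 1], drop[, 2]))
    keep <- !key %in% dk
  }
  n <- nrow(mol@atoms)
  adj <- vector("list", n)
  for (e in which(keep)) {
    adj[[bd$i[e]]] <- c(adj[[bd$i[e]]], bd$j[e])
    adj[[bd$j[e]]] <- c(adj[[bd$j[e]]], bd$i[e])
  }
  subtrees <- lapply(dih, function(e) .subtree_atoms(adj, bd$i[e], bd$j[e]))

  heavy <- which(mol@atoms$element != "H")
  has_rings <- nrow(drop) > 0
  ff_stage <- NULL
  if (has_rings)
    ff_stage <- lapply(c(10, 50, 200), function(k)
      .ff_terms(mol, drop = drop, restraintK = k))

  out_coords <- list()
  out_e <- numeric(0)
  nfail <- 0L

  .with_seed(seed, {
    for (s in seq_len(nSamples)) {
      xyz <- start
      for (d in seq_along(dih)) {
        phi <- stats::runif(1, 0, 2 * pi)
        e <- dih[[d]]
        xyz[subtrees[[d]], ] <- .rotate_about(
          xyz[subtrees[[d]], , drop = FALSE],
          xyz[bd$i[e], ], xyz[bd$j[e], ], phi)
      }
      if (has_rings) {
        for (ffs in ff_stage) xyz <- .minimize(xyz, ffs, maxit = 400)$coords
      }
      res <- .minimize(xyz, ff_full)
      xyz <- res$coords
      if (has_rings) {
        dl <- sqrt(rowSums((xyz[drop[, 1], , drop = FALSE] -
                              xyz[drop[, 2], , drop = FALSE])^2))
        if (any(abs(dl - opened$r0) / opened$r0 > 0.10)) {
          nfail <- nfail + 1L
          next
        }
      }
      if (.min_nonbonded_heavy(xyz, ff_full, heavy) < 1.5) {
        nfail <- nfail + 1L
        next
      }
      out_coords[[length(out_coords) + 1]] <- xyz
      out_e <- c(out_e, res$energy)
    }
  })
  if (length(out_coords) == 0)
    .stopf("molecule '%s': all %d samples failed ring closure",
           mol@id, nSamples)
  list(coords = out_coords, eVac = out_e,
       nAccepted = length(out_coords), nFailed = nfail, opened = opened)
}

## smallest distance among heavy-atom pairs >= 3 bonds apart
.min_nonbonded_heavy <- function(xyz, ff_full, heavy) {
  pr <- ff_full$pairs
  if (nrow(pr) == 0) return(Inf)
  sel <- pr[, 1] %in% heavy & pr[, 2] %in% heavy
  if (!any(sel)) return(Inf)
  i <- pr[sel, 1]; j <- pr[sel, 2]
  min(sqrt(rowSums((xyz[i, , drop = FALSE] - xyz[j, , drop = FALSE])^2)))
}

## Kabsch-superposed RMSD between two k x 3 coordinate sets.
.kabsch_rmsd <- function(X, Y) {
  X <- sweep(X, 2, colMeans(X))
  Y <- sweep(Y, 2, colMeans(Y))
  s <- svd(crossprod(X, Y))
  d <- sign(det(s$u %*% t(s$v)))
  ssd <- sum(X^2) + sum(Y^2) - 2 * sum(s$d * c(1, 1, d))
  sqrt(max(0, ssd) / nrow(X))
}

#' Cluster conformers and estimate degeneracies
#'
#' Greedy leader clustering on heavy-atom RMSD (after optimal
#' superposition): conformers are visited in order of increasing vacuum
#' energy; each either joins the first existing cluster whose
#' representative is within \code{threshold}, or founds a new cluster. The
#' representative of a cluster is therefore its lowest-energy member, and
#' the cluster size is the degeneracy n(a).
#'
#' @param samples result of \code{\link{sampleConformers}}.
#' @param mol the parent prepared \code{Molecule}.
#' @param threshold heavy-atom RMSD threshold in Angstrom (default 1.5).
#' @param seed seed recorded on the ensemble.
#' @return a \code{\linkS4class{ConformerEnsemble}}.
#' @export
clusterDegeneracy <- function(samples, mol, threshold = 1.5, seed = 1L) {
  stopifnot(length(samples$coords) >= 1)
  heavy <- which(mol@atoms$element != "H")
  ord <- order(samples$eVac)
  leaders <- integer(0)
  sizes <- integer(0)
  assign_cl <- integer(length(samples$coords))
  for (s in ord) {
    placed <- FALSE
    for (k in seq_along(leaders)) {
      r <- .kabsch_rmsd(samples$coords[[leaders[k]]][heavy, , drop = FALSE],
                        samples$coords[[s]][heavy, , drop = FALSE])
      if (r < threshold) {
        sizes[k] <- sizes[k] + 1L
        assign_cl[s] <- k
        placed <- TRUE
        break
      }
    }
    if (!placed) {
      leaders <- c(leaders, s)
      sizes <- c(sizes, 1L)
      assign_cl[s] <- length(leaders)
    }
  }
  k <- length(leaders)
  new("ConformerEnsemble",
      molecule = mol,
      coords = samples$coords[leaders],
      eVac = samples$eVac[leaders],
      eWat = rep(NA_real_, k), eMem = rep(NA_real_, k),
      degeneracy = sizes,
      nGenerated = length(samples$coords),
      members = samples$coords,
      memberCluster = assign_cl,
      seed = as.integer(seed),
      meta = list(threshold = threshold, nFailed = samples$nFailed,
                  rigidRings = samples$opened$rigidRings))
}

#' Generate a clustered conformer ensemble
#'
#' Convenience wrapper: \code{\link{sampleConformers}} followed by
#' \code{\link{clusterDegeneracy}}.
#'
#' @inheritParams sampleConformers
#' @inheritParams clusterDegeneracy
#' @return a \code{\linkS4class{ConformerEnsemble}}.
#' @examples
#' \donttest{
#' f <- tempfile(fileext = ".smi")
#' writeLines("c1ccccc1\tbenzene", f)
#' mol <- prepareMolecule(readMolecules(f)[[1]])
#' ens <- generateEnsemble(mol, nSamples = 10, seed = 1)
#' degeneracy(ens)  # rigid molecule: a single cluster
#' }
#' @export
generateEnsemble <- function(mol, nSamples = 100, seed = 1,
                             threshold = 1.5) {
  s <- sampleConformers(mol, nSamples = nSamples, seed = seed)
  clusterDegeneracy(s, mol, threshold = threshold, seed = seed)
}
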
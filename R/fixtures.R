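## Deterministic test inputs: a curated molecule panel spanning rigid
## aromatics to macrocycles and middle molecules, and a synthetic-dataset
## generator that plants a known linear model on computed descriptors so
## the whole pipeline is testable without any external data.

#' Curated fixture molecule panel
#'
#' 22 named molecules spanning the size and flexibility range relevant to
#' permeability modeling: rigid aromatics, small polar solutes, drug-like
#' molecules, flexible chains and PEG fragments, two macrocycles with
#' largest ring > 12 atoms (a crown ether and a macrolactone), and one
#' middle molecule above 500 Da (a PEG dimethyl ether).
#'
#' @return data.frame with columns \code{id} and \code{smiles}.
#' @export
fixtureMolecules <- function() {
  data.frame(
    id = c("benzene", "ethanol", "acetic_acid", "n_butane", "n_hexane",
           "cyclohexane", "toluene", "phenol", "pyridine", "aniline",
           "benzamide", "caffeine", "ibuprofen", "aspirin",
           "acetaminophen", "naproxen", "octanol", "teg", "nicotine",
           "salicylamide", "crown18", "pentadecanolide", "peg12"),
    smiles = c(
      "c1ccccc1", "CCO", "CC(=O)O", "CCCC", "CCCCCC",
      "C1CCCCC1", "Cc1ccccc1", "Oc1ccccc1", "c1ccncc1", "Nc1ccccc1",
      "NC(=O)c1ccccc1", "Cn1cnc2c1c(=O)n(C)c(=O)n2C",
      "CC(C)Cc1ccc(cc1)C(C)C(=O)O", "CC(=O)Oc1ccccc1C(=O)O",
      "CC(=O)Nc1ccc(O)cc1", "COc1ccc2cc(ccc2c1)C(C)C(=O)O",
      "CCCCCCCCO", "OCCOCCOCCO", "CN1CCCC1c1cccnc1",
      "NC(=O)c1ccccc1O", "C1COCCOCCOCCOCCOCCO1",
      "O=C1CCCCCCCCCCCCCCO1",
      paste0("CO", strrep("CCO", 11), "C")),
    stringsAsFactors = FALSE)
}

#' Prepare the fixture panel
#'
#' Parses and prepares (neutral form, hydrogens, 3D, charges) every panel
#' molecule.
#'
#' @param chargeScheme passed to \code{\link{prepareMolecule}}.
#' @return named list of prepared \code{Molecule}s.
#' @export
prepareFixturePanel <- function(chargeScheme = "gasteiger") {
  tab <- fixtureMolecules()
  f <- tempfile(fileext = ".smi")
  on.exit(unlink(f), add = TRUE)
  writeLines(paste(tab$smiles, tab$id, sep = "\t"), f)
  mols <- readMolecules(f, "smiles")
  out <- lapply(mols, prepareMolecule, chargeScheme = chargeScheme)
  names(out) <- tab$id
  out
}

## molecular size features used by the hold-out protocol
.molecule_features <- function(mol) {
  rs <- .ring_stats(mol)
  data.frame(id = mol@id, MW = molecularWeight(mol),
             N_atom = nrow(mol@atoms), N_cycle = rs$n_cycle,
             N_rot = countRotatableBonds(mol), N_ring = rs$n_ring,
             stringsAsFactors = FALSE)
}

#' Feature table of molecular size measures
#'
#' @param mols list of prepared \code{Molecule}s.
#' @return data.frame with columns \code{id}, \code{MW}, \code{N_atom},
#'   \code{N_cycle}, \code{N_rot}, \code{N_ring}.
#' @export
moleculeFeatures <- function(mols) {
  do.call(rbind, lapply(mols, .molecule_features))
}

#' Synthesize a labeled dataset with a planted linear model
#'
#' Builds an n-row descriptor table by replicating the fixture-panel
#' descriptor rows and perturbing every non-constant column with Gaussian
#' noise at half its panel standard deviation (so the synthetic rows keep
#' the real collinearity structure between e.g. ASA and LogD terms), then
#' draws sparse coefficients on standardized non-constant columns and sets
#' y = planted linear combination + intercept + Gaussian noise. The ground
#' truth is stored for recovery tests. Size features are replicated
#' alongside for hold-out splitting.
#'
#' @param nMolecules number of rows (>= 12; cross-validation is infeasible
#'   below).
#' @param X descriptor matrix to replicate (rows named by molecule id),
#'   e.g. from \code{\link{featureMatrix}}. Its rownames must appear in
#'   \code{features$id}.
#' @param features size-feature table for the same molecules.
#' @param coeffSparsity number of nonzero planted coefficients.
#' @param noiseSd response noise standard deviation.
#' @param seed integer seed; output is bit-reproducible given the seed.
#' @param sizeIndependent logical; when TRUE (default) planted
#'   coefficients avoid columns strongly rank-correlated with molecular
#'   size, so hold-out extrapolation tests a size-independent truth.
#' @return list with \code{X}, \code{y}, \code{features},
#'   \code{plantedCoef} (named, over columns of X), \code{intercept},
#'   \code{noiseSd}, \code{seed}.
#' @export
synthesizeDataset <- function(nMolecules, X, features,
                              coeffSparsity = 10, noiseSd = 0.1,
                              seed = 1, sizeIndependent = TRUE) {
  if (nMolecules < 12)
    .stopf("nMolecules = %d is too small for cross-validation (need >= 12)",
           nMolecules)
  X <- as.matrix(X)
  stopifnot(!is.null(rownames(X)), all(rownames(X) %in% features$id))
  .with_seed(seed, {
    idx <- rep_len(seq_len(nrow(X)), nMolecules)
    Xn <- X[idx, , drop = FALSE]
    rownames(Xn) <- sprintf("syn%04d", seq_len(nMolecules))
    sdv <- apply(X, 2, stats::sd)
    ## binary structural keys stay binary: only continuous, non-constant
    ## columns are perturbed (and only they receive planted coefficients)
    vary <- which(sdv > 1e-12 & !startsWith(colnames(X), "MACCS_"))
    for (j in vary)
      Xn[, j] <- Xn[, j] + stats::rnorm(nMolecules, 0, 0.5 * sdv[j])
    feats <- features[match(rownames(X)[idx], features$id), , drop = FALSE]
    feats$id <- rownames(Xn)
    rownames(feats) <- NULL

    cand <- vary
    if (sizeIndependent) {
      rk <- abs(apply(Xn[, vary, drop = FALSE], 2, function(v)
        stats::cor(v, feats$MW, method = "spearman")))
      cand <- vary[rk < 0.8 | is.na(rk)]
      if (length(cand) < coeffSparsity) cand <- vary
    }
    ## keep the planted truth identifiable: drop candidates nearly
    ## collinear (|r| >= 0.95) with an already-kept candidate, e.g. the
    ## powers of the same ensemble radius
    keep <- integer(0)
    for (j in cand) {
      if (length(keep) == 0 ||
          max(abs(stats::cor(Xn[, j], Xn[, keep, drop = FALSE]))) < 0.95)
        keep <- c(keep, j)
    }
    cand <- keep
    nz <- sort(sample(cand, min(coeffSparsity, length(cand))))
    betaStd <- stats::rnorm(length(nz))
    mu <- colMeans(Xn)[nz]
    sdn <- apply(Xn[, nz, drop = FALSE], 2, stats::sd)
    betaRaw <- betaStd / sdn
    intercept <- 0.5 - sum(betaRaw * mu)
    y <- drop(Xn[, nz, drop = FALSE] %*% betaRaw) + intercept +
      stats::rnorm(nMolecules, 0, noiseSd)
    planted <- stats::setNames(numeric(ncol(Xn)), colnames(Xn))
    planted[nz] <- betaRaw
    list(X = Xn, y = y, features = feats, plantedCoef = planted,
         intercept = intercept, noiseSd = noiseSd, seed = seed)
  })
}
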
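#' Molecule: atoms, bonds, coordinates, Sybyl types and partial charges
#'
#' Central container for a single molecule record. Atoms carry element,
#' Sybyl atom type, partial charge (e) and 3D coordinates (Angstrom); bonds
#' carry 1-based atom indices and a Sybyl order code (\code{"1"}, \code{"2"},
#' \code{"3"}, \code{"ar"}, \code{"am"}). Prepared molecules (see
#' \code{\link{prepareMolecule}}) are electrically neutral with explicit
#' hydrogens.
#'
#' @slot id single molecule identifier.
#' @slot atoms data.frame with columns \code{element}, \code{type},
#'   \code{charge}, \code{x}, \code{y}, \code{z}.
#' @slot bonds data.frame with columns \code{i}, \code{j}, \code{order}.
#' @slot formalCharge integer net formal charge (e).
#' @slot meta named list of provenance (source, charge scheme, warnings).
#'
#' @exportClass Molecule
setClass("Molecule", representation(
  id = "character",
  atoms = "data.frame",
  bonds = "data.frame",
  formalCharge = "numeric",
  meta = "list"
))

setValidity("Molecule", function(object) {
  msg <- character()
  at <- object@atoms
  need <- c("element", "type", "charge", "x", "y", "z")
  if (!all(need %in% names(at)))
    msg <- c(msg, paste("atoms must have columns", paste(need, collapse = ", ")))
  else {
    if (!all(is.finite(as.matrix(at[, c("x", "y", "z")]))))
      msg <- c(msg, "coordinates must be finite")
    if (any(!is.na(at$charge))) {
      s <- sum(at$charge)
      if (is.finite(s) && abs(s - object@formalCharge) > 1e-3)
        msg <- c(msg, sprintf(
          "partial charges sum to %.4f but formal charge is %d",
          s, as.integer(object@formalCharge)))
    }
  }
  if (nrow(object@bonds) > 0) {
    if (!all(c("i", "j", "order") %in% names(object@bonds)))
      msg <- c(msg, "bonds must have columns i, j, order")
    else if (max(object@bonds$i, object@bonds$j) > nrow(at))
      msg <- c(msg, "bond indices exceed atom count")
  }
  if (length(msg)) msg else TRUE
})

#' ConformerEnsemble: clustered conformers with degeneracies and energies
#'
#' Result of Monte-Carlo conformer generation and RMSD clustering. Each
#' cluster is represented by its lowest vacuum-energy member; the cluster
#' size is the degeneracy n(a) used as the Boltzmann prefactor. Water and
#' membrane energies (E_vac + GB/SA solvation free energy) are filled by
#' \code{\link{addSolvationEnergies}}.
#'
#' @slot molecule the parent \code{Molecule} (atom ordering shared by all
#'   conformers).
#' @slot coords list of 3-column coordinate matrices, one per cluster
#'   representative.
#' @slot eVac,eWat,eMem numeric vectors of per-conformer energies (kcal/mol);
#'   \code{eWat}/\code{eMem} may be \code{NA} until solvation is added.
#' @slot degeneracy integer cluster sizes n(a).
#' @slot nGenerated total number of accepted samples (= sum of degeneracies).
#' @slot members list of coordinate matrices of every accepted sample (the
#'   cluster members; ensemble property statistics are evaluated over them,
#'   each member carrying an equal share of its cluster's Boltzmann
#'   weight).
#' @slot memberCluster integer cluster index per member.
#' @slot seed integer seed that generated the ensemble.
#' @slot meta list (sampler settings, closure failures, etc.).
#'
#' @exportClass ConformerEnsemble
setClass("ConformerEnsemble", representation(
  molecule = "Molecule",
  coords = "list",
  eVac = "numeric",
  eWat = "numeric",
  eMem = "numeric",
  degeneracy = "integer",
  nGenerated = "integer",
  members = "list",
  memberCluster = "integer",
  seed = "integer",
  meta = "list"
))

setValidity("ConformerEnsemble", function(object) {
  msg <- character()
  k <- length(object@coords)
  if (k == 0) msg <- c(msg, "ensemble must contain at least one conformer")
  if (length(object@degeneracy) != k || length(object@eVac) != k)
    msg <- c(msg, "coords, degeneracy and eVac must have equal length")
  if (k > 0 && any(object@degeneracy < 1L))
    msg <- c(msg, "degeneracies must be >= 1")
  if (k > 0 && sum(object@degeneracy) != object@nGenerated)
    msg <- c(msg, "sum of degeneracies must equal nGenerated")
  if (length(object@members) != object@nGenerated)
    msg <- c(msg, "members must hold one coordinate set per accepted sample")
  if (length(object@memberCluster) != length(object@members) ||
      (k > 0 && !identical(as.integer(tabulate(object@memberCluster, k)),
                           object@degeneracy)))
    msg <- c(msg, "memberCluster must map members onto cluster sizes")
  if (k > 0 && !all(is.finite(object@eVac)))
    msg <- c(msg, "vacuum energies must be finite")
  if (length(msg)) msg else TRUE
})

#' PCRModel: principal-component regression model with L2 or L1 penalty
#'
#' A linear model in principal-component space: descriptors are centered by
#' the stored means, projected on the stored loading vectors, and the
#' retained-axis coefficients plus intercept give the prediction.
#'
#' @slot schema descriptor (column) names the model was fit on, in order.
#' @slot center column means used for centering.
#' @slot loadings p x r orthonormal loading matrix (columns = PC axes).
#' @slot coef coefficients for the first \code{nAxis} PC axes.
#' @slot intercept unpenalized intercept.
#' @slot lambda regularization weight.
#' @slot nAxis number of retained PC axes.
#' @slot penalty \code{"L2"} or \code{"L1"}.
#' @slot dropped names of zero-variance columns removed before PCA.
#' @slot meta provenance list (seed, charge scheme, solvation settings, ...).
#'
#' @exportClass PCRModel
setClass("PCRModel", representation(
  schema = "character",
  center = "numeric",
  loadings = "matrix",
  coef = "numeric",
  intercept = "numeric",
  lambda = "numeric",
  nAxis = "integer",
  penalty = "character",
  dropped = "character",
  meta = "list"
))

setValidity("PCRModel", function(object) {
  msg <- character()
  if (ncol(object@loadings) < object@nAxis)
    msg <- c(msg, "nAxis exceeds number of loading vectors")
  if (length(object@coef) != object@nAxis)
    msg <- c(msg, "coef length must equal nAxis")
  if (nrow(object@loadings) != length(object@schema))
    msg <- c(msg, "loadings rows must match schema length")
  if (ncol(object@loadings) > 0) {
    g <- crossprod(object@loadings)
    if (max(abs(g - diag(ncol(g)))) > 1e-8)
      msg <- c(msg, "loading vectors must be orthonormal within 1e-8")
  }
  if (!object@penalty %in% c("L2", "L1"))
    msg <- c(msg, "penalty must be 'L2' or 'L1'")
  if (length(msg)) msg else TRUE
})

#' @describeIn Molecule number of atoms
#' @param x,object a \code{Molecule}
#' @export
setMethod("length", "Molecule", function(x) nrow(x@atoms))

setMethod("show", "Molecule", function(object) {
  heavy <- sum(object@atoms$element != "H")
  cat(sprintf(
    "Molecule '%s': %d atoms (%d heavy), %d bonds, formal charge %+d\n",
    object@id, nrow(object@atoms), heavy, nrow(object@bonds),
    as.integer(object@formalCharge)))
  if (!is.null(object@meta$charge_scheme))
    cat("  partial charges:", object@meta$charge_scheme, "\n")
})

setMethod("show", "ConformerEnsemble", function(object) {
  cat(sprintf(
    "ConformerEnsemble of '%s': %d clusters from %d samples (seed %d)\n",
    object@molecule@id, length(object@coords), object@nGenerated,
    object@seed))
  cat(sprintf("  E_vac range: %.2f .. %.2f kcal/mol; solvation %s\n",
              min(object@eVac), max(object@eVac),
              if (all(is.finite(object@eWat))) "filled" else "pending"))
})

setMethod("show", "PCRModel", function(object) {
  cat(sprintf(
    "PCRModel (%s): %d descriptors, %d PC axes, lambda = %g\n",
    object@penalty, length(object@schema), object@nAxis, object@lambda))
  if (length(object@dropped))
    cat("  dropped zero-variance columns:", length(object@dropped), "\n")
})

## --- plain accessors (no slot access for users) ---

#' Molecule accessors
#'
#' @param mol a \code{Molecule}
#' @return \code{atoms()}/\code{bonds()} return data.frames; \code{molId()}
#'   the identifier; \code{formalCharge()} the integer net charge;
#'   \code{coords()} an n x 3 coordinate matrix.
#' @export
atoms <- function(mol) mol@atoms

#' @rdname atoms
#' @export
bonds <- function(mol) mol@bonds

#' @rdname atoms
#' @export
molId <- function(mol) mol@id

#' @rdname atoms
#' @export
formalCharge <- function(mol) mol@formalCharge

#' @rdname atoms
#' @export
coords <- function(mol) {
  m <- as.matrix(mol@atoms[, c("x", "y", "z")])
  dimnames(m) <- NULL
  m
}

#' ConformerEnsemble accessors
#'
#' @param ens a \code{ConformerEnsemble}
#' @return \code{conformerCoords()} the list of coordinate matrices;
#'   \code{degeneracy()} the integer cluster sizes; \code{energies()} a
#'   data.frame of per-cluster vacuum/water/membrane energies.
#' @export
conformerCoords <- function(ens) ens@coords

#' @rdname conformerCoords
#' @export
degeneracy <- function(ens) ens@degeneracy

#' @rdname conformerCoords
#' @export
energies <- function(ens) {
  data.frame(eVac = ens@eVac, eWat = ens@eWat, eMem = ens@eMem)
}

#' @rdname conformerCoords
#' @export
ensembleMolecule <- function(ens) ens@molecule
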
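## Molecule input/output and the structure-preparation pipeline.
##
## All format handling is delegated to OpenBabel through ChemmineOB
## (conversion, hydrogen addition, neutralization, 3D building, partial
## charges) and bio3d (Sybyl MOL2 parsing/writing). The internal exchange
## format is MOL2 because it carries Sybyl atom types and partial charges.

.CHARGE_SCHEMES <- c("gasteiger", "mmff94", "eem", "eqeq", "qeq", "qtpie")

.ob_opts <- function(...) {
  v <- c(...)
  data.frame(names = names(v) %||% character(),
             args = unname(v) %||% character(), stringsAsFactors = FALSE)
}

.ob_convert_file <- function(from, to, fin, fout, opts = .ob_opts()) {
  ChemmineOB::convertFormatFile(from, to, fin, fout, options = opts)
  if (!file.exists(fout) || file.size(fout) == 0)
    .stopf("OpenBabel conversion %s -> %s produced no output for '%s'",
           from, to, fin)
  invisible(fout)
}

## Parse one bio3d "mol2" record into a Molecule.
.mol2_record_to_molecule <- function(rec, id = NULL) {
  at <- rec$atom
  bd <- rec$bond
  element <- .element_of(at$elety)
  atoms <- data.frame(
    element = element, type = at$elety, charge = as.numeric(at$charge),
    x = at$x, y = at$y, z = at$z, stringsAsFactors = FALSE)
  bonds <- if (is.null(bd) || nrow(bd) == 0)
    data.frame(i = integer(), j = integer(), order = character(),
               stringsAsFactors = FALSE)
  else data.frame(i = as.integer(bd$origin), j = as.integer(bd$target),
                  order = as.character(bd$type), stringsAsFactors = FALSE)
  fc <- round(sum(atoms$charge))
  if (!is.finite(fc)) fc <- 0
  ## MOL2 stores charges at 4 decimals; spread the written-precision
  ## residual uniformly so the charge-sum invariant holds for any size
  resid <- sum(atoms$charge) - fc
  if (is.finite(resid) && abs(resid) <= 0.02 && abs(resid) > 0)
    atoms$charge <- atoms$charge - resid / nrow(atoms)
  name <- id %||% (if (!is.null(rec$name) && nzchar(rec$name)) rec$name else "mol")
  new("Molecule", id = name, atoms = atoms, bonds = bonds,
      formalCharge = fc, meta = list())
}

.read_mol2_file <- function(path) {
  recs <- tryCatch({
    r <- bio3d::read.mol2(path)
    if (inherits(r, "mol2")) list(r) else r
  }, error = function(e) .parse_mol2_minimal(path))
  lapply(recs, .mol2_record_to_molecule)
}

## minimal TRIPOS parser used only where bio3d::read.mol2 fails (records
## with zero bonds, e.g. single heavy-atom molecules)
.parse_mol2_minimal <- function(path) {
  lines <- readLines(path, warn = FALSE)
  starts <- grep("^@<TRIPOS>MOLECULE", lines)
  if (length(starts) == 0) .stopf("no MOL2 records in '%s'", path)
  ends <- c(starts[-1] - 1, length(lines))
  lapply(seq_along(starts), function(r) {
    blk <- lines[starts[r]:ends[r]]
    name <- trimws(blk[2])
    sec_atom <- grep("^@<TRIPOS>ATOM", blk)[1]
    sec_bond <- grep("^@<TRIPOS>BOND", blk)[1]
    sec_next <- grep("^@<TRIPOS>", blk)
    end_of <- function(start) {
      nxt <- sec_next[sec_next > start]
      if (length(nxt)) nxt[1] - 1 else length(blk)
    }
    sec_lines <- function(start) {
      e <- end_of(start)
      if (is.na(start) || e <= start) return(character())
      out <- blk[seq(start + 1, e)]
      out[nzchar(trimws(out))]
    }
    atom_lines <- sec_lines(sec_atom)
    tok <- strsplit(trimws(atom_lines), "[[:space:]]+")
    atom <- data.frame(
      eleno = as.numeric(vapply(tok, `[[`, "", 1)),
      elena = vapply(tok, `[[`, "", 2),
      x = as.numeric(vapply(tok, `[[`, "", 3)),
      y = as.numeric(vapply(tok, `[[`, "", 4)),
      z = as.numeric(vapply(tok, `[[`, "", 5)),
      elety = vapply(tok, `[[`, "", 6),
      resno = 1, resid = "UNL1",
      charge = vapply(tok, function(t)
        if (length(t) >= 9) as.numeric(t[[9]]) else 0, 0),
      statbit = NA, stringsAsFactors = FALSE)
    bond <- data.frame(id = numeric(), origin = numeric(),
                       target = numeric(), type = character(),
                       statbit = logical(), stringsAsFactors = FALSE)
    if (!is.na(sec_bond)) {
      bl <- sec_lines(sec_bond)
      if (length(bl)) {
        bt <- strsplit(trimws(bl), "[[:space:]]+")
        bond <- data.frame(
          id = as.numeric(vapply(bt, `[[`, "", 1)),
          origin = as.numeric(vapply(bt, `[[`, "", 2)),
          target = as.numeric(vapply(bt, `[[`, "", 3)),
          type = vapply(bt, `[[`, "", 4),
          statbit = NA, stringsAsFactors = FALSE)
      }
    }
    obj <- list(atom = atom, bond = bond, xyz = NULL, substructure = NULL,
                info = c(nrow(atom), nrow(bond), 0, 0, 0), name = name)
    class(obj) <- "mol2"
    obj
  })
}

## Build a bio3d mol2 object from a Molecule (for write.mol2).
.molecule_to_mol2 <- function(mol) {
  at <- mol@atoms
  n <- nrow(at)
  charge <- at$charge
  charge[!is.finite(charge)] <- 0
  atom <- data.frame(
    eleno = seq_len(n), elena = at$element,
    x = at$x, y = at$y, z = at$z, elety = at$type,
    resno = 1, resid = "UNL1", charge = charge, statbit = NA,
    stringsAsFactors = FALSE)
  bd <- mol@bonds
  bond <- if (nrow(bd) == 0) NULL else data.frame(
    id = seq_len(nrow(bd)), origin = bd$i, target = bd$j,
    order = bd$order, statbit = NA, stringsAsFactors = FALSE)
  obj <- list(atom = atom, bond = bond,
              xyz = matrix(as.numeric(t(as.matrix(at[, c("x", "y", "z")]))),
                           nrow = 1),
              substructure = NULL,
              info = c(n, nrow(bd), 0, 0, 0), name = mol@id)
  class(obj) <- "mol2"
  obj
}

## write a Molecule as MOL2; OpenBabel insists on a BOND section header
## even for bond-less records, which bio3d omits
.write_mol2 <- function(mol, file, append = FALSE) {
  obj <- .molecule_to_mol2(mol)
  bio3d::write.mol2(obj, file = file, append = append)
  if (is.null(obj$bond)) cat("@<TRIPOS>BOND\n", file = file, append = TRUE)
  invisible(file)
}

#' Read molecules from SMILES, SDF or Sybyl MOL2 files
#'
#' Returns one \code{\linkS4class{Molecule}} per record, in input order.
#' SMILES input is one molecule per line with an optional whitespace- or
#' tab-separated identifier; 2D coordinates are generated so that every
#' record has finite coordinates. SDF and MOL2 coordinates are taken as-is.
#'
#' @param path input file.
#' @param format one of \code{"smiles"}, \code{"sdf"}, \code{"mol2"};
#'   defaults to a guess from the file extension.
#' @return list of \code{Molecule} objects.
#' @examples
#' f <- tempfile(fileext = ".smi")
#' writeLines(c("CCO\tethanol", "c1ccccc1\tbenzene"), f)
#' mols <- readMolecules(f)
#' vapply(mols, molId, "")
#' @export
readMolecules <- function(path, format = c("auto", "smiles", "sdf", "mol2")) {
  format <- match.arg(format)
  if (!file.exists(path)) .stopf("file not found: '%s'", path)
  if (format == "auto") {
    ext <- tolower(tools::file_ext(path))
    format <- switch(ext, smi = "smiles", smiles = "smiles", sdf = "sdf",
                     sd = "sdf", mol2 = "mol2",
                     .stopf("cannot guess format from extension '.%s'", ext))
  }
  if (format == "smiles") {
    lines <- trimws(readLines(path, warn = FALSE))
    lines <- lines[nzchar(lines)]
    if (length(lines) == 0) .stopf("empty SMILES file: '%s'", path)
    toks <- strsplit(lines, "[[:space:]]+")
    smi <- vapply(toks, `[[`, "", 1L)
    ids <- vapply(seq_along(toks), function(k)
      if (length(toks[[k]]) > 1) toks[[k]][[2]] else sprintf("mol%03d", k), "")
    fin <- tempfile(fileext = ".smi")
    on.exit(unlink(fin), add = TRUE)
    writeLines(paste(smi, ids, sep = "\t"), fin)
    fout <- tempfile(fileext = ".mol2")
    on.exit(unlink(fout), add = TRUE)
    .ob_convert_file("SMI", "MOL2", fin, fout, .ob_opts(gen2D = ""))
    mols <- .read_mol2_file(fout)
    if (length(mols) != length(smi))
      .stopf("SMILES record %d of '%s' failed to parse",
             length(mols) + 1L, path)
    for (k in seq_along(mols)) {
      mols[[k]]@id <- ids[[k]]
      mols[[k]]@meta$smiles <- smi[[k]]
    }
    return(mols)
  }
  if (format == "sdf") {
    nrec <- sum(grepl("^\\${4}", readLines(path, warn = FALSE)))
    if (nrec == 0) .stopf("no SDF records in '%s'", path)
    fout <- tempfile(fileext = ".mol2")
    on.exit(unlink(fout), add = TRUE)
    .ob_convert_file("SDF", "MOL2", path, fout)
    mols <- .read_mol2_file(fout)
    if (length(mols) != nrec)
      .stopf("SDF record %d of '%s' failed to parse", length(mols) + 1L, path)
    for (k in seq_along(mols))
      if (!nzchar(mols[[k]]@id) || mols[[k]]@id == "mol")
        mols[[k]]@id <- sprintf("mol%03d", k)
    return(mols)
  }
  mols <- .read_mol2_file(path)
  if (length(mols) == 0) .stopf("no MOL2 records in '%s'", path)
  mols
}

#' Write molecules to MOL2 or SDF
#'
#' MOL2 output preserves Sybyl atom types and partial charges; SDF output is
#' produced from the MOL2 representation by OpenBabel and carries
#' coordinates and connectivity only.
#'
#' @param mols a \code{Molecule} or list of them.
#' @param path output file.
#' @param format \code{"mol2"} or \code{"sdf"} (guessed from extension by
#'   default).
#' @return \code{path}, invisibly.
#' @export
writeMolecules <- function(mols, path, format = c("auto", "mol2", "sdf")) {
  format <- match.arg(format)
  if (is(mols, "Molecule")) mols <- list(mols)
  if (format == "auto")
    format <- if (tolower(tools::file_ext(path)) %in% c("sdf", "sd"))
      "sdf" else "mol2"
  f2 <- if (format == "mol2") path else tempfile(fileext = ".mol2")
  for (k in seq_along(mols))
    .write_mol2(mols[[k]], f2, append = k > 1)
  if (format == "sdf") {
    on.exit(unlink(f2), add = TRUE)
    .ob_convert_file("MOL2", "SDF", f2, path)
  }
  invisible(path)
}

## Keep the largest connected fragment (salt stripping); logs in meta.
.largest_fragment <- function(mol) {
  g <- .bond_graph(mol)
  comp <- igraph::components(g)
  if (comp$no <= 1) return(mol)
  keep <- which(comp$membership == which.max(comp$csize))
  at <- mol@atoms[keep, , drop = FALSE]
  idx <- match(seq_len(nrow(mol@atoms)), keep)
  bd <- mol@bonds
  sel <- bd$i %in% keep & bd$j %in% keep
  bd <- bd[sel, , drop = FALSE]
  bd$i <- idx[bd$i]; bd$j <- idx[bd$j]
  rownames(at) <- rownames(bd) <- NULL
  mol@atoms <- at; mol@bonds <- bd
  mol@formalCharge <- round(sum(at$charge[is.finite(at$charge)]))
  mol@meta$fragments_removed <- comp$no - 1L
  .warnf("molecule '%s': kept largest of %d fragments", mol@id, comp$no)
  mol
}

#' Prepare a molecule: neutral form, hydrogens, one 3D structure
#'
#' Reproduces the standard preparation pipeline: the largest fragment is
#' kept (salts are stripped), +1/-1 charged acid and amine centers are
#' neutralized by proton addition/removal (carboxylate to COOH, ammonium to
#' amine), explicit hydrogens are added, Sybyl atom types are assigned, a
#' single 3D conformation is built deterministically and then
#' energy-minimized with the package force field, and partial charges are
#' computed. Molecules that cannot be neutralized (e.g. quaternary
#' ammonium) are retained with a warning and flagged in \code{meta}.
#'
#' @param mol a \code{Molecule} (2D or 3D, with or without hydrogens).
#' @param chargeScheme partial-charge scheme; see
#'   \code{\link{assignPartialCharges}}.
#' @param minimize logical; minimize the built structure with the package
#'   force field (default \code{TRUE}).
#' @return a prepared \code{Molecule} with \code{formalCharge == 0} when
#'   neutralizable.
#' @examples
#' \donttest{
#' f <- tempfile(fileext = ".smi")
#' writeLines("CC(=O)[O-]\tacetate", f)
#' m <- prepareMolecule(readMolecules(f)[[1]])
#' formalCharge(m)  # 0: carboxylate has been protonated
#' }
#' @export
prepareMolecule <- function(mol, chargeScheme = "gasteiger",
                            minimize = TRUE) {
  stopifnot(is(mol, "Molecule"))
  chargeScheme <- match.arg(chargeScheme, .CHARGE_SCHEMES)
  mol <- .largest_fragment(mol)
  fin <- tempfile(fileext = ".mol2")
  fout <- tempfile(fileext = ".mol2")
  on.exit(unlink(c(fin, fout)), add = TRUE)
  .write_mol2(mol, fin)
  ## neutralize handles +-1 acid/amine centers; gen3D "fastest" is the
  ## deterministic builder + local optimization (the MC sampler does the
  ## conformational search later).
  .ob_convert_file("MOL2", "MOL2", fin, fout,
                   .ob_opts(neutralize = "", h = "", gen3D = "fastest",
                            partialcharge = chargeScheme))
  out <- .read_mol2_file(fout)[[1]]
  out@id <- mol@id
  out@meta <- mol@meta
  out@meta$charge_scheme <- chargeScheme
  out@meta$prepared <- TRUE
  if (out@formalCharge != 0) {
    .warnf("molecule '%s' could not be neutralized (formal charge %+d)",
           out@id, as.integer(out@formalCharge))
    out@meta$neutralized <- FALSE
  } else out@meta$neutralized <- TRUE
  if (minimize) {
    ff <- .ff_terms(out)
    res <- .minimize(coords(out), ff)
    out@atoms[, c("x", "y", "z")] <- res$coords
    out@meta$e_vac <- res$energy
  }
  validObject(out)
  out
}

#' Assign partial atomic charges
#'
#' Computes per-atom partial charges with one of OpenBabel's charge models
#' and stores them on the molecule. The charge sum equals the formal charge
#' (to 1e-3 e). The scheme used is recorded in the molecule metadata so
#' trained models can refuse descriptor tables from a different scheme.
#'
#' @param mol a \code{Molecule} with explicit hydrogens.
#' @param scheme one of \code{"gasteiger"} (default), \code{"mmff94"},
#'   \code{"eem"}, \code{"eqeq"}, \code{"qeq"}, \code{"qtpie"}.
#' @return the \code{Molecule} with updated charges.
#' @export
assignPartialCharges <- function(mol, scheme = "gasteiger") {
  stopifnot(is(mol, "Molecule"))
  if (!scheme %in% .CHARGE_SCHEMES)
    .stopf("unknown charge scheme '%s'; available: %s", scheme,
           paste(.CHARGE_SCHEMES, collapse = ", "))
  fin <- tempfile(fileext = ".mol2")
  fout <- tempfile(fileext = ".mol2")
  on.exit(unlink(c(fin, fout)), add = TRUE)
  .write_mol2(mol, fin)
  .ob_convert_file("MOL2", "MOL2", fin, fout,
                   .ob_opts(partialcharge = scheme))
  out <- .read_mol2_file(fout)[[1]]
  if (nrow(out@atoms) != nrow(mol@atoms))
    .stopf("charge assignment changed the atom count of '%s'", mol@id)
  mol@atoms$charge <- out@atoms$charge
  mol@formalCharge <- round(sum(out@atoms$charge))
  mol@meta$charge_scheme <- scheme
  validObject(mol)
  mol
}

#' Molecular weight of a molecule
#'
#' @param mol a \code{Molecule}.
#' @return molecular weight in Da (standard atomic weights).
#' @export
molecularWeight <- function(mol) {
  m <- .ATOMIC_MASS[mol@atoms$element]
  if (anyNA(m))
    .stopf("no atomic mass for element(s): %s",
           paste(unique(mol@atoms$element[is.na(m)]), collapse = ", "))
  sum(m)
}
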
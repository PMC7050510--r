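## Shared fixtures, memoized across test files (test_dir runs one process).

.tcache <- new.env(parent = emptyenv())

cache_get <- function(key, expr) {
  if (!exists(key, envir = .tcache)) assign(key, force(expr), envir = .tcache)
  get(key, envir = .tcache)
}

TEST_SMILES <- c(
  methane = "C", ethane = "CC", ethanol = "CCO", benzene = "c1ccccc1",
  n_butane = "CCCC", n_hexane = "CCCCCC", cyclohexane = "C1CCCCC1",
  acetate = "CC(=O)[O-]", teg = "OCCOCCOCCO",
  crown18 = "C1COCCOCCOCCOCCOCCO1")

prep_smi <- function(id) {
  cache_get(paste0("mol_", id), {
    f <- tempfile(fileext = ".smi")
    writeLines(paste(TEST_SMILES[[id]], id, sep = "\t"), f)
    m <- suppressWarnings(prepareMolecule(readMolecules(f)[[1]]))
    unlink(f)
    m
  })
}

ens_of <- function(id, n = 100, seed = 1) {
  cache_get(sprintf("ens_%s_%d_%d", id, n, seed), {
    ens <- suppressWarnings(
      generateEnsemble(prep_smi(id), nSamples = n, seed = seed))
    addSolvationEnergies(ens)
  })
}

panel_mols <- function() {
  cache_get("panel", suppressWarnings(prepareFixturePanel()))
}

panel_eds100 <- function() {
  cache_get("eds100", suppressWarnings(
    computeDescriptors(panel_mols(), runConfig(seed = 11), nSamples = 100)))
}

## ensemble with prescribed solvent energies/degeneracies (for the
## Boltzmann-law and LogD-law tests)
fake_ens <- function(eWat, eMem, n = rep(1L, length(eWat))) {
  mol <- prep_smi("methane")
  k <- length(eWat)
  cds <- replicate(k, coords(mol), simplify = FALSE)
  new("ConformerEnsemble", molecule = mol, coords = cds,
      eVac = numeric(k), eWat = eWat, eMem = eMem,
      degeneracy = as.integer(n), nGenerated = as.integer(sum(n)),
      members = rep(cds, times = n),
      memberCluster = rep(seq_len(k), times = n),
      seed = 1L, meta = list())
}

## dihedral angle (degrees) over four atom indices
dihedral_deg <- function(p, idx) {
  cr <- function(a, b) c(a[2] * b[3] - a[3] * b[2],
                         a[3] * b[1] - a[1] * b[3],
                         a[1] * b[2] - a[2] * b[1])
  b1 <- p[idx[2], ] - p[idx[1], ]
  b2 <- p[idx[3], ] - p[idx[2], ]
  b3 <- p[idx[4], ] - p[idx[3], ]
  n1 <- cr(b1, b2); n2 <- cr(b2, b3); m <- cr(n1, n2)
  atan2(sum(m * b2) / sqrt(sum(b2^2)), sum(n1 * n2)) * 180 / pi
}
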
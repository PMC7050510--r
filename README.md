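# permeaR

Conformer-ensemble QSPR models of passive membrane permeability.

Passive transcellular permeability — the quantity PAMPA assays measure
as an apparent permeability coefficient `Papp` — limits the oral
bioavailability of drug candidates, and is notoriously hard to predict
for flexible "middle" molecules (MW > 500 Da) and macrocycles, whose
conformational ensembles differ between water and the membrane interior.
`permeaR` is for computational and medicinal chemists who want a
physically interpretable permeability model rather than a black box.

## The model

Fick's law factorizes the apparent permeability into partitioning and
diffusion:

```
Log10 Papp = Log10 D  +  Log10 M  −  Log10 h
```

with `D` the water/membrane distribution coefficient, `M` the diffusion
constant in the membrane and `h` the membrane thickness. `permeaR`
computes both factors from a Monte-Carlo conformer ensemble:

* conformers are generated by random dihedral sampling with ring
  opening/closure under a simplified AMBER-like force field, and
  clustered by heavy-atom RMSD (< 1.5 Å) to estimate each conformer's
  degeneracy `n(a)`;
* each conformer gets water and membrane energies from a generalized
  Born / surface-area model (solvation parameters +10 and −5
  cal/mol/Å², dielectrics 78.5 and 2.0), giving Boltzmann weights
  `d(a) ∝ n(a)·exp(−E(a)/kT)` per phase and a partition-function
  `LogD = Log10(Z_mem/Z_wat)`;
* diffusion combines viscous (Einstein–Stokes, ∝ 1/R) and inertial
  (∝ 1/R²) resistance; expanding its log yields the feature block
  `⟨R⟩, ⟨R⟩², ⟨R⟩³, Log10⟨R⟩, σ(R)` over the ensemble radius of
  gyration;
* descriptors — ensemble means and deviations of LogD, atom-typed
  accessible surface area, intramolecular hydrogen bonds and radius in
  both phases, plus MACCS keys, O-H/N-H hydrogen charges and counts —
  feed a principal-component regression with an L2 (default, λ = 1e-6)
  or L1 penalty, with axis count chosen by cross-validated Q².

Two feature layouts bracket the permeation regimes: Model A (conformer
fixed while crossing; water-ensemble statistics) and Model B
(re-equilibrated conformers; membrane-ensemble statistics plus the
ensemble LogD); Model AB is their union.

## Worked example

```r
library(permeaR)

f <- tempfile(fileext = ".smi")
writeLines("CC(C)Cc1ccc(cc1)C(C)C(=O)O\tibuprofen", f)
mol <- prepareMolecule(readMolecules(f)[[1]])
mol
#> Molecule 'ibuprofen': 33 atoms (15 heavy), 33 bonds, formal charge +0
#>   partial charges: gasteiger

ens <- generateEnsemble(mol, nSamples = 50, seed = 7)
ens <- addSolvationEnergies(ens)
ens
#> ConformerEnsemble of 'ibuprofen': 4 clusters from 50 samples (seed 7)
#>   E_vac range: 4.49 .. 5.60 kcal/mol; solvation filled

ed <- ensembleDescriptors(ens)
ed
#> EnsembleDescriptors 'ibuprofen': 4 clusters, LogD 3.10, <R>_wat 3.10 A (sd 0.09)
```

The 50 samples collapse into 4 conformer clusters. The computed
partition-function LogD of 3.10 places ibuprofen in the lipophilic range
(its measured octanol–water logP is ≈ 3.5), the ensemble radius ⟨R⟩ of
3.10 Å with σ(R) = 0.09 Å quantifies its modest conformational
breathing, and the full Model AB feature vector has 239 named terms:

```r
v <- featuresModelAB(featuresModelA(ed), featuresModelB(ed))
length(v)
#> [1] 239
```

With a labeled table (`id` → measured Log10 Papp) the regression side
runs as:

```r
eds <- computeDescriptors(mols, runConfig(seed = 7))   # list of molecules
X   <- featureMatrix(eds, "AB")
cv  <- kfoldCV(X, y, k = 4, lambda = 1e-6, seed = 7)   # pooled Q2 / RMSE
fit <- fitPCR(X, y, nAxis = selectNAxis(X, y, seed = 7))
writePCRModel(fit, "model.json")
```

`holdoutEvaluate(X, y, features, "MW")` runs the size-stratified
hold-out protocol (train on the smaller 75%, predict the largest 25%),
and `sweepConformerNumber()` tabulates Q²/RMSE against the Monte-Carlo
sample count. A command-line front end covering the same stages ships
as `inst/scripts/permeate` (subcommands `prep`, `conformers`,
`featurize`, `train`, `crossval`, `holdout`, `predict`, `fixtures`,
`sweep`).

No experimental dataset ships with the package: a 23-molecule fixture
panel (rigid aromatics through macrocycles and a >500 Da PEG ether) and
a planted-model synthetic-data generator (`fixtureMolecules()`,
`synthesizeDataset()`) exercise the full pipeline; see the vignette for
what that does and does not demonstrate.

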
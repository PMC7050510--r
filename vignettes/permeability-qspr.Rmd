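---
title: "Conformer-ensemble QSPR modeling of passive membrane permeability"
author: "permeaR"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Conformer-ensemble QSPR modeling of passive membrane permeability}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

# The model

Transcellular passive permeability, as measured in PAMPA-type assays, is
treated as a Fick's-law process: the apparent permeability is the product
of the water/membrane distribution coefficient `D` and the diffusion
constant `M` of the solute inside the membrane, divided by the membrane
thickness, so that on the log scale

    Log10 Papp = Log10 D + Log10 M - Log10 h.

Both factors depend on the conformational state of the solute, and for
flexible middle molecules and macrocycles the conformational ensemble in
water differs from the one in the membrane. The package therefore builds
its descriptors from a Boltzmann-weighted conformer ensemble evaluated in
two implicit solvents, and expresses `Log10 Papp` as a linear model over
those descriptors, fit by principal-component regression (PCR).

Two limiting permeability regimes are represented as separate feature
layouts:

* **Model A** — membrane crossing is faster than conformational
  relaxation: each conformer crosses as-is, so the water-ensemble
  distribution governs everything. The log of a weighted sum of
  per-conformer permeabilities is expanded in cumulants, which turns the
  layout into means plus deviations under water weights: the mean and
  deviation of the per-conformer LogD, water-weighted ASA, hydrogen-bond
  and radius statistics.
* **Model B** — crossing is slower than conformational relaxation: the
  ensemble re-equilibrates inside the membrane. The layout uses the
  ensemble (partition-function) LogD plus membrane-weighted statistics.
* **Model AB** — the union of both schemas, shared conformer-independent
  terms appearing once. Because either regime may dominate for a given
  molecule, the merged layout lets the regression decide.

The diffusion constant combines viscous resistance (Einstein–Stokes,
inversely proportional to the solute radius `R`) and inertial resistance
(proportional to the cross-section, hence `R^2`). Expanding the log of
the combined resistance in powers of `R` motivates the diffusion feature
block `<R>`, `<R>^2`, `<R>^3`, `Log10<R>`, plus the ensemble deviation
`sigma(R)` from the cumulant expansion. Every term carries its own fitted
coefficient, so the signs and magnitudes of the series are absorbed by
the regression; ablation flags can drop any subset of the block or add
`<R>^4`, which lets the contribution of each resistance term be measured.

# Pipeline stages and the choices behind them

## Structure preparation

Input molecules (SMILES, SDF, MOL2) are reduced to their largest fragment
(salt stripping), neutralized at +1/-1 acid and amine centers
(carboxylate to COOH, ammonium to amine — only the neutral species is
assumed membrane-permeant), given explicit hydrogens and Sybyl atom
types, and embedded in 3D. The 3D builder is deliberately run in its
deterministic single-structure mode without a stochastic rotor search:
the package's own Monte-Carlo sampler performs the conformational
search, and bit-reproducibility of the whole pipeline under a seed is a
design requirement. Partial charges default to Gasteiger; the regression
consumes only the maximum O-H / N-H hydrogen charges, for which any
electronegativity-equalization scheme preserves the ordering. The scheme
name is recorded in the molecule and model metadata so descriptor tables
from different schemes are not mixed. Molecules that cannot be
neutralized (e.g. quaternary ammonium) are retained with a warning and
flagged.

## Force field

Conformer generation uses a small purpose-built AMBER-like potential
keyed on Sybyl atom types: harmonic bonds and angles, one cosine torsion
per central bond (threefold for sp3–sp3, twofold for conjugated, amide
and aromatic bonds), and 12-6 Lennard-Jones interactions. There is no
electrostatic term: the same conformer energies are reused in water and
membrane, whose dielectric constants differ by a factor of ~40, so
polarity enters only through the solvation model. Two deliberate
simplifications: a single torsion term per central bond (reference path
through the lowest-index heavy neighbors) instead of a sum over all
paths, and van der Waals interactions over *all* pairs separated by at
least three bonds (1-4 pairs scaled by 0.5) rather than a 1-5
truncation — collision avoidance inside macrocycles cannot be guaranteed
by truncated lists. Nonbonded exclusions are always computed on the full
bond graph, including ring bonds that are temporarily opened, so closure
pairs keep their 1-2/1-3 exclusions. Pairs closer than 0.7 Å switch to a
linear extension of the LJ wall, giving overlapping atoms a large but
finite repulsion with a finite gradient. Parameters are generic; only
relative energies within one molecule are used.

## Conformer sampling, ring opening and closure

Each sample draws every rotatable dihedral uniformly on [0°, 360°).
Rings are first opened by removing one bond per independent cycle —
never an aromatic, double, triple or amide bond; among breakable single
bonds the one with the fewest heavy substituents is chosen, ties broken
by lowest atom index pair — which frees the ring dihedrals for sampling.
Minimization then recloses the rings: three stages of harmonic closure
restraints with force constants ramped 10 → 50 → 200 kcal/mol/Å²,
followed by a final minimization under the full force field with the
real ring bonds restored (L-BFGS-B, convergence at max gradient
0.05 kcal/mol/Å or 2000 iterations). A sample is accepted when every
reopened bond is within 10% of its reference length and no heavy-atom
nonbonded pair is closer than 1.5 Å; failures are discarded and counted.
Rings with no breakable bond (aromatics) stay rigid with a warning.
Molecules with no rotatable dihedrals return their single minimized
structure regardless of the requested sample count.

## Degeneracy and ensemble statistics

Accepted samples are clustered by greedy leader clustering on
superposition-minimized heavy-atom RMSD at the 1.5 Å threshold, visiting
conformers in order of increasing vacuum energy, so each cluster's
representative is its lowest-energy member and the cluster size is the
degeneracy `n(a)` — the Boltzmann prefactor. Conformer weights in
solvent `s` are `d(a) ∝ n(a) exp(-E_s(a)/kT)` with
`E_s(a) = E_vac(a) + ΔG_GBSA(a, s)` (the total-energy reading: Boltzmann
weighting across conformers must include intramolecular strain),
computed max-subtracted so arbitrary energy scales cannot overflow.

Ensemble property statistics are evaluated over *all* accepted samples,
each member carrying an equal share `d(a)/n(a)` of its cluster's weight.
This is the cluster-mean reading of the weighted average: it reduces
exactly to representative-only evaluation when members coincide, keeps
`sigma = 0` for rigid molecules, and retains the intra-cluster geometric
spread — at the 1.5 Å threshold the entire conformer set of a short
flexible chain such as n-hexane falls inside one cluster (measured
maximum pairwise RMSD ≈ 1.2 Å), yet its radius genuinely fluctuates by
~0.1 Å, which the deviation descriptors should see.

## Solvation and LogD

The two phases are water (dielectric 78.5, atomic solvation parameter
+10 cal/mol/Å²) and a single low-dielectric membrane phase (dielectric
2.0, −5 cal/mol/Å²) that also plays the role of octanol in the
distribution coefficient. The polar term is a pairwise-descreening
(HCT-style) generalized Born model on Bondi radii with a 0.09 Å offset;
the nonpolar term applies the solvation parameter uniformly to the
numeric (Shrake–Rupley) accessible surface area computed on a
deterministic Fibonacci sphere (240 points per atom by default; the
closed-form isolated-atom area is reproduced to well under 1% at 960
points). The ensemble LogD is the log-ratio of the conformer partition
functions in the two phases; the per-conformer LogD entering Model A is
the single-conformer closed form `-(E_mem - E_wat)/(kT ln 10)`. The GB
flavor and radii set are recorded in the ensemble metadata so models
from different solvation settings are not mixed.

## Descriptors

Per conformer: heavy-atom radius of gyration (the radius entering the
diffusion block — rotation-invariant, cheap, monotone with size; the
regression absorbs its scale), ASA aggregated over a fixed 26-type Sybyl
inventory (schema-stable across datasets), and the intramolecular
hydrogen-bond count (donor hydrogens on O/N, acceptors O/N/S, H···A ≤
2.5 Å, angle at H ≥ 120°, donor and acceptor ≥ 3 bonds apart; both
geometric cutoffs are configuration keys since no canonical values
exist). Conformer-independent: the 166 MACCS keys, the maximum hydrogen
partial charge over O-H and N-H groups (proxies for acidity/basicity),
and atom, rotatable-bond, donor and acceptor counts. The deviation
statistic takes a square root so `sigma(R)` carries Å units, consistent
with reporting deviations rather than variances.

## Regression

Descriptors are centered (not scaled — the projection definition
subtracts the mean only) and decomposed by SVD; zero-variance columns
(e.g. constant MACCS keys) are dropped and recorded. With orthogonal PC
scores the L2 solution is elementwise:
`c_j = p_jᵀ(y - ȳ)/(d_j² + λ)` with the intercept unpenalized; λ
defaults to 1e-6. The L1 variant solves the same objective with an
absolute-value penalty by coordinate descent. The retained axis count
maximizes cross-validated Q²; because the Q² curve plateaus once the
informative axes are in, the smallest count within 1e-3 of the maximum
is selected (exact ties therefore also resolve to the smaller count).
Outer 4-fold cross-validation re-selects the axis count inside each fold
on the training part only (nested, leakage-free); a non-nested flag
reproduces single selection on the full data. The size-stratified
hold-out protocol sorts molecules by MW, atom count, cycle count,
rotatable bonds or largest-ring size, holds out the top 25% (ties broken
by molecule id), selects axes by 3-fold CV on the smaller-molecule side,
and reports Pearson R and RMSE on the held-out larger molecules;
back-projected coefficient vectors from different training sets are
compared by Pearson correlation as a robustness measure.

# The synthetic-data generator

No experimental permeability data ship with the package. Tests instead
run on (i) a 23-molecule panel spanning rigid aromatics, small polar
solutes, drug-like molecules, flexible chains, two macrocycles with
largest ring > 12 atoms and one PEG ether above 500 Da — emulating the
size spread of a realistic permeability dataset — and (ii) datasets with
a *planted* linear model: panel descriptor rows are replicated and
perturbed (Gaussian noise at half the column standard deviation;
binary MACCS columns stay binary), sparse coefficients are drawn on
perturbed columns screened to pairwise |r| < 0.95 so the truth is
identifiable, and `y` is the planted combination plus Gaussian noise
(default sd 0.1). Because the descriptors are computed, not drawn, the
regression tests exercise the real collinearity structure (the ASA block
and the LogD term double-count the solute–solvent interaction, which is
exactly what PCR is there to absorb).

What passing these tests shows — and what it does not: the planted-model
recovery demonstrates that the regression harness is correct and that
the descriptor pipeline produces a numerically well-behaved design
matrix under realistic collinearity; it says nothing about how well the
physical model predicts *measured* permeability, which requires an
experimental dataset. The generator also does not emulate assay noise
structure, pH effects, or inter-laboratory variability.

# Numerical choices and degenerate inputs

* Sample counts: 100 Monte-Carlo samples per molecule by default (a
  sweep utility covers 1–300); problem sizes in the test suite are 100
  samples for ensemble-statistics checks, 200 rows for planted-model
  recovery, chosen so the whole suite runs in a few minutes on one CPU.
* Boltzmann weights and LogD use max-subtracted exponentials; weights
  are exact to 1e-12 normalization.
* The cumulant utility returns the exact log-sum alongside the order-1/2
  truncations; the expansion is asymptotic, reliable for two-point
  spreads up to ~1.3 Log10 units.
* MOL2 charges are written at 4 decimals; the residual against the
  integer formal charge is spread uniformly over atoms at parse time so
  the neutrality invariant holds for any molecule size.
* Degenerate inputs: empty ensembles error; a molecule whose every ring
  closure fails errors (and is dropped, with a report, in batch runs);
  single-atom molecules parse through an internal minimal TRIPOS reader;
  zero-variance responses make Q² undefined and error explicitly.
* Clustering is not symmetry-corrected: a symmetric molecule's rotated
  copies may split clusters; degeneracy then shifts between symmetric
  minima with identical energies, leaving Boltzmann weights unaffected.

# Known limitations

The force field is generic and untyped beyond Sybyl classes; absolute
conformer energies are not meaningful, only relative ones within a
molecule. The membrane is a single homogeneous low-dielectric phase, not
a bilayer profile; pH-dependent ionization is folded into descriptors
(hydrogen charges, MACCS keys) rather than handled by protonation-state
enumeration; tautomers are not enumerated. Permanent ions are carried
through with a warning but the neutral-form assumption behind the
distribution model does not hold for them.
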
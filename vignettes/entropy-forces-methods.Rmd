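---
title: "Entropy, pairwise forces, and interface geometry: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Entropy, pairwise forces, and interface geometry: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(tidytraj)
```

tidytraj implements the trajectory-analysis layer of a comparative MD study
of a chaperoned protein complex: the tapasin–MHC I system in its
peptide-deficient (PD) and peptide-loaded (PL) states is the motivating
case, but every function is generic over topologies, trajectories and named
residue selections. This vignette explains the models, the tunable
parameters, the synthetic-data generators used for validation, and the
design choices made where the methods literature leaves the design open.

## Data model and units

Structures are read from PDB (via bio3d), trajectories from CHARMM-format
DCD or multi-model PDB. Coordinates are Angstrom, times ps, masses u,
charges e, LJ sigma nm, LJ epsilon kJ/mol, forces pN, entropies J/(K mol).
Nonbonded parameters travel in a plain-text sidecar table
(`read_parameters()`), decoupling the analysis from any one MD engine's
topology format. Named selections ("domain maps") are closed residue-index
intervals on author/PDB numbering, optionally per chain; the shipped
default map for the tapasin–MHC I system marks the MHC I α1/α2/α3
boundaries (1–90, 91–182, 183–276) as approximate and user-overridable,
because crystal-numbering boundaries for the sub-domains are conventional
rather than canonical. Tapasin splits at residue 270 (TN 1–269, TC
270–381).

DCD stores one timestep in its header, so only uniformly spaced
trajectories can be written to DCD; the writer records the spacing in ps
and the reader reconstructs times from it. Irregular series belong in
multi-model PDB, where each MODEL carries its time on a REMARK line.

## Quasi-harmonic configurational entropy

`schlitter_entropy()` evaluates the quasi-harmonic upper bound

$$ S = \frac{R}{2}\,\ln\det\!\left[\mathbf{1} +
   \frac{k_B T e^2}{\hbar^2}\,
   \mathbf{M}^{1/2}\mathbf{C}\,\mathbf{M}^{1/2}\right] $$

on the molar scale, with $\mathbf{C}$ the covariance of Cα positional
fluctuations about their time mean after least-squares superposition
(Kabsch, proper rotations only) of every frame onto a reference structure
over the same selection — by default the first frame of the analysed
window. Numerically the determinant is never formed: the symmetrized
mass-weighted covariance is diagonalised and $\frac{R}{2}\sum_i
\ln(1+\lambda_i)$ accumulated via `log1p`, which is stable across the
10-plus orders of magnitude the eigenvalues span. Eigenvalues in
$[-10^{-8}, 0)$ are treated as roundoff and clipped; anything more negative
is rejected as not a covariance.

Choices worth knowing:

* **Per-domain fitting.** `entropy_by_domain()` fits each domain onto its
  own selection before computing its covariance (`fit = "per_domain"`),
  so a domain's entropy measures its internal fluctuations, not its
  rigid-body motion relative to the rest of the complex. A `"global"` mode
  (one fit on all mapped atoms) exists for sensitivity checks, since
  published per-domain tables do not always state which convention was
  used; `"none"` is for ensembles known to carry no rigid-body component.
  The decomposition neglects inter-domain correlations: the whole is not
  the sum of the parts except in the independent-domain limit.
* **Uncertainty.** `entropy_uncertainty()` reports
  $|S(\text{all frames}) - S(\text{first } 90\%)|$ with both entropies
  computed from growing windows with a common origin — the entropy still
  being accumulated by the final 10% of cumulative sampling. For converged
  i.i.d. ensembles this is well below 1% of $S$; for correlated real
  trajectories it is a lower-bound-flavoured convergence measure, not a
  statistical error bar.
* **Quasi-harmonic bias.** The estimator is an upper bound (anharmonicity
  and supralinear correlations are ignored) and is biased upward at small
  frame counts because the sample covariance is rank-deficient; comparative
  differences between states cancel most of this, which is why the package
  is organised around PD/PL difference tables.
* **Solvent entropy.** `solvent_entropy()` is the empirical linear form
  $\Delta S_{solv} = a_{pol}\,\Delta SAS_{pol} + a_{apol}\,\Delta
  SAS_{apol}$. The coefficients must be supplied explicitly;
  `default_solvent_entropy_coefficients()` ships literature
  hydration-entropy values (−0.46 and +1.26 J K⁻¹ mol⁻¹ Å⁻², 300 K) marked
  "verify before quantitative use" — the estimate is qualitative by
  construction. `total_entropy()` adds the configurational and solvent
  changes.

## Pairwise residue–residue forces

`residue_pair_forces()` recomputes nonbonded forces between two disjoint
atom groups (for the motivating system: tapasin TN plus the peptide
against MHC I α1 plus α2) from charges and LJ parameters, and reduces them
to one signed scalar per residue pair and frame. Conventions:

* The per-atom-pair scalar is the central force $f = -dU/dr$ for
  $U = k_e q_1 q_2 / r + 4\varepsilon[(\sigma/r)^{12} - (\sigma/r)^6]$,
  negative = attractive, truncated to zero beyond a 10 Å cutoff.
  Lorentz–Berthelot combination supplies pair σ/ε.
* The default residue-pair scalarisation is the **signed sum** of atom-pair
  scalars: it preserves attraction/repulsion semantics and is additive over
  atom pairs. The alternative (magnitude of the net force vector, signed by
  its projection on the residue-center axis) is available as
  `convention = "vector_projected"`; published force-distribution tables do
  not always print which scalarisation their code used, so both are kept
  and the choice is recorded in the table's attributes.
* Plain truncation, no Ewald: potential-shifting does not change forces
  inside the cutoff, and reciprocal-space contributions cannot be
  attributed to residue pairs. This is an approximation relative to the
  simulation Hamiltonian and is documented as such.
* Errors are block-averaged (`block_error()`): block sizes double until the
  standard error of the block means changes by less than 5% over two
  successive doublings; without a plateau the largest size with at least 4
  blocks is used. Constant series give exactly 0.
* `delta_force_table()` matches pairs across states and reports
  $\Delta F = F_{2} - F_{1}$ with the **linear sum** of the two state
  errors. Linear summation (not quadrature) is deliberately conservative
  and matches how such tables are conventionally printed; pairs observed in
  only one state keep their value and get an absent difference.
* The report threshold used by the pipeline defaults to 200 pN — a
  "strongest forces" table cut — and is user-overridable; the library
  function defaults to 0 (keep everything) so oracles see every pair.

## Surface areas and geometric observables

`sas()` is a Shrake–Rupley implementation: each atom's sphere (Bondi radius
plus a 1.4 Å probe) is sampled with a deterministic Fibonacci lattice
(default 960 points) and the accessible fraction counted against all
neighbouring expanded spheres. Polar area is the N/O contribution
(hydrogens follow their heavy neighbour), apolar the rest; the split is by
element because finer chemotype rules add parameters without changing the
comparative story. `buried_surface()` is SAS(a) + SAS(b) − SAS(a∪b) per
frame, exactly symmetric in the groups. At 960 points the single-sphere
area is exact by construction and the two-sphere overlap case agrees with
the spherical-cap closed form to about 0.1%.

RMSD uses split fit/measure selections: superpose on the fit selection's
Cα atoms, measure over another selection without re-fitting — the
construction needed to report, e.g., one domain's excursions in the
reference frame of another domain (with fit = measure it reduces to
ordinary RMSD). RMSF fits on the measured selection by default.
`fraction_below()` is an exact count proportion. `discard_equilibration()`
drops the leading 10% of frames before any equilibrium average;
`moving_average()` is centered with edge truncation, with 1-ns smoothing
expressed as a 1000 ps window. Multi-replica states are pooled after
per-replica windowing (pooling order is configurable because either order
is defensible when replicas are exchangeable).

## The synthetic-data generators

The generators define the validation conditions; they are first-class,
tested code:

* `gaussian_trajectory()` draws i.i.d. frames from a prescribed 3N-variate
  Gaussian and returns the exact Schlitter entropy of the generating
  covariance. Frames are i.i.d. because the estimators under test are
  ensemble averages and i.i.d. sampling gives the sharpest oracle; an AR(1)
  mode exists solely to exercise block averaging. T defaults to 300 K.
  Validation uses 50 000 frames for 1–5 particles (sample-vs-analytic
  agreement within 2%; observed ≈ 0.1%) and 20 000 frames for the
  domain-recovery harness — sizes chosen so the whole suite runs in
  seconds while the Monte-Carlo error stays an order of magnitude below
  the tolerance being asserted.
* `pd_pl_pair()` builds two ensembles whose covariances differ by scaling
  one particle subset's rows/columns by `scale` (diagonal block by
  `scale²`); with an independent subset the entropy difference is known in
  closed form, giving a parameter-recovery test for
  `entropy_by_domain()` — the per-domain ΔS table should put ≥ 90% of the
  analytic change in the scaled domain and < 10% elsewhere, and does
  (observed: ≈ 100% and < 1%).
* `bead_complex()` builds small two-group charged/LJ complexes whose
  residue-pair forces an independent brute-force double loop reproduces to
  1e-9 relative; `sphere_fixture()` plus `two_sphere_reference()` cover
  the surface stage.

What the Gaussian ensembles deliberately do **not** emulate: anharmonic
wells, slow conformational transitions, autocorrelation (beyond the AR(1)
switch), solvent, and rigid-body diffusion. Passing the oracle suites
therefore demonstrates the estimators are implemented correctly, not that
quasi-harmonic entropy or truncated pairwise forces are adequate physics
for any particular real system — that judgement stays with the analyst.

## Degenerate inputs and numerical edges

Selections that resolve to zero atoms are hard errors (silent no-op
analyses are worse than crashes). Fit selections that are coincident or
collinear are rejected by name; fitting is reduced to translation for
2-atom selections and disabled for single atoms. Overlapping atoms (r <
1e-3 Å) abort force evaluation. Covariances with eigenvalues below −1e-8
(natural units) are rejected; small negatives are clipped. DCD record
markers are checked on both sides of every record and corrupt frames are
reported by index. Output TSVs print numbers through a fixed `formatC`
format so identical configurations yield identical bytes.

## Known limitations

Quasi-harmonic entropies are upper bounds and converge slowly with
sampling; per-domain values ignore inter-domain correlations. Recomputed
forces use plain truncation rather than the simulation's PME; solvent
entropy coefficients are literature-grade. The PDB reader keeps the
highest-occupancy altloc and infers missing elements from atom names with
a warning. None of these affect the package's two-state difference tables
more than the approximations they inherit from the underlying methods.
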
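# tidytraj

Tidy analysis of molecular-dynamics trajectories: quasi-harmonic
configurational entropy, pairwise residue–residue forces, and interface
geometry, with a synthetic-data module that makes every stage verifiable
against closed-form ground truth.

## What problem this solves

Comparative MD studies of protein complexes — the motivating system is the
tapasin–MHC I peptide-editing complex, analysed in its peptide-deficient
(PD) and peptide-loaded (PL) states — need three quantitative layers on top
of the raw trajectories:

1. **Thermodynamics.** The configurational entropy of a selection is
   estimated by the quasi-harmonic (Schlitter) upper bound

   $$ S = \frac{R}{2}\,\ln\det\!\left[\mathbf{1} +
      \frac{k_B T e^2}{\hbar^2}\,
      \mathbf{M}^{1/2}\mathbf{C}\,\mathbf{M}^{1/2}\right], $$

   where **C** is the covariance matrix of Cα positional fluctuations after
   rigid-body fitting, **M** the diagonal mass matrix, *e* Euler's number.
   The decomposition into named domains (MHC I α1/α2/α3, β2m, the peptide,
   tapasin TN/TC) assigns entropy changes to structural elements;
   sampling-convergence uncertainties come from the entropy contributed by
   the final 10% of cumulative sampling. Solvent entropy is estimated
   separately from buried polar/apolar surface, and a totals helper adds the
   configurational and solvent terms.

2. **Mechanics.** Force distribution analysis: time-averaged signed
   Coulomb + Lennard-Jones 6–12 forces summed over atom pairs for every
   residue pair spanning two groups (negative = attractive), with
   block-averaged errors and a PD→PL difference table that mirrors the
   "strongest pairwise forces" tables of comparative binding studies.

3. **Geometry.** Shrake–Rupley solvent-accessible surface with a 1.4 Å
   probe and polar/apolar split, buried interface area, fit/measure RMSD
   (superpose on one selection, measure another), RMSF profiles, named
   groove-width distances, threshold fractions, 1-ns moving averages, and
   the discard-the-first-10% equilibration rule.

Because real multi-microsecond trajectories are too large to ship, the
`synthetic` module generates inputs whose answers are known exactly:
multivariate-Gaussian ensembles with closed-form Schlitter entropy, paired
PD/PL ensembles whose entropy difference is confined to a chosen domain,
charged/LJ bead complexes whose residue-pair forces an independent
brute-force loop can verify, and sphere clusters with analytic surface
areas. All results are tibbles; `tidy()`, `glance()` and `autoplot()`
methods are provided.

## Worked example

A two-state toy complex with a deliberately weakened salt-bridge-like
contact in the "PL" state:

```r
library(tidytraj)

mk <- function(q) bead_complex(
  pos1 = rbind(c(0, 0, 0), c(6, 0, 0)), pos2 = rbind(c(0, 0, 7), c(6, 0, 7)),
  charge1 = c(q, 0.8), charge2 = c(1, -0.7),
  n_frames = 200, jitter = 0.15, seed = 42)
pd <- mk(-1.0); pl <- mk(-0.4)      # charge -1 weakened to -0.4

t_pd <- residue_pair_forces(pd$trajectory, pd$topology, pd$group1, pd$group2)
t_pl <- residue_pair_forces(pl$trajectory, pl$topology, pl$group1, pl$group2)
delta_force_table(t_pd, t_pl)
#>   residue_a residue_b   F_pd F_pd_err    F_pl F_pl_err delta_F delta_F_err
#> 1   A:GLY:1   B:GLY:1 -471.4   2.0689 -188.55   0.8276   282.8      2.8964
#> 2   A:GLY:2   B:GLY:2 -264.2   1.1304 -264.23   1.1304     0.0      2.2608
#> 3   A:GLY:2   B:GLY:1  218.0   0.5200  218.03   0.5200     0.0      1.0400
#> 4   A:GLY:1   B:GLY:2  189.4   0.3569   75.74   0.1427  -113.6      0.4996
```

The weakened contact (residue 1 of chain A against residue 1 of chain B)
loses 282.8 pN of attraction (`delta_F > 0` = less attractive in the second
state); untouched pairs show `delta_F = 0`. Errors are block-averaged;
the difference error is the linear sum of the state errors.

Entropy against the closed form:

```r
g <- gaussian_trajectory(masses = rep(12, 3), covariance = diag(0.25, 9),
                         n_frames = 50000, seed = 1)
schlitter_entropy(fit_and_covariance(g$trajectory, 1:3, fit = "none"),
                  g$masses)$S_config
#> [1] 184.415        # J/(K mol); analytic value 184.3785
```

The sampled estimate agrees with the analytic Schlitter value of the
generating covariance to 0.02%.

For a full two-state comparison driven by a YAML config (per-domain entropy
tables, force tables, buried surface, RMSD/RMSF/distances), see
`run_all()` and the vignette; a thin command-line front-end lives at
`inst/cli/tidytraj-cli.R`.

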
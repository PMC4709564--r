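Package: tidytraj
Title: Tidy Analysis of Molecular Dynamics Trajectories: Configurational
    Entropy, Pairwise Residue Forces, and Interface Geometry
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Tools for comparative analysis of molecular dynamics ensembles of
    protein complexes, developed around the tapasin-MHC I peptide-editing
    system. Computes quasi-harmonic (Schlitter) configurational entropy with
    per-domain decomposition and sampling-convergence uncertainties, pairwise
    residue-residue nonbonded forces (force distribution analysis) with
    block-averaged errors and state-difference tables, solvent-accessible and
    buried interface surface areas (Shrake-Rupley), and the standard geometric
    observables (fit/measure RMSD, RMSF, named inter-residue distances,
    threshold fractions, moving averages, equilibration windowing). A seeded
    synthetic-data module generates Gaussian positional ensembles, charged
    Lennard-Jones bead complexes, and sphere clusters with analytically known
    entropy, forces, and surface areas, so every stage is verifiable against
    closed-form ground truth. Results are tibbles designed for dplyr/ggplot2
    workflows.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    bio3d,
    dplyr,
    generics,
    ggplot2,
    purrr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    yaml
Suggests:
    jsonlite,
    optparse,
    readr,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
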
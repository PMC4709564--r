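# Physical constants (CODATA 2018). Internal units are Angstrom / ps / u / e /
# kJ/mol unless a function documents otherwise.
.const <- list(
  kB       = 1.380649e-23,       # Boltzmann constant, J/K
  hbar     = 1.054571817e-34,    # reduced Planck constant, J s
  u_kg     = 1.66053906660e-27,  # atomic mass unit, kg
  R        = 8.314462618,        # molar gas constant, J/(K mol)
  NA_mol   = 6.02214076e23,      # Avogadro constant, 1/mol
  ke       = 138.935458,         # Coulomb constant, kJ mol^-1 nm e^-2
  kJmol_nm_to_pN = 1.66053906660,# 1 kJ mol^-1 nm^-1 in pN
  A2_to_m2 = 1e-20               # Angstrom^2 in m^2
)

# Default temperature for entropy estimates, K.
.default_temperature <- 300

# Standard atomic masses (u) for the elements a protein analysis meets.
.element_masses <- c(
  H = 1.008, C = 12.011, N = 14.007, O = 15.999, S = 32.06,
  P = 30.974, SE = 78.971, FE = 55.845, ZN = 65.38, MG = 24.305,
  CA = 40.078, "NA" = 22.990, CL = 35.45, K = 39.098, X = 12.011
)

# Bondi van der Waals radii (Angstrom); X is the fallback for unknown elements.
.vdw_radii <- c(
  H = 1.20, C = 1.70, N = 1.55, O = 1.52, S = 1.80, P = 1.80,
  SE = 1.90, F = 1.47, CL = 1.75, BR = 1.85, I = 1.98, X = 1.70
)
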
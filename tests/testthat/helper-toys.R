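# Shared toy builders. Everything is generated in code; no stored fixtures.

# n_frames of rigid-body motion (rotation about z + drift) applied to a base
# structure; internal geometry is constant by construction.
rigid_motion_traj <- function(base, n_frames = 15) {
  th <- seq(0, 1.2, length.out = n_frames)
  coords <- array(NA_real_, c(n_frames, nrow(base), 3))
  for (i in seq_len(n_frames)) {
    Rz <- matrix(c(cos(th[i]), -sin(th[i]), 0,
                   sin(th[i]), cos(th[i]), 0,
                   0, 0, 1), 3, 3, byrow = TRUE)
    coords[i, , ] <- base %*% t(Rz) +
      matrix(rep(c(2 * i, -i, 0.5 * i), each = nrow(base)), nrow(base))
  }
  trajectory(coords)
}

# non-degenerate random structure
random_structure <- function(n, seed = 1, spread = 5) {
  set.seed(seed)
  matrix(stats::rnorm(3 * n, sd = spread), n, 3)
}

# a 3-residue toy peptide topology with N/CA/C atoms per residue
toy_peptide_topology <- function() {
  per <- c("N", "CA", "C")
  el <- c("N", "C", "C")
  topology(tibble::tibble(
    serial = 1:9,
    name = rep(per, 3),
    element = rep(el, 3),
    residue_index = rep(1:3, each = 3),
    residue_name = "ALA",
    chain_id = "A"
  ))
}

# two-state bead complexes with one deliberately weakened contact in "PL"
weakened_contact_pair <- function() {
  mk <- function(q_first) {
    bead_complex(
      pos1 = rbind(c(0, 0, 0), c(6, 0, 0)),
      pos2 = rbind(c(0, 0, 7), c(6, 0, 7)),
      charge1 = c(q_first, 0.8), charge2 = c(1, -0.7),
      n_frames = 8, jitter = 0.05, seed = 21)
  }
  list(pd = mk(-1), pl = mk(-0.4))  # pair (1,1) attraction weakened in PL
}
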
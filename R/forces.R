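#' Nonbonded interaction parameters
#'
#' Settings for pairwise force recomputation: plain truncation at the cutoff
#' (forces, unlike potentials, are unchanged by potential shifting, and
#' reciprocal-space contributions are not attributable to residue pairs — an
#' approximation relative to the simulation Hamiltonian), Coulomb constant in
#' MD units, and the Lorentz-Berthelot combination rule for Lennard-Jones
#' sigma/epsilon.
#'
#' @param cutoff Cutoff distance, Angstrom (default 10).
#' @param coulomb_constant Coulomb constant, kJ mol^-1 nm e^-2.
#' @param combine LJ combination rule; only `"lorentz-berthelot"` is
#'   implemented.
#' @return An object of class `nonbonded_params`.
#' @export
nonbonded_params <- function(cutoff = 10,
                             coulomb_constant = .const$ke,
                             combine = "lorentz-berthelot") {
  if (cutoff <= 0) stop("cutoff must be > 0")
  combine <- match.arg(combine, "lorentz-berthelot")
  structure(list(cutoff = cutoff, coulomb_constant = coulomb_constant,
                 combine = combine),
            class = "nonbonded_params")
}

#' Signed nonbonded force between two atoms
#'
#' Central-force scalar `f = -dU/dr` for the Coulomb plus Lennard-Jones 6-12
#' pair potential `U = ke q1 q2 / r + 4 eps [(sig/r)^12 - (sig/r)^6]`,
#' truncated to zero beyond the cutoff. Negative values are attractive,
#' positive repulsive. The returned vector is the force on atom 2,
#' `f * r_hat` with `r_hat` the unit vector from atom 1 to atom 2.
#'
#' @param r_vec 3-vector from atom 1 to atom 2, Angstrom.
#' @param q1,q2 Charges, e.
#' @param sigma Combined LJ sigma, nm.
#' @param epsilon Combined LJ epsilon, kJ/mol.
#' @param params A [nonbonded_params()].
#' @return List with `scalar` (pN) and `vector` (pN, force on atom 2).
#' @export
atom_pair_force <- function(r_vec, q1, q2, sigma = 0, epsilon = 0,
                            params = nonbonded_params()) {
  r <- sqrt(sum(r_vec^2))
  if (r < 1e-3) stop("overlapping atoms (r = ", format(r), " Angstrom)")
  if (r > params$cutoff) {
    return(list(scalar = 0, vector = c(0, 0, 0)))
  }
  r_nm <- r / 10
  f_kj <- params$coulomb_constant * q1 * q2 / r_nm^2
  if (epsilon > 0 && sigma > 0) {
    sr6 <- (sigma / r_nm)^6
    f_kj <- f_kj + 24 * epsilon / r_nm * (2 * sr6^2 - sr6)
  }
  f_pn <- f_kj * .const$kJmol_nm_to_pN
  list(scalar = f_pn, vector = f_pn * r_vec / r)
}

#' Time-averaged pairwise residue-residue forces between two groups
#'
#' Force distribution analysis: for every residue pair (one residue from each
#' group) the per-frame nonbonded forces over all atom pairs are reduced to a
#' signed scalar, time-averaged over the analysis window, and reported with a
#' block-averaged statistical error. Negative forces are attractive. The
#' default scalarisation is the sum of per-atom-pair signed central-force
#' scalars (`-dU/dr`), which keeps attraction/repulsion semantics and is
#' additive over atom pairs; `convention = "vector_projected"` instead takes
#' the magnitude of the net force vector, signed by its projection onto the
#' residue-center axis.
#'
#' @param traj A [trajectory()].
#' @param topology The matching [topology()]; must carry charges and LJ
#'   parameters.
#' @param group1,group2 Disjoint atom index vectors (e.g. from
#'   [resolve_selection()]).
#' @param params A [nonbonded_params()].
#' @param threshold Report threshold, pN: pairs with `|F_mean|` below it are
#'   dropped (default 0 keeps everything; a 200 pN threshold reproduces a
#'   "strongest forces" table).
#' @param convention `"scalar_sum"` (default) or `"vector_projected"`.
#' @return A `pair_force_table`: tibble with columns `residue_a`,
#'   `residue_b` (labels `chain:resname:index`), `F_mean` (pN), `F_err`
#'   (pN), `n_frames`, sorted by `|F_mean|` descending; attributes `groups`,
#'   `cutoff`, `threshold`, `convention`.
#' @export
residue_pair_forces <- function(traj, topology, group1, group2,
                                params = nonbonded_params(),
                                threshold = 0,
                                convention = c("scalar_sum",
                                               "vector_projected")) {
  convention <- match.arg(convention)
  if (length(intersect(group1, group2)) > 0) {
    stop("groups overlap at the atom level")
  }
  if (is.null(topology$charge) || is.null(topology$lj_sigma) ||
      is.null(topology$lj_epsilon)) {
    stop("topology lacks nonbonded parameters (charges/LJ); ",
         "attach them with read_parameters()")
  }
  a <- topology$atoms
  res_label <- paste0(a$chain_id, ":", a$residue_name, ":", a$residue_index)
  grid <- expand.grid(i = group1, j = group2)
  ii <- grid$i; jj <- grid$j
  pair_key <- paste(res_label[ii], res_label[jj], sep = "|")
  keys <- unique(pair_key)
  key_idx <- match(pair_key, keys)
  q12 <- params$coulomb_constant * topology$charge[ii] * topology$charge[jj]
  sig <- (topology$lj_sigma[ii] + topology$lj_sigma[jj]) / 2
  eps <- sqrt(topology$lj_epsilon[ii] * topology$lj_epsilon[jj])
  nf <- n_frames(traj)
  series <- matrix(0, nrow = nf, ncol = length(keys))
  cutoff <- params$cutoff
  for (fr in seq_len(nf)) {
    X <- frame_coords(traj, fr)
    dx <- X[jj, , drop = FALSE] - X[ii, , drop = FALSE]
    r <- sqrt(rowSums(dx^2))
    if (any(r < 1e-3)) {
      stop("overlapping atoms in frame ", fr, " (pair ",
           pair_key[which(r < 1e-3)[1]], ")")
    }
    within <- r <= cutoff
    f <- numeric(length(r))
    if (any(within)) {
      r_nm <- r[within] / 10
      fk <- q12[within] / r_nm^2
      lj <- within & eps > 0 & sig > 0
      if (any(lj)) {
        ljw <- lj[within]
        sr6 <- (sig[within][ljw] / r_nm[ljw])^6
        fk[ljw] <- fk[ljw] + 24 * eps[within][ljw] / r_nm[ljw] *
          (2 * sr6^2 - sr6)
      }
      f[within] <- fk * .const$kJmol_nm_to_pN
    }
    if (convention == "scalar_sum") {
      series[fr, ] <- rowsum_keys(f, key_idx, length(keys))
    } else {
      fvec <- f / pmax(r, 1e-12) * dx  # force on the group-2 atom
      vx <- rowsum_keys(fvec[, 1], key_idx, length(keys))
      vy <- rowsum_keys(fvec[, 2], key_idx, length(keys))
      vz <- rowsum_keys(fvec[, 3], key_idx, length(keys))
      mag <- sqrt(vx^2 + vy^2 + vz^2)
      # sign from projection onto the residue-center separation axis
      sgn <- vapply(seq_along(keys), function(k) {
        at <- key_idx == k
        ca <- colMeans(X[unique(ii[at]), , drop = FALSE])
        cb <- colMeans(X[unique(jj[at]), , drop = FALSE])
        u <- cb - ca
        nu <- sqrt(sum(u^2))
        if (nu < 1e-12) return(1)
        s <- sum(c(vx[k], vy[k], vz[k]) * u / nu)
        if (s < 0) -1 else 1
      }, numeric(1))
      series[fr, ] <- sgn * mag
    }
  }
  F_mean <- colMeans(series)
  nonzero <- colSums(series != 0) > 0
  F_err <- vapply(seq_along(keys), function(k) {
    if (!nonzero[k]) return(0)
    if (nf >= 4) block_error(series[, k]) else 0
  }, numeric(1))
  lab <- matrix(unlist(strsplit(keys, "|", fixed = TRUE)), ncol = 2,
                byrow = TRUE)
  out <- tibble::tibble(
    residue_a = lab[, 1], residue_b = lab[, 2],
    F_mean = F_mean, F_err = F_err, n_frames = nf
  )
  out <- out[nonzero & abs(out$F_mean) >= threshold, , drop = FALSE]
  out <- out[order(-abs(out$F_mean)), , drop = FALSE]
  new_pair_force_table(out, groups = list(group1 = group1, group2 = group2),
                       cutoff = cutoff, threshold = threshold,
                       convention = convention)
}

rowsum_keys <- function(x, idx, nkeys) {
  out <- numeric(nkeys)
  s <- rowsum(x, idx)
  out[as.integer(rownames(s))] <- s[, 1]
  out
}

new_pair_force_table <- function(df, groups = NULL, cutoff = NA_real_,
                                 threshold = 0, convention = "scalar_sum") {
  out <- tibble::as_tibble(df)
  attr(out, "groups") <- groups
  attr(out, "cutoff") <- cutoff
  attr(out, "threshold") <- threshold
  attr(out, "convention") <- convention
  class(out) <- c("pair_force_table", class(tibble::tibble()))
  out
}

#' Construct a pair-force table from values
#'
#' Builds a `pair_force_table` directly from per-pair means and errors, e.g.
#' to combine published per-state forces into a difference table.
#'
#' @param residue_a,residue_b Residue labels.
#' @param F_mean Signed mean forces, pN (negative = attractive).
#' @param F_err Block-averaged errors, pN.
#' @param n_frames Frames behind each mean (optional).
#' @inheritParams residue_pair_forces
#' @export
pair_force_table <- function(residue_a, residue_b, F_mean, F_err = 0,
                             n_frames = NA_integer_, threshold = 0,
                             convention = "scalar_sum") {
  df <- tibble::tibble(residue_a = residue_a, residue_b = residue_b,
                       F_mean = F_mean,
                       F_err = rep_len(F_err, length(F_mean)),
                       n_frames = as.integer(rep_len(n_frames,
                                                     length(F_mean))))
  if (anyDuplicated(paste(df$residue_a, df$residue_b, sep = "|"))) {
    stop("duplicate residue pairs")
  }
  if (any(df$F_err < 0)) stop("F_err must be >= 0")
  df <- df[order(-abs(df$F_mean)), , drop = FALSE]
  new_pair_force_table(df, threshold = threshold, convention = convention)
}

#' Block-averaged standard error of a correlated series
#'
#' Standard error of the mean estimated by block averaging: the series is cut
#' into blocks whose size doubles (1, 2, 4, ...); at each size the standard
#' error of the block means is computed, and the estimate is taken where it
#' plateaus (less than 5% change over two successive doublings); if no
#' plateau is reached the largest usable block size (at least 4 blocks) is
#' used. Deterministic given the series; exactly 0 for a constant series.
#'
#' @param series Numeric vector of per-frame values (length >= 4).
#' @return Standard error, same units as `series`.
#' @export
block_error <- function(series) {
  n <- length(series)
  if (n < 4) stop("block averaging needs at least 4 values")
  if (stats::sd(series) == 0) return(0)
  sizes <- 1
  while (floor(n / (2 * sizes[length(sizes)])) >= 4) {
    sizes <- c(sizes, 2 * sizes[length(sizes)])
  }
  se <- vapply(sizes, function(b) {
    nb <- floor(n / b)
    means <- colMeans(matrix(series[seq_len(nb * b)], nrow = b))
    stats::sd(means) / sqrt(nb)
  }, numeric(1))
  if (length(se) >= 3) {
    for (i in seq_len(length(se) - 2)) {
      d1 <- abs(se[i + 1] - se[i]) / max(se[i], 1e-300)
      d2 <- abs(se[i + 2] - se[i + 1]) / max(se[i + 1], 1e-300)
      if (d1 < 0.05 && d2 < 0.05) return(se[i + 2])
    }
  }
  se[length(se)]
}

#' Difference table between two states
#'
#' Matches residue pairs of two pair-force tables (e.g. peptide-deficient vs
#' peptide-loaded) and reports `delta_F = F_state2 - F_state1` with the
#' combined error taken as the linear sum of the two state errors. Pairs
#' present in only one state keep their per-state value and get an absent
#' (`NA`) difference, the analogue of a dash in a printed table.
#'
#' @param table_pd,table_pl `pair_force_table`s for the two states, built
#'   with identical group definitions.
#' @return Tibble with columns `residue_a`, `residue_b`, `F_pd`, `F_pd_err`,
#'   `F_pl`, `F_pl_err`, `delta_F`, `delta_F_err`, sorted by the larger
#'   per-state magnitude.
#' @export
delta_force_table <- function(table_pd, table_pl) {
  g1 <- attr(table_pd, "groups"); g2 <- attr(table_pl, "groups")
  if (!is.null(g1) && !is.null(g2) && !identical(g1, g2)) {
    stop("the two tables were built with different group definitions")
  }
  pd <- tibble::as_tibble(table_pd)[, c("residue_a", "residue_b",
                                        "F_mean", "F_err")]
  pl <- tibble::as_tibble(table_pl)[, c("residue_a", "residue_b",
                                        "F_mean", "F_err")]
  names(pd)[3:4] <- c("F_pd", "F_pd_err")
  names(pl)[3:4] <- c("F_pl", "F_pl_err")
  out <- dplyr::full_join(pd, pl, by = c("residue_a", "residue_b"))
  out$delta_F <- out$F_pl - out$F_pd
  out$delta_F_err <- out$F_pl_err + out$F_pd_err
  mag <- pmax(abs(out$F_pd), abs(out$F_pl), na.rm = TRUE)
  out <- out[order(-mag), , drop = FALSE]
  class(out) <- c("delta_force_table", class(tibble::tibble()))
  out
}
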
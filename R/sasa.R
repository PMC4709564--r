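# Deterministic, near-uniform unit-sphere point set (Fibonacci lattice).
fibonacci_sphere <- function(n) {
  i <- seq_len(n) - 0.5
  phi <- pi * (1 + sqrt(5)) * i
  z <- 1 - 2 * i / n
  rho <- sqrt(pmax(0, 1 - z^2))
  cbind(rho * cos(phi), rho * sin(phi), z)
}

#' Van der Waals radii for SAS
#'
#' Bondi radii by element, Angstrom; unknown elements fall back to 1.70
#' (carbon). Per-atom overrides come from a `radius_override` column in the
#' topology's atom table (used by the sphere fixtures).
#'
#' @param topology A [topology()].
#' @return Per-atom radii, Angstrom.
#' @export
atom_radii <- function(topology) {
  r <- .vdw_radii[topology$atoms$element]
  r[is.na(r)] <- .vdw_radii[["X"]]
  r <- unname(r)
  if ("radius_override" %in% names(topology$atoms)) {
    ov <- topology$atoms$radius_override
    r[!is.na(ov)] <- ov[!is.na(ov)]
  }
  r
}

# polar = N/O (plus hydrogens riding on them); apolar = the rest
polar_mask <- function(topology) {
  a <- topology$atoms
  polar <- a$element %in% c("N", "O")
  h <- which(a$element == "H")
  if (length(h) > 0) {
    heavy <- which(a$element != "H")
    for (i in h) {
      # hydrogen follows its nearest preceding heavy atom in the same residue
      cand <- heavy[a$residue_index[heavy] == a$residue_index[i] &
                      a$chain_id[heavy] == a$chain_id[i] & heavy < i]
      if (length(cand) > 0) polar[i] <- polar[max(cand)]
    }
  }
  polar
}

#' Solvent-accessible surface area (Shrake-Rupley)
#'
#' Rolls a spherical probe over the structure by sphere-point sampling: each
#' atom is expanded by the probe radius, `n_points` near-uniform test points
#' are placed on the expanded sphere, and the accessible fraction is the
#' fraction of points inside no other expanded sphere. Polar area is the
#' contribution of nitrogen and oxygen atoms (with attached hydrogens);
#' apolar area is everything else.
#'
#' @param coords `n_atoms x 3` matrix, Angstrom (a single structure frame).
#' @param topology The matching [topology()]; radii from [atom_radii()].
#' @param probe Probe radius, Angstrom (default 1.4, a water molecule).
#' @param n_points Test points per atom (default 960).
#' @param subset Optional atom indices: the SAS of that sub-structure alone
#'   (other atoms removed, not merely unreported).
#' @return An object of class `sas_result`: list with `total`, `polar`,
#'   `apolar` (Angstrom^2) and `per_atom` (tibble: atom, area, polar).
#' @export
sas <- function(coords, topology, probe = 1.4, n_points = 960,
                subset = NULL) {
  radii <- atom_radii(topology)
  polar <- polar_mask(topology)
  if (!is.null(subset)) {
    coords <- coords[subset, , drop = FALSE]
    radii <- radii[subset]
    polar <- polar[subset]
    atom_ids <- subset
  } else {
    atom_ids <- seq_len(nrow(coords))
  }
  n <- nrow(coords)
  if (length(radii) != n) stop("radius missing for some atoms")
  R <- radii + probe
  pts <- fibonacci_sphere(n_points)
  area <- numeric(n)
  for (i in seq_len(n)) {
    p <- sweep(pts * R[i], 2, coords[i, ], "+")
    # neighbours whose expanded sphere can reach atom i's surface
    d2 <- rowSums(sweep(coords, 2, coords[i, ])^2)
    nb <- which(d2 < (R + R[i])^2 & seq_len(n) != i)
    acc <- rep(TRUE, n_points)
    for (j in nb) {
      if (!any(acc)) break
      dj <- rowSums(sweep(p[acc, , drop = FALSE], 2, coords[j, ])^2)
      acc[acc] <- dj >= R[j]^2
    }
    area[i] <- 4 * pi * R[i]^2 * sum(acc) / n_points
  }
  structure(list(
    total = sum(area),
    polar = sum(area[polar]),
    apolar = sum(area[!polar]),
    per_atom = tibble::tibble(atom = atom_ids, area = area, polar = polar)
  ), class = "sas_result")
}

#' @export
print.sas_result <- function(x, ...) {
  cat(sprintf("<sas_result> total %.1f A^2 (polar %.1f, apolar %.1f)\n",
              x$total, x$polar, x$apolar))
  invisible(x)
}

#' Buried interface surface between two groups over a trajectory
#'
#' Per frame, the buried surface is `SAS(a alone) + SAS(b alone) -
#' SAS(a and b together)`: the area each partner loses to the interface.
#' Symmetric in the two groups and non-negative up to sampling noise.
#'
#' @param traj A [trajectory()].
#' @param topology The matching [topology()].
#' @param group_a,group_b Disjoint atom index vectors.
#' @param probe,n_points As in [sas()].
#' @return A `traj_timeseries` tibble (`time_ps`, `value`) in Angstrom^2,
#'   with `unit` attribute; also carries `polar`/`apolar` buried columns.
#' @export
buried_surface <- function(traj, topology, group_a, group_b,
                           probe = 1.4, n_points = 960) {
  if (length(intersect(group_a, group_b)) > 0) stop("groups overlap")
  both <- sort(c(group_a, group_b))
  nf <- n_frames(traj)
  val <- pol <- apol <- numeric(nf)
  for (i in seq_len(nf)) {
    X <- frame_coords(traj, i)
    sa <- sas(X, topology, probe, n_points, subset = group_a)
    sb <- sas(X, topology, probe, n_points, subset = group_b)
    sab <- sas(X, topology, probe, n_points, subset = both)
    val[i] <- sa$total + sb$total - sab$total
    pol[i] <- sa$polar + sb$polar - sab$polar
    apol[i] <- sa$apolar + sb$apolar - sab$apolar
  }
  new_timeseries(traj$times, val, unit = "A^2",
                 extra = tibble::tibble(polar = pol, apolar = apol))
}

new_timeseries <- function(times, values, unit = "", extra = NULL) {
  out <- tibble::tibble(time_ps = times, value = values)
  if (!is.null(extra)) out <- dplyr::bind_cols(out, extra)
  attr(out, "unit") <- unit
  class(out) <- c("traj_timeseries", class(tibble::tibble()))
  out
}
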
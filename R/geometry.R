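#' RMSD time series with separate fit and measure selections
#'
#' Per frame: superpose on the fit selection's alpha-carbons (least squares,
#' proper rotation), then report the RMSD over the measure selection without
#' re-fitting. With `fit = measure` this is ordinary RMSD; with a distal
#' measure selection it reports displacement of that region relative to the
#' fitted frame of reference (e.g. one domain's excursions measured in the
#' reference frame of another).
#'
#' @param traj A [trajectory()].
#' @param fit_idx,measure_idx Atom index vectors (fit should be
#'   alpha-carbons).
#' @param reference Reference structure: a frame index into `traj` or a full
#'   `n_atoms x 3` matrix (e.g. an X-ray structure's coordinates).
#' @return A `traj_timeseries` tibble (`time_ps`, `value`), Angstrom.
#' @export
rmsd_series <- function(traj, fit_idx, measure_idx, reference = 1L) {
  if (is.numeric(reference) && length(reference) == 1) {
    reference <- frame_coords(traj, reference)
  }
  if (nrow(reference) != dim(traj$coords)[2]) {
    stop("reference atom count (", nrow(reference),
         ") must match the trajectory (", dim(traj$coords)[2], ")")
  }
  fitted <- superpose_trajectory(traj, fit_idx, reference)
  refm <- reference[measure_idx, , drop = FALSE]
  val <- vapply(seq_len(n_frames(fitted)), function(i) {
    d <- frame_coords(fitted, i)[measure_idx, , drop = FALSE] - refm
    sqrt(mean(rowSums(d^2)))
  }, numeric(1))
  new_timeseries(traj$times, val, unit = "A")
}

#' Per-residue root-mean-square fluctuation
#'
#' RMSF of each selected atom about its time-mean position after fitting
#' every frame onto the fit selection (by default the measured selection
#' itself, matching per-protein fluctuation profiles).
#'
#' @param traj A [trajectory()] (>= 2 frames).
#' @param selection Atom indices measured (typically alpha-carbons).
#' @param fit_idx Atom indices fitted on; default `selection`.
#' @param topology Optional [topology()] to label residues.
#' @return Tibble with columns `atom`, `rmsf` (Angstrom) and, with a
#'   topology, `chain_id`, `residue_index`, `residue_name`.
#' @export
rmsf_profile <- function(traj, selection, fit_idx = selection,
                         topology = NULL) {
  if (n_frames(traj) < 2) stop("RMSF needs at least 2 frames")
  fitted <- superpose_trajectory(traj, fit_idx, 1L)
  sub <- fitted$coords[, selection, , drop = FALSE]
  mean_pos <- apply(sub, c(2, 3), mean)
  dev2 <- sweep(sub, c(2, 3), mean_pos)^2
  rmsf <- sqrt(apply(dev2, 2, mean) * 3)  # mean over frames & axes -> per-atom
  out <- tibble::tibble(atom = selection, rmsf = rmsf)
  if (!is.null(topology)) {
    a <- topology$atoms[selection, ]
    out$chain_id <- a$chain_id
    out$residue_index <- a$residue_index
    out$residue_name <- a$residue_name
  }
  out
}

#' Fraction of a series below a threshold
#'
#' Exact count proportion (no interpolation), e.g. the fraction of recorded
#' configurations with RMSD below 3 Angstrom.
#'
#' @param series A `traj_timeseries` or numeric vector.
#' @param threshold Threshold in the series' unit.
#' @return Fraction in `[0, 1]`.
#' @export
fraction_below <- function(series, threshold) {
  v <- if (is.data.frame(series)) series$value else series
  if (length(v) == 0) stop("empty series")
  mean(v < threshold)
}

#' Named inter-atom distance time series
#'
#' Euclidean distances per frame between named atom pairs (e.g. the
#' alpha-carbon groove-width distances d1 and d2 across a binding cleft).
#'
#' @param traj A [trajectory()].
#' @param topology The matching [topology()].
#' @param pairs Data frame with columns `chain_a`, `residue_a`, `chain_b`,
#'   `residue_b`, optional `atom_a`, `atom_b` (default `"CA"`), optional
#'   `label`.
#' @return A tibble in long form: `label`, `time_ps`, `value` (Angstrom).
#' @export
named_distances <- function(traj, topology, pairs) {
  pairs <- tibble::as_tibble(pairs)
  if (!"atom_a" %in% names(pairs)) pairs$atom_a <- "CA"
  if (!"atom_b" %in% names(pairs)) pairs$atom_b <- "CA"
  if (!"label" %in% names(pairs)) {
    pairs$label <- paste0(pairs$chain_a, pairs$residue_a, "-",
                          pairs$chain_b, pairs$residue_b)
  }
  a <- topology$atoms
  find_atom <- function(chain, resid, name) {
    idx <- which(a$chain_id == chain & a$residue_index == resid &
                   a$name == name)
    if (length(idx) != 1) {
      stop("cannot resolve atom ", chain, ":", resid, ":", name,
           " (", length(idx), " matches)")
    }
    idx
  }
  purrr::pmap_dfr(pairs, function(chain_a, residue_a, chain_b, residue_b,
                                  atom_a, atom_b, label, ...) {
    i <- find_atom(chain_a, residue_a, atom_a)
    j <- find_atom(chain_b, residue_b, atom_b)
    xi <- matrix(traj$coords[, i, ], ncol = 3)
    xj <- matrix(traj$coords[, j, ], ncol = 3)
    d <- sqrt(rowSums((xi - xj)^2))
    tibble::tibble(label = label, time_ps = traj$times, value = d)
  })
}

#' Minimum inter-group distance time series
#'
#' Per frame, the minimum over all atom pairs between two selections (e.g.
#' the minimum domain-domain distance used to monitor interface rupture).
#'
#' @param traj A [trajectory()].
#' @param group_a,group_b Atom index vectors.
#' @return A `traj_timeseries` tibble, Angstrom.
#' @export
min_distance_series <- function(traj, group_a, group_b) {
  val <- vapply(seq_len(n_frames(traj)), function(i) {
    X <- frame_coords(traj, i)
    A <- X[group_a, , drop = FALSE]
    B <- X[group_b, , drop = FALSE]
    d2 <- outer(rowSums(A^2), rowSums(B^2), "+") - 2 * tcrossprod(A, B)
    sqrt(max(0, min(d2)))
  }, numeric(1))
  new_timeseries(traj$times, val, unit = "A")
}

#' Equilibration windowing
#'
#' Discards the leading fraction of a trajectory or time series before any
#' equilibrium average (default: keep the final 90%).
#'
#' @param x A [trajectory()] or `traj_timeseries`.
#' @param discard_fraction Leading fraction to drop (default 0.10).
#' @return Same type as `x`.
#' @export
discard_equilibration <- function(x, discard_fraction = 0.10) {
  if (discard_fraction < 0 || discard_fraction >= 1) {
    stop("discard_fraction must be in [0, 1)")
  }
  if (inherits(x, "traj_frames")) {
    n <- n_frames(x)
    keep <- seq.int(floor(n * discard_fraction) + 1, n)
    return(subset_frames(x, keep))
  }
  n <- nrow(x)
  x[seq.int(floor(n * discard_fraction) + 1, n), , drop = FALSE]
}

#' Centered moving average of a time series
#'
#' Moving average over a window expressed in ps (e.g. 1000 ps = 1 ns),
#' centered, with edge truncation (windows shrink near the ends rather than
#' padding).
#'
#' @param series A `traj_timeseries`.
#' @param window_ps Window width, ps; must not exceed the series span.
#' @return The series with `value` replaced by its moving average.
#' @export
moving_average <- function(series, window_ps) {
  t <- series$time_ps
  span <- diff(range(t))
  if (length(t) > 1 && window_ps > span) {
    stop("moving-average window (", window_ps, " ps) exceeds the series span (",
         span, " ps)")
  }
  half <- window_ps / 2
  v <- series$value
  out <- vapply(seq_along(t), function(i) {
    mean(v[t >= t[i] - half & t <= t[i] + half])
  }, numeric(1))
  series$value <- out
  series
}

#' Histogram summary of a series (distribution panels)
#'
#' @param series A `traj_timeseries` or numeric vector.
#' @param breaks Passed to [graphics::hist()] semantics via
#'   [base::cut()]-free binning: either a bin width or a vector of break
#'   points.
#' @return Tibble with `mid`, `count`, `density`.
#' @export
series_histogram <- function(series, breaks = 30) {
  v <- if (is.data.frame(series)) series$value else series
  h <- graphics::hist(v, breaks = breaks, plot = FALSE)
  tibble::tibble(mid = h$mids, count = h$counts, density = h$density)
}
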
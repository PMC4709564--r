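#' Positional covariance after rigid-body fitting
#'
#' Computes the `3n x 3n` covariance matrix of Cartesian positional
#' fluctuations of the selected atoms about their time mean, after removing
#' overall translation and rotation by least-squares fitting every frame onto
#' a reference structure over the same selection. The covariance is the input
#' to [schlitter_entropy()].
#'
#' @param traj A [trajectory()] (at least 2 frames).
#' @param selection Atom indices (typically alpha-carbons, see
#'   [resolve_selection()]).
#' @param reference Frame index (into `traj`) or full-system `n_atoms x 3`
#'   matrix used as the fit reference; default the first frame of the
#'   analysed window.
#' @param fit `"kabsch"` (default) removes rigid-body motion;
#'   `"none"` uses raw coordinates, appropriate for ensembles known to carry
#'   no rigid-body component (e.g. the package's Gaussian generators). With
#'   fewer than 3 selected atoms only translation is removed under
#'   `"kabsch"`; for a single atom fitting is disabled entirely.
#' @param selection_name Label carried into the result.
#' @return An object of class `covariance_result`: list with `matrix`
#'   (Angstrom^2, symmetric), `selection`, `selection_name`, `n_frames`,
#'   `fit`.
#' @export
fit_and_covariance <- function(traj, selection, reference = 1L,
                               fit = c("kabsch", "none"),
                               selection_name = "selection") {
  fit <- match.arg(fit)
  if (n_frames(traj) < 2) stop("covariance needs at least 2 frames")
  if (length(selection) < 1) stop("empty selection")
  if (fit == "kabsch" && length(selection) > 1) {
    if (length(selection) >= 3) {
      check_fit_selection(frame_coords(traj, 1)[selection, , drop = FALSE],
                          paste0("selection '", selection_name, "'"))
    }
    traj <- superpose_trajectory(traj, selection, reference)
  }
  nf <- n_frames(traj)
  X <- matrix(traj$coords[, selection, , drop = FALSE], nrow = nf)
  # coords[,sel,] flattens atom-major then axis-major: columns are
  # (a1x,a2x,...,a1y,...); reorder to (a1x,a1y,a1z,a2x,...)
  natom <- length(selection)
  perm <- as.vector(vapply(seq_len(natom),
                           function(a) a + natom * (0:2), numeric(3)))
  X <- X[, perm, drop = FALSE]
  Xc <- sweep(X, 2, colMeans(X))
  C <- crossprod(Xc) / nf
  C <- (C + t(C)) / 2
  structure(list(matrix = C, selection = selection,
                 selection_name = selection_name, n_frames = nf, fit = fit),
            class = "covariance_result")
}

#' @export
print.covariance_result <- function(x, ...) {
  cat("<covariance_result> '", x$selection_name, "': ",
      nrow(x$matrix), " x ", nrow(x$matrix), " (", length(x$selection),
      " atoms), ", x$n_frames, " frames, fit = ", x$fit, "\n", sep = "")
  invisible(x)
}

#' Quasi-harmonic (Schlitter) configurational entropy
#'
#' Evaluates the quasi-harmonic upper bound on the configurational entropy
#' from the mass-weighted positional covariance,
#' \deqn{S = \frac{R}{2}\,\ln\det\left[\mathbf{1} +
#'   \frac{k_B T e^2}{\hbar^2}\, \mathbf{M}^{1/2}\mathbf{C}\,\mathbf{M}^{1/2}
#'   \right],}
#' with \eqn{k_B} the Boltzmann constant, \eqn{T} the temperature, \eqn{e}
#' Euler's number, \eqn{\hbar} the reduced Planck constant, \eqn{\mathbf{M}}
#' the diagonal mass matrix and \eqn{\mathbf{C}} the covariance matrix of
#' particle fluctuations. The determinant is evaluated through the
#' eigenvalues of the symmetrized mass-weighted covariance (never a raw
#' determinant), which is numerically stable and guarantees symmetry; small
#' negative eigenvalues (roundoff) are clipped to zero. The result is molar,
#' J/(K mol).
#'
#' @param cov A `covariance_result` from [fit_and_covariance()], or a bare
#'   symmetric `3n x 3n` matrix in Angstrom^2.
#' @param masses Per-atom masses, u (length `n`).
#' @param temperature Temperature, K.
#' @return An object of class `entropy_result`: a one-row tibble with columns
#'   `selection`, `S_config` (J/(K mol)), `uncertainty` (NA here; see
#'   [entropy_uncertainty()]), `temperature`, `n_frames`, `n_atoms`.
#' @export
schlitter_entropy <- function(cov, masses, temperature = .default_temperature) {
  if (inherits(cov, "covariance_result")) {
    label <- cov$selection_name
    nf <- cov$n_frames
    C <- cov$matrix
  } else {
    label <- "selection"
    nf <- NA_integer_
    C <- cov
  }
  if (temperature <= 0) stop("temperature must be > 0")
  if (any(masses <= 0)) stop("masses must be > 0")
  n <- nrow(C) / 3
  if (n != length(masses)) {
    stop("covariance is for ", n, " atoms but ", length(masses),
         " masses given")
  }
  S <- schlitter_from_matrix(C, masses, temperature)
  new_entropy_result(label, S, NA_real_, temperature, nf, n)
}

# Core evaluation; C in Angstrom^2, masses in u. Returns J/(K mol).
schlitter_from_matrix <- function(C, masses, temperature) {
  msqrt <- rep(sqrt(masses * .const$u_kg), each = 3)
  alpha <- .const$kB * temperature * exp(2) / .const$hbar^2
  A <- alpha * .const$A2_to_m2 * (msqrt * C * rep(msqrt, each = length(msqrt)))
  A <- (A + t(A)) / 2
  ev <- eigen(A, symmetric = TRUE, only.values = TRUE)$values
  if (any(ev < -1e-8)) {
    stop("mass-weighted covariance has a substantially negative eigenvalue (",
         format(min(ev)), "); not a valid covariance")
  }
  ev[ev < 0] <- 0
  (.const$R / 2) * sum(log1p(ev))
}

new_entropy_result <- function(selection, S, uncertainty, temperature,
                               n_frames, n_atoms) {
  out <- tibble::tibble(
    selection = selection, S_config = S, uncertainty = uncertainty,
    temperature = temperature, n_frames = as.integer(n_frames),
    n_atoms = as.integer(n_atoms)
  )
  class(out) <- c("entropy_result", class(out))
  out
}

#' Per-domain configurational entropy decomposition
#'
#' Computes the Schlitter entropy for each named selection of a domain map
#' (alpha-carbon atoms) and for the whole set of mapped atoms. The
#' decomposition assigns entropy changes to structural elements but neglects
#' inter-domain correlations: the entropy of the whole is not the sum of the
#' parts.
#'
#' @param traj A [trajectory()].
#' @param topology The matching [topology()].
#' @param map A [domain_map()].
#' @param temperature Temperature, K.
#' @param fit `"per_domain"` (default) fits each domain onto its own
#'   selection, measuring internal fluctuations only; `"global"` fits every
#'   frame once on all mapped alpha-carbons; `"none"` uses raw coordinates.
#' @param whole Name for the all-domains row; `NULL` suppresses it.
#' @param uncertainty If `TRUE` (default), attach the cumulative-sampling
#'   uncertainty of [entropy_uncertainty()] to every row.
#' @return An `entropy_result` tibble with one row per selection (plus the
#'   whole), columns as in [schlitter_entropy()].
#' @export
entropy_by_domain <- function(traj, topology, map,
                              temperature = .default_temperature,
                              fit = c("per_domain", "global", "none"),
                              whole = "whole", uncertainty = TRUE) {
  fit <- match.arg(fit)
  sels <- lapply(names(map), function(nm) {
    resolve_selection(map, nm, topology, atom_filter = "CA")
  })
  names(sels) <- names(map)
  all_idx <- sort(unique(unlist(sels)))
  if (fit == "global") {
    traj <- superpose_trajectory(traj, all_idx, 1L)
  }
  fit_mode <- if (fit == "per_domain") "kabsch" else "none"
  one <- function(nm, idx) {
    cov <- fit_and_covariance(traj, idx, fit = fit_mode, selection_name = nm)
    res <- schlitter_entropy(cov, topology$mass[idx], temperature)
    if (uncertainty) {
      res$uncertainty <- entropy_uncertainty(traj, idx, topology$mass[idx],
                                             temperature, fit = fit_mode)
    }
    res
  }
  rows <- purrr::map2(names(sels), sels, one)
  if (!is.null(whole)) rows <- c(rows, list(one(whole, all_idx)))
  out <- dplyr::bind_rows(rows)
  class(out) <- c("entropy_result", class(tibble::tibble()))
  out
}

#' Sampling-convergence uncertainty of the Schlitter entropy
#'
#' The quasi-harmonic entropy grows with sampling; its convergence error is
#' estimated as the difference between the entropy of the full window and the
#' entropy of the first 90% of it (both computed with growing-window
#' covariances from the same origin), i.e. the change contributed by the
#' final 10% of cumulative sampling.
#'
#' @inheritParams fit_and_covariance
#' @param masses Per-atom masses for the selection, u.
#' @param temperature Temperature, K.
#' @param final_fraction Fraction of cumulative sampling whose contribution
#'   is reported (default 0.10).
#' @return Uncertainty in J/(K mol), `>= 0`.
#' @export
entropy_uncertainty <- function(traj, selection, masses,
                                temperature = .default_temperature,
                                fit = c("kabsch", "none"),
                                final_fraction = 0.10) {
  fit <- match.arg(fit)
  nf <- n_frames(traj)
  if (nf < 10) stop("uncertainty estimate needs at least 10 frames")
  n90 <- floor(nf * (1 - final_fraction))
  S_all <- schlitter_entropy(
    fit_and_covariance(traj, selection, fit = fit), masses, temperature)$S_config
  S_90 <- schlitter_entropy(
    fit_and_covariance(subset_frames(traj, seq_len(n90)), selection, fit = fit),
    masses, temperature)$S_config
  abs(S_all - S_90)
}

#' Solvent entropy from buried polar/apolar surface
#'
#' Quasi-harmonic analysis cannot treat the solvent; the solvent contribution
#' is instead estimated from an empirical linear relationship between changes
#' in polar and apolar solvent-accessible surface and solvent entropy:
#' `dS_solv = a_polar * dSAS_polar + a_apolar * dSAS_apolar`. This is a
#' rough, qualitative estimate intended for mechanistic interpretation, not a
#' quantitative free-energy term.
#'
#' @param delta_sas_polar,delta_sas_apolar Surface changes, Angstrom^2
#'   (complex minus components, so burial is negative).
#' @param coeffs Coefficients from [solvent_entropy_coefficients()]; must be
#'   supplied explicitly or via the documented default.
#' @return Solvent entropy change, J/(K mol).
#' @export
solvent_entropy <- function(delta_sas_polar, delta_sas_apolar, coeffs) {
  if (missing(coeffs) || is.null(coeffs)) {
    stop("solvent-entropy coefficients must be supplied explicitly; ",
         "see solvent_entropy_coefficients()")
  }
  stopifnot(is.finite(coeffs$a_polar), is.finite(coeffs$a_apolar))
  coeffs$a_polar * delta_sas_polar + coeffs$a_apolar * delta_sas_apolar
}

#' @rdname solvent_entropy
#' @param a_polar,a_apolar Coefficients, J/(K mol Angstrom^2).
#' @param provenance Free-text provenance note carried with the values.
#' @export
solvent_entropy_coefficients <- function(a_polar, a_apolar,
                                         provenance = "user-supplied") {
  structure(list(a_polar = a_polar, a_apolar = a_apolar,
                 provenance = provenance),
            class = "solvent_entropy_coefficients")
}

#' @rdname solvent_entropy
#' @details `default_solvent_entropy_coefficients()` returns
#'   hydration-entropy coefficients per unit buried surface derived from
#'   literature calorimetric parameterisations (about -0.46 J/(K mol A^2)
#'   polar and +1.26 J/(K mol A^2) apolar at 300 K, signed so that burying
#'   apolar surface releases solvent entropy). Literature values: verify
#'   before quantitative use.
#' @export
default_solvent_entropy_coefficients <- function() {
  solvent_entropy_coefficients(
    a_polar = -0.46, a_apolar = 1.26,
    provenance = paste("literature hydration-entropy coefficients at 300 K;",
                       "verify before quantitative use"))
}

#' @rdname solvent_entropy
#' @param delta_s_config Configurational entropy change, J/(K mol).
#' @param delta_s_solv Solvent entropy change, J/(K mol).
#' @return `total_entropy()`: the sum of the configurational and solvent
#'   entropy changes, J/(K mol).
#' @export
total_entropy <- function(delta_s_config, delta_s_solv) {
  delta_s_config + delta_s_solv
}
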
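#' Synthetic Gaussian positional ensembles with known entropy
#'
#' Generates i.i.d. multivariate-Gaussian coordinate frames with a prescribed
#' `3N x 3N` covariance (Angstrom^2), the statistical structure the
#' quasi-harmonic entropy machinery assumes. Because the covariance is known
#' exactly, the Schlitter entropy of the generating distribution is available
#' in closed form and is returned alongside the trajectory as ground truth.
#' Frames are independent by design (the estimators under test are ensemble
#' averages); an AR(1) mode exists solely to exercise block-averaged error
#' estimation.
#'
#' @param masses Per-particle masses, u.
#' @param covariance `3N x 3N` symmetric positive-semidefinite matrix,
#'   Angstrom^2. Eigenvalues down to `-1e-10` are clipped to zero; more
#'   negative is an error.
#' @param mean `3N` vector of mean positions, Angstrom (default: particles
#'   spread 10 Angstrom apart on the x axis, so selections and SAS stay
#'   sane).
#' @param n_frames Number of frames (>= 2).
#' @param seed Integer seed; same seed, same bytes.
#' @param temperature Temperature for the analytic entropy, K.
#' @param dt Frame spacing, ps.
#' @param ar1 Optional AR(1) coefficient in `[0, 1)`; 0 (default) gives
#'   i.i.d. frames. The stationary covariance is held equal to `covariance`.
#' @return A list: `trajectory` (a [trajectory()]), `topology` (CA-bead
#'   [topology()], one residue per particle), `analytic_entropy` (J/(K mol),
#'   the closed-form Schlitter value for the specified covariance and
#'   masses), `covariance`, `masses`, `temperature`.
#' @export
#' @examples
#' g <- gaussian_trajectory(masses = 12, covariance = diag(0.25, 3),
#'                          n_frames = 100, seed = 1)
#' g$analytic_entropy
gaussian_trajectory <- function(masses, covariance, mean = NULL,
                                n_frames = 1000, seed = 1,
                                temperature = .default_temperature,
                                dt = 1, ar1 = 0) {
  N <- length(masses)
  if (!is.matrix(covariance) || nrow(covariance) != 3 * N ||
      ncol(covariance) != 3 * N) {
    stop("covariance must be 3N x 3N with N = length(masses) = ", N)
  }
  if (max(abs(covariance - t(covariance))) > 1e-8) {
    stop("covariance must be symmetric")
  }
  if (n_frames < 2) stop("n_frames must be >= 2")
  if (ar1 < 0 || ar1 >= 1) stop("ar1 must be in [0, 1)")
  C <- (covariance + t(covariance)) / 2
  ed <- eigen(C, symmetric = TRUE)
  ev <- ed$values
  if (any(ev < -1e-10)) {
    stop("covariance not positive semidefinite (eigenvalue ",
         format(min(ev)), ")")
  }
  ev[ev < 0] <- 0
  if (is.null(mean)) {
    mean <- as.vector(t(cbind(10 * (seq_len(N) - 1), 0, 0)))
  }
  if (length(mean) != 3 * N) stop("mean must have length 3N")
  L <- ed$vectors %*% (sqrt(ev) * t(ed$vectors))  # symmetric square root
  set.seed(seed)
  if (ar1 == 0) {
    Z <- matrix(stats::rnorm(n_frames * 3 * N), nrow = n_frames)
  } else {
    # AR(1) innovations scaled to keep the stationary covariance at C
    Z <- matrix(NA_real_, n_frames, 3 * N)
    Z[1, ] <- stats::rnorm(3 * N)
    sd_innov <- sqrt(1 - ar1^2)
    for (i in 2:n_frames) {
      Z[i, ] <- ar1 * Z[i - 1, ] + sd_innov * stats::rnorm(3 * N)
    }
  }
  X <- Z %*% L
  X <- sweep(X, 2, mean, "+")
  coords <- array(NA_real_, dim = c(n_frames, N, 3))
  for (a in seq_len(N)) {
    coords[, a, ] <- X[, (3 * a - 2):(3 * a)]
  }
  top <- bead_topology(N, masses = masses)
  list(
    trajectory = trajectory(coords, times = dt * (seq_len(n_frames) - 1)),
    topology = top,
    analytic_entropy = schlitter_from_matrix(C, masses, temperature),
    covariance = C, masses = masses, temperature = temperature
  )
}

# One CA bead per residue on chain "A"; the plumbing all generators share.
bead_topology <- function(N, masses = NULL, charge = NULL,
                          lj_sigma = NULL, lj_epsilon = NULL,
                          chain = "A", element = "C", name = "CA",
                          residue_index = seq_len(N)) {
  topology(
    tibble::tibble(
      serial = seq_len(N), name = name, element = element,
      residue_index = as.integer(residue_index), residue_name = "GLY",
      chain_id = chain),
    mass = if (is.null(masses)) rep(12.011, N) else masses,
    charge = charge, lj_sigma = lj_sigma, lj_epsilon = lj_epsilon
  )
}

#' Paired ensembles differing by a controlled covariance change
#'
#' Builds two Gaussian ensembles emulating two states of a system (e.g.
#' peptide-deficient vs peptide-loaded): the second state's covariance equals
#' the first's with the rows/columns of a particle subset scaled by `scale`
#' (so the subset's diagonal block is scaled by `scale^2`). When the subset
#' is independent of the rest, the entropy difference is known in closed
#' form, which makes the pair a parameter-recovery harness for per-domain
#' entropy decomposition.
#'
#' @param masses,covariance,mean,n_frames,seed,temperature,dt As in
#'   [gaussian_trajectory()].
#' @param scale Positive factor applied to the subset's fluctuations.
#' @param subset Particle indices (1-based) whose fluctuations change.
#' @return List: `pd`, `pl` (each as returned by [gaussian_trajectory()];
#'   `pd` is the base ensemble), `analytic_delta_S` (J/(K mol),
#'   `S(pl) - S(pd)` from the closed form), `subset`, `scale`.
#' @export
pd_pl_pair <- function(masses, covariance, scale, subset, mean = NULL,
                       n_frames = 1000, seed = 1,
                       temperature = .default_temperature, dt = 1) {
  if (scale <= 0) stop("scale must be > 0")
  if (length(subset) == 0) stop("subset must not be empty")
  N <- length(masses)
  if (any(subset < 1 | subset > N)) stop("subset out of range")
  d <- rep(1, 3 * N)
  for (a in subset) d[(3 * a - 2):(3 * a)] <- scale
  cov_pl <- d * covariance * rep(d, each = 3 * N)
  pd <- gaussian_trajectory(masses, covariance, mean, n_frames, seed,
                            temperature, dt)
  pl <- gaussian_trajectory(masses, cov_pl, mean, n_frames, seed + 1,
                            temperature, dt)
  list(pd = pd, pl = pl,
       analytic_delta_S = pl$analytic_entropy - pd$analytic_entropy,
       subset = subset, scale = scale)
}

#' Two-group charged/Lennard-Jones bead complexes
#'
#' Builds a small complex of two disjoint bead groups with explicit charges
#' and LJ parameters, one bead per residue by default, as the oracle
#' substrate for pairwise force analysis: with few beads the exact
#' residue-pair forces are available by direct summation. Frames are the
#' static input positions, optionally with seeded isotropic Gaussian jitter.
#'
#' @param pos1,pos2 `n x 3` matrices of bead positions, Angstrom.
#' @param charge1,charge2 Per-bead charges, e.
#' @param sigma1,sigma2 Per-bead LJ sigma, nm (default 0: LJ off).
#' @param epsilon1,epsilon2 Per-bead LJ epsilon, kJ/mol (default 0).
#' @param residue1,residue2 Per-bead residue indices within each group
#'   (default: one residue per bead).
#' @param n_frames Number of frames.
#' @param jitter Gaussian positional jitter s.d., Angstrom (0 = static).
#' @param seed Seed for the jitter.
#' @return List: `topology` (groups on chains "A" and "B"), `trajectory`,
#'   `group1`, `group2` (atom index vectors).
#' @export
bead_complex <- function(pos1, pos2, charge1, charge2,
                         sigma1 = 0, sigma2 = 0, epsilon1 = 0, epsilon2 = 0,
                         residue1 = NULL, residue2 = NULL,
                         n_frames = 1, jitter = 0, seed = 1) {
  pos1 <- rbind(pos1); pos2 <- rbind(pos2)
  n1 <- nrow(pos1); n2 <- nrow(pos2)
  if (n1 < 1 || n2 < 1) stop("each group needs at least one bead")
  rec <- function(x, n) if (length(x) == 1) rep(x, n) else x
  charge1 <- rec(charge1, n1); charge2 <- rec(charge2, n2)
  sigma1 <- rec(sigma1, n1); sigma2 <- rec(sigma2, n2)
  epsilon1 <- rec(epsilon1, n1); epsilon2 <- rec(epsilon2, n2)
  if (is.null(residue1)) residue1 <- seq_len(n1)
  if (is.null(residue2)) residue2 <- seq_len(n2)
  top <- topology(
    tibble::tibble(
      serial = seq_len(n1 + n2), name = "CA", element = "C",
      residue_index = as.integer(c(residue1, residue2)),
      residue_name = "GLY",
      chain_id = rep(c("A", "B"), c(n1, n2))),
    mass = rep(12.011, n1 + n2),
    charge = c(charge1, charge2),
    lj_sigma = c(sigma1, sigma2),
    lj_epsilon = c(epsilon1, epsilon2)
  )
  base <- rbind(pos1, pos2)
  coords <- array(NA_real_, dim = c(n_frames, n1 + n2, 3))
  set.seed(seed)
  for (i in seq_len(n_frames)) {
    coords[i, , ] <- base +
      if (jitter > 0) matrix(stats::rnorm((n1 + n2) * 3, sd = jitter),
                             ncol = 3) else 0
  }
  list(topology = top,
       trajectory = trajectory(coords, times = seq_len(n_frames) - 1),
       group1 = seq_len(n1), group2 = n1 + seq_len(n2))
}

#' Sphere-cluster fixtures with analytic surface area
#'
#' Pseudo-atom clusters whose solvent-accessible surface is known in closed
#' form (isolated spheres, and the two-sphere overlap via the spherical-cap
#' formula), used to validate the surface-area stage. Per-atom radii are
#' honoured by [sas()] through the `radius_override` attribute.
#'
#' @param radii Per-sphere van der Waals radii, Angstrom (> 0).
#' @param centers `n x 3` matrix of centers, Angstrom.
#' @return List: `topology` (with per-atom `radius_override` column in
#'   `atoms`), `coords` (`n x 3`), `trajectory` (single frame).
#' @export
sphere_fixture <- function(radii, centers) {
  centers <- rbind(centers)
  if (any(radii <= 0)) stop("radii must be > 0")
  if (nrow(centers) != length(radii)) stop("one center per radius required")
  n <- length(radii)
  top <- bead_topology(n)
  top$atoms$radius_override <- as.numeric(radii)
  list(topology = top, coords = centers,
       trajectory = trajectory(centers, times = 0))
}

#' Analytic solvent-accessible area of two overlapping spheres
#'
#' Closed-form reference for the two-sphere case: each sphere of expanded
#' radius `r + probe` loses the spherical cap hidden inside the other.
#'
#' @param r1,r2 Sphere radii, Angstrom.
#' @param d Center separation, Angstrom.
#' @param probe Probe radius, Angstrom.
#' @return List: `total` accessible area, `per_sphere` (length 2),
#'   `buried` (the two-cap area = sum of isolated areas minus `total`);
#'   Angstrom^2.
#' @export
two_sphere_reference <- function(r1, r2, d, probe = 1.4) {
  R1 <- r1 + probe; R2 <- r2 + probe
  iso <- 4 * pi * c(R1^2, R2^2)
  if (d >= R1 + R2) {
    return(list(total = sum(iso), per_sphere = iso, buried = 0))
  }
  if (d <= abs(R1 - R2)) {
    # one expanded sphere inside the other: the smaller is fully buried
    inner <- which.min(c(R1, R2))
    per <- iso; per[inner] <- 0
    return(list(total = sum(per), per_sphere = per, buried = iso[inner]))
  }
  # cap heights from the radical plane
  h1 <- R1 - (d^2 + R1^2 - R2^2) / (2 * d)
  h2 <- R2 - (d^2 + R2^2 - R1^2) / (2 * d)
  per <- c(iso[1] - 2 * pi * R1 * h1, iso[2] - 2 * pi * R2 * h2)
  list(total = sum(per), per_sphere = per, buried = sum(iso) - sum(per))
}
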
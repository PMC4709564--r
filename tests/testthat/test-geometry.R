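test_that("SAS closed forms: single sphere, separated spheres, overlap", {
  sf <- sphere_fixture(1.9, c(0, 0, 0))
  s <- sas(sf$coords, sf$topology, n_points = 960)
  expect_equal(s$total, 4 * pi * 3.3^2, tolerance = 0.005)
  # far apart: sum of isolated areas
  far <- sphere_fixture(c(1.9, 1.5), rbind(c(0, 0, 0), c(30, 0, 0)))
  s2 <- sas(far$coords, far$topology, n_points = 960)
  expect_equal(s2$total, 4 * pi * (3.3^2 + 2.9^2), tolerance = 0.005)
  # overlapping: two-cap reference
  ref <- two_sphere_reference(1.9, 1.9, 4)
  ov <- sphere_fixture(c(1.9, 1.9), rbind(c(0, 0, 0), c(4, 0, 0)))
  s3 <- sas(ov$coords, ov$topology, n_points = 960)
  expect_equal(s3$total, ref$total, tolerance = 0.005)
})

test_that("polar/apolar split sums to the total and follows elements", {
  top <- toy_peptide_topology()
  coords <- random_structure(9, seed = 8, spread = 3)
  s <- sas(coords, top)
  expect_equal(s$total, s$polar + s$apolar, tolerance = 1e-9)
  expect_equal(sum(s$per_atom$polar), 3)  # the three backbone N atoms
  expect_gt(s$polar, 0)
})

test_that("buried surface is symmetric, vanishes for separated groups, and shrinks with distance", {
  far <- sphere_fixture(c(1.9, 1.9), rbind(c(0, 0, 0), c(30, 0, 0)))
  expect_equal(buried_surface(far$trajectory, far$topology, 1, 2)$value, 0)
  ov <- sphere_fixture(c(1.9, 1.9), rbind(c(0, 0, 0), c(4, 0, 0)))
  ab <- buried_surface(ov$trajectory, ov$topology, 1, 2)$value
  ba <- buried_surface(ov$trajectory, ov$topology, 2, 1)$value
  expect_identical(ab, ba)
  # monotone decrease as the spheres separate
  d <- c(3, 4, 5, 6, 7)
  bur <- vapply(d, function(dd) {
    fx <- sphere_fixture(c(1.9, 1.9), rbind(c(0, 0, 0), c(dd, 0, 0)))
    buried_surface(fx$trajectory, fx$topology, 1, 2)$value
  }, numeric(1))
  expect_true(all(diff(bur) < 0))
  expect_error(buried_surface(ov$trajectory, ov$topology, 1:2, 2), "overlap")
})

test_that("fit/measure RMSD reduces to ordinary RMSD and reports distal displacement", {
  base <- random_structure(6, seed = 12)
  static <- trajectory(array(rep(base, each = 3), c(3, 6, 3)))
  rs <- rmsd_series(static, 1:6, 1:6, reference = 1)
  expect_equal(rs$value, rep(0, 3))
  # rigid rotation of the whole: zero when fit = measure
  rigid <- rigid_motion_traj(base, 10)
  expect_lt(max(rmsd_series(rigid, 1:6, 1:6, reference = 1)$value), 1e-9)
  # hand case: two-atom measure selection displaced by (3,4,0) after fit
  base2 <- rbind(c(0, 0, 0), c(1, 0, 0), c(0, 1, 0),
                 c(5, 5, 5), c(6, 5, 5))
  fr2 <- base2
  fr2[4:5, ] <- fr2[4:5, ] + matrix(rep(c(3, 4, 0), each = 2), 2)
  coords <- array(NA_real_, c(2, 5, 3))
  coords[1, , ] <- base2; coords[2, , ] <- fr2
  rs2 <- rmsd_series(trajectory(coords), fit_idx = 1:3, measure_idx = 4:5,
                     reference = 1)
  expect_equal(rs2$value, c(0, 5))
})

test_that("rigid rotation of a two-domain toy leaves fit-selection RMSD zero but moves the distal domain", {
  base <- rbind(random_structure(4, seed = 3),
                random_structure(4, seed = 4) + 20)
  th <- 0.3
  Rz <- matrix(c(cos(th), -sin(th), 0, sin(th), cos(th), 0, 0, 0, 1),
               3, 3, byrow = TRUE)
  fr2 <- base
  fr2[5:8, ] <- sweep(sweep(fr2[5:8, ], 2, colMeans(fr2[1:4, ])) %*% t(Rz),
                      2, -colMeans(fr2[1:4, ]), "-")
  coords <- array(NA_real_, c(2, 8, 3))
  coords[1, , ] <- base; coords[2, , ] <- fr2
  tr <- trajectory(coords)
  expect_lt(max(rmsd_series(tr, 1:4, 1:4, reference = 1)$value), 1e-9)
  expect_gt(rmsd_series(tr, 1:4, 5:8, reference = 1)$value[2], 1)
})

test_that("fraction below a threshold is an exact count proportion", {
  s <- trajectory(array(0, c(1, 1, 3)))  # unused; plain numeric path
  expect_equal(fraction_below(c(1, 2, 3, 4), 2.5), 0.5)
  expect_equal(fraction_below(c(1, 2), 10), 1)
  expect_equal(fraction_below(c(5, 6), 1), 0)
  expect_error(fraction_below(numeric(0), 1), "empty")
})

test_that("RMSF: zero for static or rigid motion, exact for a known oscillation", {
  base <- random_structure(5, seed = 9)
  rigid <- rigid_motion_traj(base, 8)
  rp <- rmsf_profile(rigid, 1:5)
  expect_lt(max(rp$rmsf), 1e-9)
  # one atom oscillating +-1 A about its mean on x, fit on the fixed atoms
  coords <- array(rep(base, each = 2), c(2, 5, 3))
  coords[1, 5, 1] <- base[5, 1] + 1
  coords[2, 5, 1] <- base[5, 1] - 1
  rp2 <- rmsf_profile(trajectory(coords), selection = 1:5, fit_idx = 1:4)
  expect_equal(rp2$rmsf[5], 1, tolerance = 1e-9)
  expect_lt(max(rp2$rmsf[1:4]), 1e-9)
})

test_that("named and minimum distances do plain Euclidean geometry", {
  top <- bead_topology_for_distances <- topology(tibble::tibble(
    serial = 1:3, name = "CA", element = "C", residue_index = 1:3,
    residue_name = "GLY", chain_id = "A"))
  coords <- array(NA_real_, c(1, 3, 3))
  coords[1, 1, ] <- c(0, 0, 0)
  coords[1, 2, ] <- c(3, 4, 0)
  coords[1, 3, ] <- c(0, 0, 0)
  tr <- trajectory(coords)
  d <- named_distances(tr, top, data.frame(
    chain_a = "A", residue_a = 1, chain_b = "A", residue_b = 2))
  expect_equal(d$value, 5)
  d0 <- named_distances(tr, top, data.frame(
    chain_a = "A", residue_a = 1, chain_b = "A", residue_b = 3))
  expect_equal(d0$value, 0)
  expect_error(named_distances(tr, top, data.frame(
    chain_a = "A", residue_a = 9, chain_b = "A", residue_b = 1)), "resolve")
  # min distance <= any named pair distance
  md <- min_distance_series(tr, 1, 2:3)
  expect_lte(md$value, d$value)
  expect_equal(md$value, 0)
})

test_that("windowing discards the leading fraction and averages with edge truncation", {
  g <- gaussian_trajectory(rep(12, 2), diag(0.1, 6), n_frames = 100,
                           seed = 2)
  w <- discard_equilibration(g$trajectory, 0.10)
  expect_equal(n_frames(w), 90)
  expect_equal(w$times[1], g$trajectory$times[11])
  # constant series unchanged
  ts <- structure(tibble::tibble(time_ps = 0:99, value = rep(2, 100)),
                  class = c("traj_timeseries", class(tibble::tibble())))
  expect_equal(moving_average(ts, 10)$value, rep(2, 100))
  # alternating +-1 with an even window: interior averages are ~0
  ts2 <- structure(tibble::tibble(time_ps = 0:99,
                                  value = rep(c(1, -1), 50)),
                   class = c("traj_timeseries", class(tibble::tibble())))
  sm <- moving_average(ts2, 3)
  expect_lt(max(abs(sm$value[5:95])), 0.5)
  expect_error(moving_average(ts2, 1e6), "exceeds")
})

test_that("equilibrium statistics barely move as the discard fraction varies on converged data", {
  g <- gaussian_trajectory(rep(12, 2), diag(0.25, 6), n_frames = 20000,
                           seed = 43)
  stats_at <- vapply(c(0.05, 0.10, 0.15), function(fr) {
    w <- discard_equilibration(g$trajectory, fr)
    schlitter_entropy(fit_and_covariance(w, 1:2, fit = "none"),
                      g$masses)$S_config
  }, numeric(1))
  expect_lt(diff(range(stats_at)) / mean(stats_at), 0.01)
})

test_that("RMSD and RMSF are invariant under a global rigid transform of all frames", {
  g <- gaussian_trajectory(rep(12, 5), diag(0.2, 15), n_frames = 50,
                           seed = 77)
  tr <- g$trajectory
  th <- 1.1
  Rz <- matrix(c(cos(th), -sin(th), 0, sin(th), cos(th), 0, 0, 0, 1),
               3, 3, byrow = TRUE)
  moved <- tr$coords
  for (i in seq_len(50)) {
    moved[i, , ] <- tr$coords[i, , ] %*% t(Rz) +
      matrix(rep(c(-4, 9, 1), each = 5), 5)
  }
  tr2 <- trajectory(moved)
  expect_equal(rmsd_series(tr2, 1:5, 1:5, reference = 1)$value,
               rmsd_series(tr, 1:5, 1:5, reference = 1)$value,
               tolerance = 1e-9)
  expect_equal(rmsf_profile(tr2, 1:5)$rmsf, rmsf_profile(tr, 1:5)$rmsf,
               tolerance = 1e-9)
})
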
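test_that("static and rigid-motion trajectories give zero covariance", {
  base <- random_structure(8, seed = 2)
  static <- trajectory(array(rep(base, each = 6), c(6, 8, 3)))
  cv <- fit_and_covariance(static, 1:8)
  expect_lt(max(abs(cv$matrix)), 1e-20)
  rigid <- rigid_motion_traj(base, 12)
  cv2 <- fit_and_covariance(rigid, 1:8)
  expect_lt(max(abs(cv2$matrix)), 1e-20)
})

test_that("two frames of a single particle give the hand-computed variance", {
  coords <- array(0, c(2, 1, 3))
  coords[1, 1, 1] <- 1; coords[2, 1, 1] <- -1
  cv <- fit_and_covariance(trajectory(coords), 1)  # 1 particle: no fitting
  expect_equal(cv$matrix[1, 1], 1)
  expect_equal(cv$matrix[2, 2], 0)
  expect_equal(cv$matrix[3, 3], 0)
})

test_that("degenerate fit selections are rejected by name", {
  coords <- array(rep(cbind(1:4, 0, 0), each = 3), c(3, 4, 3))
  coords[, , 2] <- 0; coords[, , 3] <- 0
  for (i in 1:3) coords[i, , 1] <- 1:4  # collinear atoms on x
  expect_error(
    fit_and_covariance(trajectory(coords), 1:4, selection_name = "lineA"),
    "lineA")
})

test_that("zero covariance gives zero entropy and masses shift it as the closed form says", {
  z <- schlitter_entropy(matrix(0, 3, 3), masses = 12)
  expect_equal(z$S_config, 0)
  # doubling the mass in the 1-particle closed form
  sigma2 <- 0.3
  kB <- 1.380649e-23; hbar <- 1.054571817e-34
  u <- 1.66053906660e-27; Rgas <- 8.314462618
  a <- kB * 300 * exp(2) / hbar^2 * u * sigma2 * 1e-20
  s1 <- schlitter_entropy(diag(sigma2, 3), masses = 12)$S_config
  s2 <- schlitter_entropy(diag(sigma2, 3), masses = 24)$S_config
  expect_equal(s1, 3 * (Rgas / 2) * log1p(12 * a), tolerance = 1e-12)
  expect_equal(s2, 3 * (Rgas / 2) * log1p(24 * a), tolerance = 1e-12)
})

test_that("sampled Gaussian entropy matches the closed form within 2%", {
  g <- gaussian_trajectory(masses = c(12, 16, 14),
                           covariance = diag(c(rep(0.2, 3), rep(0.5, 3),
                                               rep(0.35, 3))),
                           n_frames = 50000, seed = 23)
  S <- schlitter_entropy(fit_and_covariance(g$trajectory, 1:3, fit = "none"),
                         g$masses)$S_config
  expect_equal(S, g$analytic_entropy, tolerance = 0.02)
})

test_that("entropy is invariant under global rigid motion and atom reordering", {
  set.seed(41)
  N <- 4
  C <- crossprod(matrix(rnorm(144, sd = 0.15), 12)) + diag(0.05, 12)
  g <- gaussian_trajectory(rep(12, N), C, n_frames = 4000, seed = 8)
  S0 <- schlitter_entropy(fit_and_covariance(g$trajectory, 1:N, fit = "kabsch"),
                          g$masses)$S_config
  # rotate + translate every frame identically
  th <- 0.7
  Rz <- matrix(c(cos(th), -sin(th), 0, sin(th), cos(th), 0, 0, 0, 1), 3, 3,
               byrow = TRUE)
  moved <- g$trajectory$coords
  for (i in seq_len(4000)) {
    moved[i, , ] <- g$trajectory$coords[i, , ] %*% t(Rz) +
      matrix(rep(c(5, -3, 2), each = N), N)
  }
  S1 <- schlitter_entropy(
    fit_and_covariance(trajectory(moved), 1:N, fit = "kabsch"),
    g$masses)$S_config
  expect_equal(S1, S0, tolerance = 1e-9)
  # reorder atoms (permute selection and masses together)
  perm <- c(3, 1, 4, 2)
  S2 <- schlitter_entropy(
    fit_and_covariance(trajectory(g$trajectory$coords[, perm, ,
                                                      drop = FALSE]),
                       1:N, fit = "kabsch"),
    g$masses[perm])$S_config
  expect_equal(S2, S0, tolerance = 1e-9)
})

test_that("entropy is monotone in any covariance eigenvalue", {
  C <- diag(c(0.1, 0.2, 0.3))
  s <- vapply(c(0.3, 0.6, 1.2), function(v) {
    C2 <- C; C2[3, 3] <- v
    schlitter_entropy(C2, masses = 12)$S_config
  }, numeric(1))
  expect_true(all(diff(s) > 0))
})

test_that("negative eigenvalues beyond tolerance are rejected", {
  C <- diag(c(-0.5, 0.2, 0.2))
  expect_error(schlitter_entropy(C, masses = 12), "negative eigenvalue")
})

test_that("per-domain decomposition is deterministic and additive for independent domains", {
  # two independent 2-particle domains
  C <- diag(c(rep(0.2, 6), rep(0.4, 6)))
  g <- gaussian_trajectory(rep(12, 4), C, n_frames = 8000, seed = 19)
  dm <- domain_map(
    d1 = data.frame(chain_id = "A", from = 1, to = 2),
    d2 = data.frame(chain_id = "A", from = 3, to = 4),
    d1_again = data.frame(chain_id = "A", from = 1, to = 2))
  res <- entropy_by_domain(g$trajectory, g$topology, dm, fit = "none",
                           uncertainty = FALSE)
  expect_setequal(res$selection, c("d1", "d2", "d1_again", "whole"))
  expect_equal(res$S_config[res$selection == "d1"],
               res$S_config[res$selection == "d1_again"])
  s_whole <- res$S_config[res$selection == "whole"]
  s_sum <- res$S_config[res$selection == "d1"] +
    res$S_config[res$selection == "d2"]
  expect_equal(s_whole, s_sum, tolerance = 0.02)
})

test_that("a covariance change confined to one domain localizes there", {
  dm <- domain_map(
    d1 = data.frame(chain_id = "A", from = 1, to = 2),
    d2 = data.frame(chain_id = "A", from = 3, to = 4))
  pp <- pd_pl_pair(rep(12, 4), diag(0.2, 12), scale = 2, subset = 3:4,
                   n_frames = 20000, seed = 29)
  epd <- entropy_by_domain(pp$pd$trajectory, pp$pd$topology, dm,
                           fit = "none", uncertainty = FALSE)
  epl <- entropy_by_domain(pp$pl$trajectory, pp$pl$topology, dm,
                           fit = "none", uncertainty = FALSE)
  dS <- epl$S_config - epd$S_config
  names(dS) <- epd$selection
  expect_gt(dS[["d2"]] / pp$analytic_delta_S, 0.9)
  expect_lt(abs(dS[["d1"]]) / pp$analytic_delta_S, 0.1)
})

test_that("cumulative-sampling uncertainty behaves as a convergence measure", {
  # identical frames -> 0
  base <- random_structure(3, seed = 4)
  static <- trajectory(array(rep(base, each = 12), c(12, 3, 3)))
  expect_equal(
    entropy_uncertainty(static, 1:3, masses = rep(12, 3), fit = "none"), 0)
  # converged iid Gaussian -> small relative to S
  g <- gaussian_trajectory(rep(12, 2), diag(0.3, 6), n_frames = 30000,
                           seed = 37)
  S <- schlitter_entropy(fit_and_covariance(g$trajectory, 1:2, fit = "none"),
                         g$masses)$S_config
  unc <- entropy_uncertainty(g$trajectory, 1:2, g$masses, fit = "none")
  expect_gte(unc, 0)
  expect_lt(unc / S, 0.01)
})

test_that("solvent entropy is linear and refuses to guess coefficients", {
  co <- solvent_entropy_coefficients(a_polar = -0.5, a_apolar = 1.2)
  expect_equal(solvent_entropy(0, 0, co), 0)
  x <- solvent_entropy(-120, -340, co)
  expect_equal(solvent_entropy(-240, -680, co), 2 * x)
  expect_error(solvent_entropy(-10, -10), "coefficients")
  def <- default_solvent_entropy_coefficients()
  expect_true(is.finite(def$a_polar) && is.finite(def$a_apolar))
})

test_that("configurational and solvent entropy changes combine additively", {
  expect_equal(total_entropy(-10, 564), 554)
  expect_equal(total_entropy(0, 0), 0)
})
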
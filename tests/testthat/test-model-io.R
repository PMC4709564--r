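test_that("structure write-then-read round trip preserves atoms and coords", {
  g <- gaussian_trajectory(masses = rep(12, 10), covariance = diag(0.1, 30),
                           n_frames = 2, seed = 2)
  f <- withr::local_tempfile(fileext = ".pdb")
  write_structure(g$topology, frame_coords(g$trajectory, 1), f)
  rt <- read_structure(f)
  expect_equal(n_atoms(rt$topology), 10)
  expect_identical(rt$topology$atoms$residue_index,
                   g$topology$atoms$residue_index)
  expect_identical(rt$topology$atoms$chain_id, g$topology$atoms$chain_id)
  # PDB stores 3 decimals
  expect_lt(max(abs(frame_coords(rt$trajectory, 1) -
                      frame_coords(g$trajectory, 1))), 1e-3)
})

test_that("a minimal PDB with one CA atom parses to a 1-atom carbon topology", {
  f <- withr::local_tempfile(fileext = ".pdb")
  writeLines(c(
    "ATOM      1  CA  GLY A   1       0.000   0.000   0.000  1.00  0.00           C",
    "END"), f)
  st <- read_structure(f)
  expect_equal(n_atoms(st$topology), 1)
  expect_equal(st$topology$atoms$element, "C")
  expect_equal(frame_coords(st$trajectory, 1), rbind(c(x = 0, y = 0, z = 0)),
               ignore_attr = TRUE)
})

test_that("altloc records keep the highest-occupancy location", {
  f <- withr::local_tempfile(fileext = ".pdb")
  writeLines(c(
    "ATOM      1  CA AGLY A   1       1.000   0.000   0.000  0.40  0.00           C",
    "ATOM      2  CA BGLY A   1       2.000   0.000   0.000  0.60  0.00           C",
    "END"), f)
  st <- read_structure(f)
  expect_equal(n_atoms(st$topology), 1)
  expect_equal(frame_coords(st$trajectory, 1)[1, 1], 2, ignore_attr = TRUE)
})

test_that("elements missing from the PDB are inferred with a warning", {
  f <- withr::local_tempfile(fileext = ".pdb")
  writeLines(c(
    "ATOM      1  CA  GLY A   1       0.000   0.000   0.000  1.00  0.00",
    "ATOM      2  N   GLY A   1       1.400   0.000   0.000  1.00  0.00",
    "END"), f)
  expect_warning(st <- read_structure(f), "inferred")
  expect_equal(st$topology$atoms$element, c("C", "N"))
})

test_that("DCD round trip is exact in times and float precision in coords", {
  g <- gaussian_trajectory(masses = rep(12, 7), covariance = diag(0.3, 21),
                           n_frames = 100, seed = 7, dt = 20)
  f <- withr::local_tempfile(fileext = ".dcd")
  write_trajectory(g$trajectory, f)
  rt <- read_trajectory(f, g$topology)
  expect_identical(rt$times, g$trajectory$times)
  expect_lt(max(abs(rt$coords - g$trajectory$coords)),
            1e-5 * max(abs(g$trajectory$coords)))
})

test_that("the package DCD reader agrees with the bio3d reader", {
  g <- gaussian_trajectory(masses = rep(12, 5), covariance = diag(0.2, 15),
                           n_frames = 8, seed = 3)
  f <- withr::local_tempfile(fileext = ".dcd")
  write_dcd(g$trajectory, f)
  mine <- read_dcd(f)
  ref <- bio3d::read.dcd(f, verbose = FALSE)
  for (i in c(1, 5, 8)) {
    expect_equal(matrix(ref[i, ], ncol = 3, byrow = TRUE), mine$coords[i, , ],
                 ignore_attr = TRUE)
  }
})

test_that("single-frame PDB read back as trajectory equals the structure", {
  g <- gaussian_trajectory(masses = rep(12, 4), covariance = diag(0.1, 12),
                           n_frames = 2, seed = 5)
  f <- withr::local_tempfile(fileext = ".pdb")
  write_structure(g$topology, frame_coords(g$trajectory, 1), f)
  tr <- read_trajectory(f, g$topology)
  expect_equal(n_frames(tr), 1)
  expect_lt(max(abs(frame_coords(tr, 1) - frame_coords(g$trajectory, 1))),
            1e-3)
})

test_that("atom-count mismatch between trajectory and topology errors", {
  g <- gaussian_trajectory(masses = rep(12, 4), covariance = diag(0.1, 12),
                           n_frames = 3, seed = 5)
  f <- withr::local_tempfile(fileext = ".dcd")
  write_dcd(g$trajectory, f)
  small <- gaussian_trajectory(masses = rep(12, 3),
                               covariance = diag(0.1, 9),
                               n_frames = 2, seed = 1)$topology
  expect_error(read_trajectory(f, small), "mismatch")
})

test_that("corrupt DCD frames are reported with a frame index", {
  g <- gaussian_trajectory(masses = rep(12, 4), covariance = diag(0.1, 12),
                           n_frames = 5, seed = 5)
  f <- withr::local_tempfile(fileext = ".dcd")
  write_dcd(g$trajectory, f)
  sz <- file.size(f)
  con <- file(f, "r+b")
  seek(con, sz - 30, rw = "write")
  writeBin(raw(30), con)  # clobber the tail of the last frame
  close(con)
  expect_error(read_dcd(f), "frame")
})

test_that("sidecar parameter files round trip", {
  bc <- bead_complex(pos1 = rbind(c(0, 0, 0), c(3, 0, 0)),
                     pos2 = c(0, 0, 6),
                     charge1 = c(0.25, -0.5), charge2 = 1,
                     sigma1 = 0.31, sigma2 = 0.29,
                     epsilon1 = 0.42, epsilon2 = 0.66)
  f <- withr::local_tempfile(fileext = ".tsv")
  write_parameters(bc$topology, f)
  bare <- bc$topology
  bare$charge <- bare$lj_sigma <- bare$lj_epsilon <- NULL
  back <- read_parameters(bare, f)
  expect_equal(back$charge, bc$topology$charge)
  expect_equal(back$lj_sigma, bc$topology$lj_sigma)
  expect_equal(back$lj_epsilon, bc$topology$lj_epsilon)
  expect_equal(back$mass, bc$topology$mass)
})

test_that("selection resolution honours filters, ranges, and set algebra", {
  top <- toy_peptide_topology()
  dm <- domain_map(
    all3 = data.frame(chain_id = "A", from = 1, to = 3),
    first = data.frame(chain_id = "A", from = 1, to = 1),
    rest = data.frame(chain_id = "A", from = 2, to = 3),
    split = data.frame(chain_id = c("A", "A"), from = c(1, 3), to = c(1, 3))
  )
  ca <- resolve_selection(dm, "all3", top, "CA")
  expect_length(ca, 3)                     # exactly one CA per residue
  expect_equal(top$atoms$name[ca], rep("CA", 3))
  expect_equal(resolve_selection(dm, "all3", top, "all"), 1:9)
  # union of disjoint ranges adds up
  expect_length(resolve_selection(dm, "split", top), 6)
  expect_equal(
    length(resolve_selection(dm, "first", top)) +
      length(resolve_selection(dm, "rest", top)),
    length(resolve_selection(dm, "all3", top)))
  # idempotent + sorted
  idx <- resolve_selection(dm, "rest", top)
  expect_identical(idx, sort(idx))
  expect_identical(resolve_selection(dm, "rest", top), idx)
  expect_error(resolve_selection(dm, "nope", top), "not in map")
})

test_that("a two-domain partition resolves to complementary selections", {
  n_res <- 381
  top <- topology(tibble::tibble(
    serial = seq_len(n_res), name = "CA", element = "C",
    residue_index = seq_len(n_res), residue_name = "GLY", chain_id = "D"))
  dm <- domain_map(
    TN = data.frame(chain_id = "D", from = 1, to = 269),
    TC = data.frame(chain_id = "D", from = 270, to = 381))
  tn <- resolve_selection(dm, "TN", top)
  tc <- resolve_selection(dm, "TC", top)
  expect_length(intersect(tn, tc), 0)
  expect_identical(sort(c(tn, tc)), seq_len(n_res))
})

test_that("empty selections error rather than silently no-op", {
  top <- toy_peptide_topology()
  dm <- domain_map(ghost = data.frame(chain_id = "Z", from = 1, to = 99))
  expect_error(resolve_selection(dm, "ghost", top), "zero atoms")
})

test_that("domain maps round trip through YAML", {
  dm <- default_domain_map()
  f <- withr::local_tempfile(fileext = ".yaml")
  write_domain_map(dm, f)
  back <- read_domain_map(f)
  expect_identical(names(back), names(dm))
  for (nm in names(dm)) expect_equal(back[[nm]], dm[[nm]])
})

test_that("the shipped default domain map file loads", {
  f <- system.file("extdata", "mhc_tapasin_domains.yaml",
                   package = "tidytraj")
  dm <- read_domain_map(f)
  expect_setequal(names(dm),
                  c("alpha1", "alpha2", "alpha3", "b2m", "Ag", "TN", "TC"))
  expect_equal(dm$TC$from, 270)
})
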
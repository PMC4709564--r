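#' Build a trajectory
#'
#' The substrate of every analysis: an ordered set of frames of Cartesian
#' coordinates (Angstrom) with per-frame times (ps, strictly increasing).
#'
#' @param coords Numeric array `n_frames x n_atoms x 3`, Angstrom. A single
#'   `n_atoms x 3` matrix is promoted to one frame.
#' @param times Per-frame times in ps, strictly increasing. Defaults to
#'   `0, 1, ..., n_frames - 1`.
#'
#' @return An object of class `traj_frames` with elements `coords` and `times`.
#' @export
trajectory <- function(coords, times = NULL) {
  if (is.matrix(coords)) {
    coords <- array(coords, dim = c(1, dim(coords)))
  }
  if (length(dim(coords)) != 3 || dim(coords)[3] != 3) {
    stop("coords must be an n_frames x n_atoms x 3 array")
  }
  n <- dim(coords)[1]
  if (is.null(times)) times <- as.numeric(seq_len(n) - 1)
  if (length(times) != n) stop("times must have one entry per frame")
  if (n > 1 && any(diff(times) <= 0)) stop("times must be strictly increasing")
  if (any(!is.finite(coords))) stop("coordinates must be finite")
  structure(list(coords = coords, times = as.numeric(times)),
            class = "traj_frames")
}

#' @export
print.traj_frames <- function(x, ...) {
  d <- dim(x$coords)
  cat("<traj_frames> ", d[1], " frame(s) x ", d[2], " atoms; t = ",
      format(x$times[1]), " .. ", format(x$times[d[1]]), " ps\n", sep = "")
  invisible(x)
}

#' @rdname trajectory
#' @param x A `traj_frames` object.
#' @export
n_frames <- function(x) dim(x$coords)[1]

#' Extract one frame as an n_atoms x 3 matrix
#'
#' @param traj A [trajectory()].
#' @param i Frame index.
#' @return Numeric matrix, Angstrom.
#' @export
frame_coords <- function(traj, i) {
  if (i < 1 || i > n_frames(traj)) stop("frame index out of range: ", i)
  matrix(traj$coords[i, , ], ncol = 3,
         dimnames = list(NULL, c("x", "y", "z")))
}

#' Subset a trajectory by frame index
#'
#' @param traj A [trajectory()].
#' @param idx Frame indices to keep (increasing).
#' @return A [trajectory()] with the selected frames.
#' @export
subset_frames <- function(traj, idx) {
  trajectory(traj$coords[idx, , , drop = FALSE], traj$times[idx])
}

#' Read a trajectory file
#'
#' Dispatches on extension: `.dcd` (CHARMM/NAMD binary DCD) or `.pdb`
#' (multi-MODEL text PDB). Coordinates are returned in Angstrom; DCD times are
#' reconstructed from the header's start/stride/timestep fields, which this
#' package writes in ps.
#'
#' @param path Trajectory file.
#' @param topology The matching [topology()]; the frame atom count must equal
#'   its atom count.
#' @return A [trajectory()].
#' @export
read_trajectory <- function(path, topology) {
  ext <- tolower(tools::file_ext(path))
  traj <- switch(ext,
    dcd = read_dcd(path),
    pdb = read_pdb_frames(path),
    stop("unsupported trajectory container: .", ext,
         " (use .dcd or multi-model .pdb)")
  )
  if (dim(traj$coords)[2] != n_atoms(topology)) {
    stop("atom-count mismatch: trajectory has ", dim(traj$coords)[2],
         " atoms, topology has ", n_atoms(topology))
  }
  traj
}

#' Write a trajectory file
#'
#' @param traj A [trajectory()].
#' @param path Output file; format from extension (`.dcd` or `.pdb`).
#' @param topology Required for `.pdb` output (atom records).
#' @return `path`, invisibly.
#' @export
write_trajectory <- function(traj, path, topology = NULL) {
  ext <- tolower(tools::file_ext(path))
  switch(ext,
    dcd = write_dcd(traj, path),
    pdb = {
      if (is.null(topology)) stop("writing PDB frames needs a topology")
      write_pdb_frames(traj, topology, path)
    },
    stop("unsupported trajectory container: .", ext)
  )
  invisible(path)
}

# ---- DCD (CHARMM-format Fortran unformatted records) -----------------------

.dcd_record <- function(con, payload_writer, nbytes) {
  writeBin(as.integer(nbytes), con, size = 4, endian = "little")
  payload_writer()
  writeBin(as.integer(nbytes), con, size = 4, endian = "little")
}

#' @rdname write_trajectory
#' @export
write_dcd <- function(traj, path) {
  n <- n_frames(traj)
  na <- dim(traj$coords)[2]
  dt <- if (n > 1) diff(traj$times) else 1
  if (n > 1 && diff(range(dt)) > 1e-6 * mean(dt)) {
    stop("DCD stores a single timestep; times must be uniformly spaced ",
         "(write multi-model PDB for irregular times)")
  }
  delta <- if (n > 1) mean(dt) else 1
  istart <- as.integer(round(traj$times[1] / delta))
  con <- file(path, "wb")
  on.exit(close(con))
  # header record: 'CORD' + 20 int32 slots (CHARMM layout, version 24)
  icntrl <- integer(20)
  icntrl[1] <- n        # NSET
  icntrl[2] <- istart   # ISTART (in steps of DELTA)
  icntrl[3] <- 1L       # NSAVC
  icntrl[20] <- 24L     # CHARMM version flag
  .dcd_record(con, function() {
    writeChar("CORD", con, 4, eos = NULL)
    writeBin(icntrl[1:9], con, size = 4, endian = "little")
    writeBin(as.numeric(delta), con, size = 4, endian = "little") # DELTA, ps
    writeBin(icntrl[11:20], con, size = 4, endian = "little")
  }, 84)
  title <- formatC("written by tidytraj; times in ps", width = -80)
  .dcd_record(con, function() {
    writeBin(1L, con, size = 4, endian = "little")
    writeChar(title, con, 80, eos = NULL)
  }, 84)
  .dcd_record(con, function() {
    writeBin(as.integer(na), con, size = 4, endian = "little")
  }, 4)
  for (i in seq_len(n)) {
    for (ax in 1:3) {
      .dcd_record(con, function() {
        writeBin(as.numeric(traj$coords[i, , ax]), con, size = 4,
                 endian = "little")
      }, 4 * na)
    }
  }
  invisible(path)
}

#' @rdname read_trajectory
#' @export
read_dcd <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  expect_marker <- function(nbytes, what) {
    m <- readBin(con, "integer", 1, size = 4, endian = "little")
    if (length(m) != 1 || m != nbytes) {
      stop("corrupt DCD (", what, "): record marker ", m, " != ", nbytes)
    }
  }
  expect_marker(84, "header")
  magic <- readChar(con, 4)
  if (!identical(magic, "CORD")) stop("not a DCD coordinate file: ", path)
  icntrl <- readBin(con, "integer", 9, size = 4, endian = "little")
  delta <- readBin(con, "numeric", 1, size = 4, endian = "little")
  icntrl2 <- readBin(con, "integer", 10, size = 4, endian = "little")
  expect_marker(84, "header")
  nset <- icntrl[1]; istart <- icntrl[2]; nsavc <- icntrl[3]
  has_cell <- icntrl2[1] != 0  # CHARMM unit-cell flag (icntrl[11])
  tlen <- readBin(con, "integer", 1, size = 4, endian = "little")
  ntitle <- readBin(con, "integer", 1, size = 4, endian = "little")
  readChar(con, 80 * ntitle)
  expect_marker(tlen, "title")
  expect_marker(4, "natom")
  na <- readBin(con, "integer", 1, size = 4, endian = "little")
  expect_marker(4, "natom")
  coords <- array(NA_real_, dim = c(nset, na, 3))
  for (i in seq_len(nset)) {
    if (has_cell) {
      expect_marker(48, paste0("cell, frame ", i))
      readBin(con, "numeric", 6, size = 8, endian = "little")
      expect_marker(48, paste0("cell, frame ", i))
    }
    for (ax in 1:3) {
      expect_marker(4 * na, paste0("frame ", i))
      v <- readBin(con, "numeric", na, size = 4, endian = "little")
      if (length(v) != na) stop("corrupt DCD: truncated frame ", i)
      coords[i, , ax] <- v
      expect_marker(4 * na, paste0("frame ", i))
    }
  }
  times <- (istart + (seq_len(nset) - 1) * nsavc) * delta
  trajectory(coords, times)
}
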
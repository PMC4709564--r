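#' Read a protein structure from PDB
#'
#' Parses a PDB file (through bio3d) into the package's data model. Alternate
#' locations are collapsed by keeping the highest-occupancy altloc per atom
#' (ties broken by altloc identifier). Chains and author residue numbering are
#' preserved exactly as printed. Elements missing from columns 77-78 are
#' inferred from the atom name with a warning.
#'
#' @param path PDB file.
#' @return A list with `topology` (a [topology()] without nonbonded
#'   parameters) and `trajectory` (a single-frame [trajectory()]), so the pair
#'   plugs straight into the analysis functions.
#' @export
read_structure <- function(path) {
  pdb <- bio3d::read.pdb(path, rm.alt = FALSE, verbose = FALSE)
  at <- pdb$atom[pdb$atom$type %in% c("ATOM", "HETATM"), , drop = FALSE]
  if (nrow(at) == 0) stop("no coordinate (ATOM/HETATM) records in ", path)
  if (any(is.na(at$x) | is.na(at$y) | is.na(at$z))) {
    bad <- which(is.na(at$x) | is.na(at$y) | is.na(at$z))[1]
    stop("missing coordinates at atom record ", bad, " (serial ",
         at$eleno[bad], ") in ", path)
  }
  # altloc: keep the highest-occupancy location of each (chain, resno, name)
  alt <- at$alt
  alt[is.na(alt)] <- ""
  if (any(nzchar(alt))) {
    occ <- at$o
    occ[is.na(occ)] <- 1
    key <- paste(at$chain, at$resno, at$insert, at$elety, sep = "\r")
    keep <- unlist(lapply(split(seq_len(nrow(at)), key), function(idx) {
      if (length(idx) == 1) return(idx)
      idx[order(-occ[idx], alt[idx])][1]
    }), use.names = FALSE)
    at <- at[sort(keep), , drop = FALSE]
  }
  elem <- at$elesy
  missing_elem <- is.na(elem) | !nzchar(trimws(elem))
  if (any(missing_elem)) {
    warning(sum(missing_elem), " atom(s) lack an element column; ",
            "inferred from atom names")
    elem[missing_elem] <- infer_element(at$elety[missing_elem])
  }
  chain <- at$chain
  chain[is.na(chain)] <- "A"
  atoms <- tibble::tibble(
    serial = as.integer(at$eleno),
    name = trimws(at$elety),
    element = toupper(trimws(elem)),
    residue_index = as.integer(at$resno),
    residue_name = trimws(at$resid),
    chain_id = chain
  )
  top <- topology(atoms)
  coords <- cbind(at$x, at$y, at$z)
  list(topology = top, trajectory = trajectory(coords, times = 0))
}

# Element from a PDB atom name: strip digits/primes, handle the common
# two-letter cases; single-frame heuristics good enough for protein atoms.
infer_element <- function(name) {
  nm <- toupper(gsub("[0-9'\"]", "", trimws(name)))
  vapply(nm, function(x) {
    if (x %in% c("CL", "BR", "FE", "ZN", "MG", "NA", "SE", "MN", "CU")) return(x)
    if (nchar(x) >= 1) substr(x, 1, 1) else "C"
  }, character(1), USE.NAMES = FALSE)
}

#' Write a structure or multi-frame trajectory as PDB
#'
#' @param topology A [topology()].
#' @param coords An `n_atoms x 3` matrix (Angstrom) for `write_structure()`.
#' @param path Output file.
#' @return `path`, invisibly.
#' @export
write_structure <- function(topology, coords, path) {
  a <- topology$atoms
  bio3d::write.pdb(
    file = path,
    xyz = as.numeric(t(coords)),
    resno = a$residue_index, resid = a$residue_name,
    eleno = a$serial, elety = a$name, chain = a$chain_id,
    elesy = a$element
  )
  invisible(path)
}

#' @rdname write_structure
#' @param traj A [trajectory()]; written as one MODEL per frame with the time
#'   (ps) recorded on each MODEL's REMARK line.
#' @export
write_pdb_frames <- function(traj, topology, path) {
  con <- file(path, "wt")
  on.exit(close(con))
  tmp <- tempfile(fileext = ".pdb")
  on.exit(unlink(tmp), add = TRUE)
  for (i in seq_len(n_frames(traj))) {
    writeLines(sprintf("MODEL     %4d", i), con)
    writeLines(sprintf("REMARK 250 TIME_PS %.6f", traj$times[i]), con)
    write_structure(topology, frame_coords(traj, i), tmp)
    lines <- readLines(tmp)
    writeLines(grep("^(ATOM|HETATM|TER)", lines, value = TRUE), con)
    writeLines("ENDMDL", con)
  }
  writeLines("END", con)
  invisible(path)
}

#' @rdname read_trajectory
#' @export
read_pdb_frames <- function(path) {
  lines <- readLines(path)
  model_starts <- grep("^MODEL", lines)
  if (length(model_starts) == 0) model_starts <- 1L
  pdb <- bio3d::read.pdb(path, multi = TRUE, verbose = FALSE)
  xyz <- pdb$xyz
  nf <- nrow(xyz)
  coords <- array(NA_real_, dim = c(nf, ncol(xyz) / 3, 3))
  for (i in seq_len(nf)) {
    coords[i, , ] <- matrix(xyz[i, ], ncol = 3, byrow = TRUE)
  }
  tm <- grep("^REMARK 250 TIME_PS", lines, value = TRUE)
  times <- if (length(tm) == nf) {
    as.numeric(sub("^REMARK 250 TIME_PS +", "", tm))
  } else {
    as.numeric(seq_len(nf) - 1)
  }
  trajectory(coords, times)
}
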
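#' Build a topology
#'
#' A topology couples an ordered atom table with the per-atom parameters the
#' analyses need: masses (for mass-weighted covariances), partial charges and
#' Lennard-Jones parameters (for pairwise force recomputation). Atom order is
#' significant and shared with every [trajectory()] analysed against it.
#'
#' @param atoms Data frame with one row per atom and columns `serial`
#'   (integer), `name` (atom name, e.g. `"CA"`), `element` (symbol),
#'   `residue_index` (integer, author/PDB numbering, 1-based per chain),
#'   `residue_name` (3-letter code), `chain_id` (string).
#' @param mass Per-atom masses, u. Defaults to standard atomic masses looked
#'   up by element.
#' @param charge Per-atom partial charges, elementary charges, or `NULL` when
#'   no force analysis is intended.
#' @param lj_sigma,lj_epsilon Per-atom Lennard-Jones parameters (sigma in nm,
#'   epsilon in kJ/mol), or `NULL`.
#'
#' @return An object of class `traj_topology`: a list with the validated
#'   `atoms` tibble and numeric parameter vectors.
#' @export
#' @examples
#' top <- topology(tibble::tibble(
#'   serial = 1L, name = "CA", element = "C", residue_index = 1L,
#'   residue_name = "ALA", chain_id = "A"))
#' n_atoms(top)
topology <- function(atoms, mass = NULL, charge = NULL,
                     lj_sigma = NULL, lj_epsilon = NULL) {
  atoms <- tibble::as_tibble(atoms)
  required <- c("serial", "name", "element", "residue_index",
                "residue_name", "chain_id")
  missing_cols <- setdiff(required, names(atoms))
  if (length(missing_cols) > 0) {
    stop("atoms table lacks column(s): ", paste(missing_cols, collapse = ", "))
  }
  if (nrow(atoms) == 0) stop("topology needs at least one atom")
  if (any(is.na(atoms$element) | !nzchar(atoms$element))) {
    stop("every atom needs a non-empty element symbol")
  }
  atoms$serial <- as.integer(atoms$serial)
  atoms$residue_index <- as.integer(atoms$residue_index)
  atoms$element <- toupper(atoms$element)

  n <- nrow(atoms)
  if (is.null(mass)) mass <- element_masses(atoms$element)
  check_len <- function(x, what) {
    if (!is.null(x) && length(x) != n) {
      stop(what, " must have one value per atom (", n, "), got ", length(x))
    }
    if (!is.null(x)) as.numeric(x) else NULL
  }
  mass <- check_len(mass, "mass")
  charge <- check_len(charge, "charge")
  lj_sigma <- check_len(lj_sigma, "lj_sigma")
  lj_epsilon <- check_len(lj_epsilon, "lj_epsilon")
  if (any(!is.finite(mass)) || any(mass <= 0)) stop("masses must be finite and > 0")
  if (!is.null(lj_sigma) && any(lj_sigma < 0)) stop("lj_sigma must be >= 0")
  if (!is.null(lj_epsilon) && any(lj_epsilon < 0)) stop("lj_epsilon must be >= 0")

  structure(
    list(atoms = atoms, mass = mass, charge = charge,
         lj_sigma = lj_sigma, lj_epsilon = lj_epsilon),
    class = "traj_topology"
  )
}

#' Standard atomic mass lookup
#'
#' @param element Character vector of element symbols.
#' @return Masses in u; unknown elements fall back to carbon with a warning.
#' @export
element_masses <- function(element) {
  element <- toupper(element)
  m <- .element_masses[element]
  unknown <- is.na(m)
  if (any(unknown)) {
    warning("unknown element(s) ", paste(unique(element[unknown]), collapse = ", "),
            "; using carbon mass")
    m[unknown] <- .element_masses[["X"]]
  }
  unname(m)
}

#' @export
print.traj_topology <- function(x, ...) {
  cat("<traj_topology> ", nrow(x$atoms), " atoms, ",
      dplyr::n_distinct(paste(x$atoms$chain_id, x$atoms$residue_index)),
      " residues, ", dplyr::n_distinct(x$atoms$chain_id), " chain(s)\n", sep = "")
  cat("  parameters:",
      if (is.null(x$charge)) "masses only" else "masses, charges, LJ", "\n")
  invisible(x)
}

#' @rdname topology
#' @param x Object to query.
#' @export
n_atoms <- function(x) UseMethod("n_atoms")

#' @export
n_atoms.traj_topology <- function(x) nrow(x$atoms)

#' @export
n_atoms.traj_frames <- function(x) dim(x$coords)[2]

#' Read or write a sidecar nonbonded-parameter table
#'
#' Analyses that recompute forces need per-atom charges and Lennard-Jones
#' parameters. These are carried in a plain whitespace-separated text table
#' ("sidecar" to the structure file) with header
#' `serial mass charge lj_sigma lj_epsilon` — masses in u, charges in e,
#' sigma in nm, epsilon in kJ/mol — so the analysis is decoupled from any one
#' MD engine's topology format.
#'
#' @param topology A [topology()].
#' @param path File path.
#' @return `read_parameters()` returns the topology with parameters attached;
#'   `write_parameters()` returns `path` invisibly.
#' @export
read_parameters <- function(topology, path) {
  tab <- utils::read.table(path, header = TRUE)
  need <- c("serial", "mass", "charge", "lj_sigma", "lj_epsilon")
  if (!all(need %in% names(tab))) {
    stop("parameter file must have columns: ", paste(need, collapse = ", "))
  }
  idx <- match(topology$atoms$serial, tab$serial)
  if (any(is.na(idx))) {
    stop("parameter file lacks entries for atom serial(s): ",
         paste(utils::head(topology$atoms$serial[is.na(idx)], 5), collapse = ", "))
  }
  topology$mass <- as.numeric(tab$mass[idx])
  topology$charge <- as.numeric(tab$charge[idx])
  topology$lj_sigma <- as.numeric(tab$lj_sigma[idx])
  topology$lj_epsilon <- as.numeric(tab$lj_epsilon[idx])
  if (any(topology$mass <= 0)) stop("parameter file contains non-positive masses")
  topology
}

#' @rdname read_parameters
#' @export
write_parameters <- function(topology, path) {
  if (is.null(topology$charge) || is.null(topology$lj_sigma) ||
      is.null(topology$lj_epsilon)) {
    stop("topology carries no charges/LJ parameters to write")
  }
  tab <- data.frame(
    serial = topology$atoms$serial,
    mass = topology$mass,
    charge = topology$charge,
    lj_sigma = topology$lj_sigma,
    lj_epsilon = topology$lj_epsilon
  )
  utils::write.table(format(tab, digits = 17, scientific = FALSE, trim = TRUE),
                     path, quote = FALSE, row.names = FALSE)
  invisible(path)
}
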
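# Least-squares rigid-body superposition (Kabsch). Shared by the covariance,
# RMSD and RMSF machinery.

# Optimal proper rotation R and translation mapping moving (n x 3) onto
# ref (n x 3) in the least-squares sense. Returns the transformed FULL
# coordinate set `apply_to` (defaults to `moving`).
kabsch_superpose <- function(moving, ref, apply_to = moving) {
  if (nrow(moving) != nrow(ref)) stop("fit selections differ in atom count")
  if (nrow(moving) == 1) {
    # a single atom defines translation only
    shift <- ref[1, ] - moving[1, ]
    return(sweep(apply_to, 2, -shift, "-"))
  }
  cm <- colMeans(moving)
  cr <- colMeans(ref)
  P <- sweep(moving, 2, cm)
  Q <- sweep(ref, 2, cr)
  H <- crossprod(P, Q)  # 3 x 3
  sv <- svd(H)
  d <- sign(det(tcrossprod(sv$v, sv$u)))
  R <- sv$v %*% diag(c(1, 1, d)) %*% t(sv$u)
  # row-vector convention: x_new = (x - cm) %*% t(R) + cr
  sweep(sweep(apply_to, 2, cm) %*% t(R), 2, -cr, "-")
}

# Degenerate fit selections (all atoms coincident or collinear) make the
# rotation ill-defined; detect via the rank of the centred coordinates.
check_fit_selection <- function(coords, label = "fit selection") {
  if (nrow(coords) < 3) return(invisible(TRUE))  # handled by caller policy
  s <- svd(sweep(coords, 2, colMeans(coords)))$d
  if (s[2] < 1e-8 * max(s[1], 1e-8)) {
    stop(label, " is degenerate (atoms coincident or collinear); ",
         "rotation undefined")
  }
  invisible(TRUE)
}

#' Superpose every frame of a trajectory onto a reference
#'
#' Least-squares fits each frame (optimal translation + proper rotation,
#' Kabsch algorithm) onto the reference coordinates over `fit_idx`, applying
#' the transform to all atoms. With fewer than 3 fit atoms only the
#' translation is removed (a rotation is not defined), mirroring the
#' convention that fitting is disabled for single-particle systems.
#'
#' @param traj A [trajectory()].
#' @param fit_idx Atom indices used to define the fit.
#' @param ref Reference coordinates: an `n_atoms x 3` matrix (full system) or
#'   a frame index into `traj` (default 1, i.e. the first frame of the
#'   analysed window).
#' @return A [trajectory()] with transformed coordinates.
#' @export
superpose_trajectory <- function(traj, fit_idx, ref = 1L) {
  if (is.numeric(ref) && length(ref) == 1) ref <- frame_coords(traj, ref)
  if (nrow(ref) != dim(traj$coords)[2]) {
    stop("reference must carry the full atom set")
  }
  refsel <- ref[fit_idx, , drop = FALSE]
  if (length(fit_idx) >= 3) check_fit_selection(refsel, "fit selection")
  out <- traj$coords
  for (i in seq_len(n_frames(traj))) {
    fr <- frame_coords(traj, i)
    out[i, , ] <- kabsch_superpose(fr[fit_idx, , drop = FALSE], refsel, fr)
  }
  trajectory(out, traj$times)
}
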
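#' Re-image molecules to an anchor selection
#'
#' Translates each molecule by integer multiples of the box vectors so that
#' its center of mass lies within half a box length of the anchor
#' selection's center of mass in x, y and z. Intra-molecule geometry is
#' unchanged (whole-molecule translations only). This reproduces the
#' standard "autoimage" preprocessing that keeps the protein contiguous
#' under periodic boundary conditions.
#'
#' @param traj \code{"trajectory"} with a box on every frame.
#' @param anchor selection string or atom positions defining the anchor.
#' @return re-imaged \code{"trajectory"}.
#' @export
reimage_to_anchor <- function(traj, anchor) {
  if (is.null(traj$box)) stop("re-imaging requires an orthorhombic box on every frame")
  if (is.character(anchor)) anchor <- select_atoms(traj$top, anchor)
  if (!length(anchor)) stop("anchor selection is empty")
  at <- traj$top$atoms
  mols <- split(seq_len(nrow(at)), at$molno)
  elem <- at$elem
  for (f in seq_len(traj$n_frames)) {
    xyz <- frame_coords(traj, f)
    L <- traj$box[f, ]
    ref <- center_of_mass(xyz[anchor, , drop = FALSE], elem[anchor])
    for (idx in mols) {
      com <- center_of_mass(xyz[idx, , drop = FALSE], elem[idx])
      shift <- -L * round((com - ref) / L)
      if (any(shift != 0))
        xyz[idx, ] <- sweep(xyz[idx, , drop = FALSE], 2, shift, "+")
    }
    traj <- .set_frame(traj, f, xyz)
  }
  traj
}

# Least-squares rotation (Kabsch, SVD form) mapping moving -> fixed after
# both are centered; determinant check forbids reflections.
kabsch_rotation <- function(fixed, moving) {
  H <- crossprod(moving, fixed)
  s <- svd(H)
  d <- sign(det(s$v %*% t(s$u)))
  D <- diag(c(1, 1, d))
  s$v %*% D %*% t(s$u)
}

.check_noncollinear <- function(x) {
  if (nrow(x) < 3) stop("superposition selection needs >= 3 atoms")
  xc <- sweep(x, 2, colMeans(x))
  sv <- svd(xc)$d
  if (sv[2] < 1e-8 * max(sv[1], 1))
    stop("superposition selection is collinear/degenerate")
}

#' Superpose every frame onto a reference frame
#'
#' Rigid-body least-squares superposition (rotation + translation, no
#' reflection) of each frame onto the given reference frame, fitting on the
#' selection and applying the transform to all atoms.
#'
#' @param traj trajectory.
#' @param ref_frame 1-based reference frame index.
#' @param sel selection string or atom positions to fit on.
#' @return superposed trajectory.
#' @export
superpose_frames <- function(traj, ref_frame = 1L, sel = "calpha") {
  if (is.character(sel)) sel <- select_atoms(traj$top, sel)
  if (!length(sel)) stop("superposition selection is empty")
  ref <- frame_coords(traj, ref_frame)[sel, , drop = FALSE]
  .check_noncollinear(ref)
  ref_c <- colMeans(ref)
  ref0 <- sweep(ref, 2, ref_c)
  for (f in seq_len(traj$n_frames)) {
    xyz <- frame_coords(traj, f)
    mov <- xyz[sel, , drop = FALSE]
    mc <- colMeans(mov)
    R <- kabsch_rotation(ref0, sweep(mov, 2, mc))
    xyz <- sweep(sweep(xyz, 2, mc) %*% t(R), 2, ref_c, "+")
    traj <- .set_frame(traj, f, xyz)
  }
  traj
}

#' Best-fit RMSD time series
#'
#' Per-frame root-mean-square deviation (Angstrom) of the selection from a
#' reference frame, after least-squares superposition on that same
#' selection.
#'
#' @param traj trajectory.
#' @param ref_frame 1-based reference frame index (default 1; the reference
#'   structure for published time courses is configurable here).
#' @param sel selection string or atom positions.
#' @return data.frame (class \code{"rmsd_series"}): time_ns, rmsd_A,
#'   selection, reference_frame.
#' @export
rmsd_series <- function(traj, ref_frame = 1L, sel = "backbone") {
  lab <- if (is.character(sel)) sel else "custom"
  if (is.character(sel)) sel <- select_atoms(traj$top, sel)
  if (!length(sel)) stop("RMSD selection is empty")
  ref <- frame_coords(traj, ref_frame)[sel, , drop = FALSE]
  ref0 <- sweep(ref, 2, colMeans(ref))
  rmsd <- vapply(seq_len(traj$n_frames), function(f) {
    mov <- frame_coords(traj, f)[sel, , drop = FALSE]
    mov0 <- sweep(mov, 2, colMeans(mov))
    R <- kabsch_rotation(ref0, mov0)
    sqrt(mean(rowSums((mov0 %*% t(R) - ref0)^2)))
  }, numeric(1))
  out <- data.frame(time_ns = traj$time, rmsd_A = rmsd, selection = lab,
                    reference_frame = ref_frame)
  class(out) <- c("rmsd_series", "data.frame")
  out
}

#' Write an RMSD series to CSV
#' @param x \code{"rmsd_series"}; @param path output CSV.
#' @export
write_rmsd_csv <- function(x, path) {
  utils::write.csv(as.data.frame(x), path, row.names = FALSE)
  invisible(path)
}
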
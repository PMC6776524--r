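#' Focused PCA of arm motion, mode projections and tilt/twist angles
#'
#' Eigendecomposition of the 3N x 3N C-alpha coordinate covariance over a
#' trajectory interval isolates the dominant collective motions (arm tilt
#' and twist under membrane stretch). Per-arm tilt/twist series use the
#' spherical angles of the proximal-to-distal arm axis relative to the
#' membrane normal (z), zeroed at a reference frame.
#'
#' @name arm_motion_pca
NULL

#' Principal component analysis of C-alpha motion
#'
#' Frames of the interval are superposed on the interval's first frame
#' (least squares on the selection) before the covariance is built.
#' Eigenvalues are in Angstrom^2, descending; variance fraction k is
#' lambda_k / sum(lambda). Each eigenvector is oriented so its projection
#' increases over the analysis interval (sign convention).
#'
#' @param traj trajectory.
#' @param sel C-alpha selection (string or positions).
#' @param interval frame indices (default all).
#' @param superpose superpose frames on the interval's first frame first
#'   (default TRUE; set FALSE if the trajectory is already aligned).
#' @return object of class \code{"pca_result"}: list(mean [3N], vectors
#'   [3N x m, orthonormal columns], values [descending], fractions, sel,
#'   interval, time).
#' @export
fit_pca <- function(traj, sel = "calpha", interval = NULL, superpose = TRUE) {
  if (is.character(sel)) sel <- select_atoms(traj$top, sel)
  if (is.null(interval)) interval <- seq_len(traj$n_frames)
  if (length(interval) < 3) stop("PCA needs at least 3 frames")
  if (superpose) {
    sub <- trajectory(traj$top, traj$xyz[interval, , drop = FALSE],
                      box = if (is.null(traj$box)) NULL else
                        traj$box[interval, , drop = FALSE],
                      time = traj$time[interval])
    sub <- superpose_frames(sub, ref_frame = 1L, sel = sel)
    X <- sub$xyz
  } else X <- traj$xyz[interval, , drop = FALSE]
  cols <- as.integer(t(outer(3 * (sel - 1), 1:3, "+")))
  X <- X[, cols, drop = FALSE]
  mu <- colMeans(X)
  Xc <- sweep(X, 2, mu)
  s <- svd(Xc, nu = 0)
  values <- s$d^2 / (nrow(Xc) - 1)
  keep <- values > max(values) * 1e-12
  values <- values[keep]
  vectors <- s$v[, keep, drop = FALSE]
  # sign convention: projection increases over the interval
  proj <- Xc %*% vectors
  tt <- seq_len(nrow(proj))
  for (k in seq_len(ncol(vectors))) {
    if (stats::cov(tt, proj[, k]) < 0) vectors[, k] <- -vectors[, k]
  }
  structure(list(mean = mu, vectors = vectors, values = values,
                 fractions = values / sum(values), sel = sel,
                 interval = interval, time = traj$time[interval]),
            class = "pca_result")
}

#' @export
print.pca_result <- function(x, ...) {
  k <- min(5, length(x$values))
  cat("PCA:", length(x$values), "modes;",
      paste0("PC", seq_len(k), " = ",
             sprintf("%.1f%%", 100 * x$fractions[seq_len(k)]),
             collapse = ", "), "\n")
  invisible(x)
}

#' Project frames onto principal modes
#'
#' Projection = dot product of (frame - mean) with each eigenvector, in
#' Angstrom of total C-alpha displacement along the mode. The mean
#' structure projects to 0 on every mode.
#'
#' @param traj trajectory (same selection geometry as the PCA).
#' @param pca \code{"pca_result"}.
#' @param modes mode indices (default 1:2).
#' @param interval frame indices (default the PCA interval).
#' @param superpose superpose onto the PCA's alignment first (default TRUE).
#' @return data.frame: time_ns then one column per mode (\code{PC1}, ...).
#' @export
project_onto_modes <- function(traj, pca, modes = 1:2, interval = NULL,
                               superpose = TRUE) {
  if (any(modes < 1 | modes > ncol(pca$vectors)))
    stop("mode index out of range 1..", ncol(pca$vectors))
  if (is.null(interval)) interval <- pca$interval
  sub <- trajectory(traj$top, traj$xyz[interval, , drop = FALSE],
                    box = if (is.null(traj$box)) NULL else
                      traj$box[interval, , drop = FALSE],
                    time = traj$time[interval])
  if (superpose) sub <- superpose_frames(sub, 1L, pca$sel)
  cols <- as.integer(t(outer(3 * (pca$sel - 1), 1:3, "+")))
  Xc <- sweep(sub$xyz[, cols, drop = FALSE], 2, pca$mean)
  P <- Xc %*% pca$vectors[, modes, drop = FALSE]
  out <- data.frame(time_ns = traj$time[interval])
  for (j in seq_along(modes)) out[[paste0("PC", modes[j])]] <- P[, j]
  out
}

#' Per-arm tilt and twist angle series
#'
#' The arm axis is the vector from the proximal to the distal C-alpha
#' centroid. Tilt is the change (vs the reference frame) of the polar angle
#' between the arm axis and the membrane normal (z); twist is the change of
#' the azimuthal angle of the axis about z. Both in degrees, signed; the
#' azimuth change is wrapped to (-180, 180].
#'
#' @param traj trajectory.
#' @param arms named list: each arm is list(proximal = sel, distal = sel)
#'   with selection strings or atom positions.
#' @param ref_frame reference frame index (default 1).
#' @return data.frame (class \code{"tilt_twist_series"}): arm, time_ns,
#'   tilt_deg, twist_deg.
#' @export
tilt_twist_angles <- function(traj, arms, ref_frame = 1L) {
  rows <- list()
  for (lab in names(arms)) {
    prox <- arms[[lab]]$proximal; dist <- arms[[lab]]$distal
    if (is.character(prox)) prox <- select_atoms(traj$top, prox)
    if (is.character(dist)) dist <- select_atoms(traj$top, dist)
    if (!length(prox) || !length(dist))
      stop("arm '", lab, "': empty proximal or distal selection")
    ax <- function(f) {
      xyz <- frame_coords(traj, f)
      v <- colMeans(xyz[dist, , drop = FALSE]) -
        colMeans(xyz[prox, , drop = FALSE])
      nv <- sqrt(sum(v^2))
      if (nv < 1e-9) stop("arm '", lab, "': zero-length axis at frame ", f)
      v / nv
    }
    v0 <- ax(ref_frame)
    th0 <- acos(pmin(pmax(v0[3], -1), 1)) * 180 / pi
    ph0 <- atan2(v0[2], v0[1]) * 180 / pi
    for (f in seq_len(traj$n_frames)) {
      v <- ax(f)
      th <- acos(pmin(pmax(v[3], -1), 1)) * 180 / pi
      ph <- atan2(v[2], v[1]) * 180 / pi
      rows[[length(rows) + 1L]] <- data.frame(
        arm = lab, time_ns = traj$time[f],
        tilt_deg = th - th0, twist_deg = wrap_angle(ph - ph0))
    }
  }
  out <- do.call(rbind, rows)
  class(out) <- c("tilt_twist_series", "data.frame")
  out
}

#' Write PCA outputs (eigenvalues, projections, tilt/twist, eigenvectors)
#'
#' Eigenvectors are dumped as a plain-text whitespace-separated matrix (one
#' row per coordinate, one column per mode) for visualization tools.
#'
#' @param pca \code{"pca_result"}; @param proj projection data.frame or
#'   NULL; @param tilt \code{"tilt_twist_series"} or NULL; @param dir output
#'   directory.
#' @export
write_pca_outputs <- function(pca, proj = NULL, tilt = NULL, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  utils::write.csv(
    data.frame(mode = seq_along(pca$values), eigenvalue_A2 = pca$values,
               variance_fraction = pca$fractions),
    file.path(dir, "eigenvalues.csv"), row.names = FALSE)
  utils::write.table(format(pca$vectors, digits = 8),
                     file.path(dir, "eigenvectors.txt"),
                     row.names = FALSE, col.names = FALSE, quote = FALSE)
  if (!is.null(proj))
    utils::write.csv(proj, file.path(dir, "projections.csv"), row.names = FALSE)
  if (!is.null(tilt))
    utils::write.csv(as.data.frame(tilt), file.path(dir, "tilt_twist.csv"),
                     row.names = FALSE)
  invisible(dir)
}
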
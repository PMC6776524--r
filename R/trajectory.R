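#' Trajectory container
#'
#' Frames of per-atom coordinates (Angstrom) with per-frame orthorhombic box
#' lengths and time stamps (ns), bound to a \code{\link{topology}}. The
#' coordinate matrix follows the bio3d convention: one row per frame,
#' columns x1, y1, z1, x2, ...
#'
#' @param top \code{"topology"}.
#' @param xyz numeric matrix, frames x 3*n_atoms.
#' @param box numeric matrix frames x 3 (Lx, Ly, Lz in Angstrom) or NULL.
#' @param time numeric vector of frame times in ns; defaults to
#'   \code{(0:(F-1)) * dt}.
#' @param dt frame interval in ns used when \code{time} is NULL. The default
#'   1.2 ns matches the trajectory output interval used throughout the
#'   analyses.
#' @return object of class \code{"trajectory"}.
#' @export
trajectory <- function(top, xyz, box = NULL, time = NULL, dt = 1.2) {
  stopifnot(inherits(top, "topology"))
  xyz <- as.matrix(xyz)
  if (ncol(xyz) != 3L * top$n_atoms)
    stop("coordinate columns (", ncol(xyz), ") do not match 3 x atom count (",
         3L * top$n_atoms, ")")
  nf <- nrow(xyz)
  if (is.null(time)) time <- (seq_len(nf) - 1) * dt
  if (length(time) != nf) stop("time length must equal frame count")
  if (nf > 1 && any(diff(time) <= 0)) stop("frame times must strictly increase")
  if (!is.null(box)) {
    box <- matrix(as.numeric(box), ncol = 3,
                  nrow = nf, byrow = is.null(dim(box)))
    if (any(!is.finite(box)) || any(box <= 0))
      stop("box lengths must be positive and finite")
  }
  structure(list(top = top, xyz = xyz, box = box, time = time,
                 n_frames = nf), class = "trajectory")
}

#' @export
print.trajectory <- function(x, ...) {
  cat(sprintf("Trajectory: %d frames x %d atoms, t = %.2f..%.2f ns%s\n",
              x$n_frames, x$top$n_atoms, x$time[1], x$time[x$n_frames],
              if (is.null(x$box)) " (no box)" else ""))
  invisible(x)
}

#' Coordinates of one frame as an n x 3 matrix
#' @param traj trajectory; @param frame 1-based frame index;
#' @param sel optional atom positions or selection string.
#' @export
frame_coords <- function(traj, frame, sel = NULL) {
  x <- matrix(traj$xyz[frame, ], ncol = 3, byrow = TRUE)
  if (!is.null(sel)) {
    if (is.character(sel)) sel <- select_atoms(traj$top, sel)
    x <- x[sel, , drop = FALSE]
  }
  x
}

# Replace coordinates of one frame from an n x 3 matrix.
.set_frame <- function(traj, frame, coords) {
  traj$xyz[frame, ] <- as.numeric(t(coords))
  traj
}

#' Load a trajectory from multi-model PDB or DCD
#'
#' Multi-model PDB and DCD are read via bio3d. XTC is not supported and is
#' refused with an explicit error. Box lengths are taken from the file
#' (CRYST1 records / DCD unit cell) when present, else from \code{box}.
#'
#' @param path trajectory file (.pdb, .dcd).
#' @param top \code{"topology"} the frames must match.
#' @param box fallback c(Lx, Ly, Lz) in Angstrom when the file stores none.
#' @param dt frame interval (ns) when the file stores no times.
#' @return \code{"trajectory"}.
#' @export
load_trajectory <- function(path, top, box = NULL, dt = 1.2) {
  if (!file.exists(path)) stop("file not found: ", path)
  ext <- tolower(tools::file_ext(path))
  if (ext == "xtc")
    stop("XTC input is not supported; convert to DCD or multi-model PDB")
  if (ext == "dcd") {
    cellxyz <- tryCatch(bio3d::read.dcd(path, verbose = FALSE, cell = TRUE),
                        error = function(e) NULL)
    xyz <- bio3d::read.dcd(path, verbose = FALSE)
    fbox <- NULL
    if (!is.null(cellxyz) && ncol(cellxyz) >= 6)
      fbox <- cellxyz[, c(1, 2, 3), drop = FALSE]
  } else {
    pdb <- suppressWarnings(bio3d::read.pdb(path, multi = TRUE, verbose = FALSE))
    xyz <- pdb$xyz
    if (is.null(dim(xyz))) xyz <- matrix(xyz, nrow = 1)
    fbox <- .read_cryst1(path)
  }
  n_file <- ncol(xyz) / 3
  if (n_file != top$n_atoms)
    stop("atom count mismatch: file has ", n_file, ", topology has ",
         top$n_atoms)
  bad <- which(apply(xyz, 1, function(r) any(!is.finite(r))))
  if (length(bad)) stop("unreadable coordinates at frame ", bad[1])
  if (is.null(fbox) && !is.null(box)) fbox <- matrix(box, nrow(xyz), 3, byrow = TRUE)
  if (!is.null(fbox) && nrow(fbox) == 1 && nrow(xyz) > 1)
    fbox <- fbox[rep(1, nrow(xyz)), , drop = FALSE]
  trajectory(top, xyz, box = fbox, dt = dt)
}

.read_cryst1 <- function(path) {
  ln <- grep("^CRYST1", readLines(path, warn = FALSE), value = TRUE)
  if (!length(ln)) return(NULL)
  abc <- t(vapply(ln, function(l)
    as.numeric(c(substr(l, 7, 15), substr(l, 16, 24), substr(l, 25, 33))),
    numeric(3)))
  rownames(abc) <- NULL
  ang <- vapply(ln, function(l)
    as.numeric(c(substr(l, 34, 40), substr(l, 41, 47), substr(l, 48, 54))),
    numeric(3))
  if (any(abs(ang - 90) > 1e-3, na.rm = TRUE))
    stop("triclinic box is not supported (orthorhombic only)")
  abc
}

#' Write a trajectory as multi-model PDB
#'
#' One MODEL/ENDMDL block per frame, a CRYST1 record per frame when a box is
#' present, and TER records at molecule boundaries (so that molecule
#' inference on re-read reproduces the grouping).
#'
#' @param traj trajectory; @param path output file.
#' @export
write_trajectory_pdb <- function(traj, path) {
  at <- traj$top$atoms
  n <- nrow(at)
  con <- file(path, "w")
  on.exit(close(con))
  ter_after <- which(diff(c(at$molno, -1L)) != 0L)
  chain <- substr(ifelse(is.na(at$chain) | at$chain == "", "A", at$chain), 1, 1)
  for (f in seq_len(traj$n_frames)) {
    if (!is.null(traj$box))
      writeLines(sprintf(
        "CRYST1%9.3f%9.3f%9.3f%7.2f%7.2f%7.2f P 1           1",
        traj$box[f, 1], traj$box[f, 2], traj$box[f, 3], 90, 90, 90), con)
    writeLines(sprintf("MODEL     %4d", f), con)
    xyz <- frame_coords(traj, f)
    nm <- ifelse(nchar(at$name) < 4, sprintf(" %-3s", at$name),
                 substr(at$name, 1, 4))
    lines <- sprintf(
      "ATOM  %5d %4s %-4s%1s%4d    %8.3f%8.3f%8.3f  1.00  0.00          %2s",
      (seq_len(n) - 1L) %% 99999L + 1L, nm, substr(at$resname, 1, 4), chain,
      at$resno %% 10000L, xyz[, 1], xyz[, 2], xyz[, 3],
      substr(at$elem, 1, 2))
    out <- character(n + length(ter_after))
    pos <- seq_len(n) + findInterval(seq_len(n) - 1L, ter_after)
    out[pos] <- lines
    out[setdiff(seq_along(out), pos)] <- "TER"
    writeLines(out, con)
    writeLines("ENDMDL", con)
  }
  writeLines("END", con)
  invisible(path)
}

#' Write a trajectory as a CHARMM-format DCD file
#'
#' Minimal single-precision DCD writer (no fixed atoms, orthorhombic unit
#' cell block when a box is present), readable by \code{bio3d::read.dcd}.
#'
#' @param traj trajectory; @param path output file.
#' @export
write_trajectory_dcd <- function(traj, path) {
  con <- file(path, "wb")
  on.exit(close(con))
  has_cell <- !is.null(traj$box)
  wrec <- function(writer) {
    # fortran unformatted record: length prefix/suffix in bytes
    tmp <- raw(0)
    rc <- rawConnection(tmp, "wb")
    writer(rc)
    dat <- rawConnectionValue(rc)
    close(rc)
    writeBin(length(dat), con, size = 4, endian = "little")
    writeBin(dat, con)
    writeBin(length(dat), con, size = 4, endian = "little")
  }
  icntrl <- integer(20)
  icntrl[1] <- traj$n_frames; icntrl[2] <- 1L; icntrl[3] <- 1L
  icntrl[11] <- if (has_cell) 1L else 0L
  icntrl[20] <- 24L
  wrec(function(rc) {
    writeChar("CORD", rc, nchars = 4, eos = NULL)
    writeBin(icntrl, rc, size = 4, endian = "little")
  })
  wrec(function(rc) {
    writeBin(1L, rc, size = 4, endian = "little")
    writeChar(formatC("piezotraj synthetic trajectory", width = -80), rc,
              nchars = 80, eos = NULL)
  })
  wrec(function(rc) writeBin(traj$top$n_atoms, rc, size = 4, endian = "little"))
  idx <- seq_len(traj$top$n_atoms)
  for (f in seq_len(traj$n_frames)) {
    if (has_cell) {
      b <- traj$box[f, ]
      wrec(function(rc) writeBin(as.numeric(c(b[1], 0, b[2], 0, 0, b[3])),
                                 rc, size = 8, endian = "little"))
    }
    xyz <- frame_coords(traj, f)
    for (d in 1:3)
      wrec(function(rc) writeBin(as.numeric(xyz[, d]), rc, size = 4,
                                 endian = "little"))
  }
  invisible(path)
}
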
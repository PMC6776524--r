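#' Membrane dome curvature from lipid headgroup positions
#'
#' The curvature pipeline: assign lipids to leaflets, grid the headgroup
#' center-of-mass heights per leaflet (with periodic tiling and optional
#' local-mean smoothing), fit a bivariate radial Gaussian dome
#' \deqn{z(x,y) = z_0 + z_h \exp(-((x-r_x)^2+(y-r_y)^2)/\sigma^2)}
#' and report the curvature radius at the dome apex from the peak second
#' derivative \eqn{d = -2 z_h / \sigma^2}, \eqn{R = (1+d^2)^{3/2}/d}.
#'
#' @name membrane_curvature
NULL

#' Assign lipids to upper/lower leaflets
#'
#' A lipid belongs to the upper leaflet iff its designated head atom lies
#' above (greater z than) its designated tail atom in the given frame. Valid
#' while the membrane surface never folds past vertical, which holds for the
#' Piezo dome geometry.
#'
#' @param traj trajectory; @param frame frame index.
#' @param lipid_resname lipid residue name (e.g. "POPC").
#' @param head_names atom name(s) of the headgroup; first match per lipid is
#'   the designated head for the up/down test.
#' @param tail_name atom name of the designated tail atom.
#' @return object of class \code{"leaflet_assignment"}: data.frame with
#'   molno, leaflet ("upper"/"lower").
#' @export
assign_leaflets <- function(traj, frame = 1L, lipid_resname = "POPC",
                            head_names = "P", tail_name = "T") {
  at <- traj$top$atoms
  lip <- which(at$resname == lipid_resname)
  if (!length(lip)) stop("no lipids with resname ", lipid_resname)
  xyz <- frame_coords(traj, frame)
  mols <- split(lip, at$molno[lip])
  res <- lapply(names(mols), function(m) {
    idx <- mols[[m]]
    h <- idx[at$name[idx] %in% head_names]
    t <- idx[at$name[idx] == tail_name]
    if (!length(h)) stop("lipid molecule ", m, " has no head atom (",
                         paste(head_names, collapse = ","), ")")
    if (!length(t)) stop("lipid molecule ", m, " has no tail atom (",
                         tail_name, ")")
    data.frame(molno = as.integer(m),
               leaflet = if (xyz[h[1], 3] > xyz[t[1], 3]) "upper" else "lower")
  })
  out <- do.call(rbind, res)
  class(out) <- c("leaflet_assignment", "data.frame")
  out
}

#' Kernel size for local-mean smoothing
#'
#' One quarter of the geometric mean of the grid dimensions (gridpoint
#' counts), rounded up.
#'
#' @param nx,ny gridpoint counts.
#' @return integer kernel size in grid units.
#' @export
#' @examples kernel_size_rule(52, 50)  # 13
kernel_size_rule <- function(nx, ny) {
  stopifnot(nx >= 1, ny >= 1)
  as.integer(ceiling(sqrt(nx * ny) / 4))
}

# Circular (wrap-mode) running mean of length k along rows then columns;
# the separable equivalent of a k x k uniform filter with wrap edges.
.uniform_filter_wrap <- function(z, k) {
  if (k <= 1) return(z)
  smooth1 <- function(m) {
    n <- nrow(m)
    off <- seq_len(k) - 1L - (k %/% 2L)   # centered window, even k biased low
    acc <- matrix(0, n, ncol(m))
    for (o in off) acc <- acc + m[((seq_len(n) - 1L + o) %% n) + 1L, , drop = FALSE]
    acc / k
  }
  t(smooth1(t(smooth1(z))))
}

#' Grid headgroup heights onto a regular x-y grid
#'
#' Implements the gridding protocol: (1) the points are tiled into the
#' eight adjacent x-y periodic images (9x the point count); (2) grid extents
#' cover all original points with one grid-spacing padding per edge;
#' (3) heights are interpolated onto the grid from the scattered tiled
#' points by bilinear-weight (cloud-in-cell) binning, followed by a
#' discrete-Laplacian sharpening step that cancels the binning kernel's
#' second-order low-pass bias; (4) optionally a uniform local-mean kernel of
#' size \code{kernel_size_rule(nx, ny)} with wrap-mode edges is applied.
#'
#' @param points n x 3 matrix of headgroup COM coordinates (Angstrom).
#' @param box c(Lx, Ly) or c(Lx, Ly, Lz) box lengths for the periodic tiling.
#' @param spacing grid spacing in Angstrom (default 4.6, about twice the
#'   molecular radius of a phosphate ion).
#' @param smooth apply the local-mean kernel (default TRUE).
#' @param kernel optional kernel size override (grid units).
#' @return object of class \code{"headgroup_grid"}: list(z [nx x ny], x, y,
#'   spacing, nx, ny, smoothed, kernel).
#' @export
build_height_grid <- function(points, box, spacing = 4.6, smooth = TRUE,
                              kernel = NULL) {
  points <- as.matrix(points)
  if (nrow(points) < 4) stop("need at least 4 headgroup points")
  if (spacing <= 0) stop("grid spacing must be positive")
  box <- as.numeric(box)
  if (any(box[1:2] <= 0)) stop("box lengths must be positive")
  if (stats::sd(points[, 1]) < 1e-9 || stats::sd(points[, 2]) < 1e-9)
    stop("headgroup points are collinear; cannot interpolate a surface")

  # (2) extents with one-spacing padding per edge
  x0 <- min(points[, 1]) - spacing
  x1 <- max(points[, 1]) + spacing
  y0 <- min(points[, 2]) - spacing
  y1 <- max(points[, 2]) + spacing
  nx <- max(4L, as.integer(ceiling((x1 - x0) / spacing)) + 1L)
  ny <- max(4L, as.integer(ceiling((y1 - y0) / spacing)) + 1L)
  gx <- x0 + (seq_len(nx) - 1L) * spacing
  gy <- y0 + (seq_len(ny) - 1L) * spacing

  # (1) tile into the 8 adjacent x-y periodic images
  tiled <- tile_points_xy(points, box)

  # (3) triangular-kernel weighted binning onto the grid. The deposit
  # footprint is a separable triangle of half-width `deposit_width` cells
  # (wide enough that typical lipid densities leave no gridpoint empty).
  w <- 2L   # deposit half-width in cells
  fx <- (tiled[, 1] - x0) / spacing
  fy <- (tiled[, 2] - y0) / spacing
  keep <- fx > -w & fx < nx - 1L + w & fy > -w & fy < ny - 1L + w
  fx <- fx[keep]; fy <- fy[keep]; tz <- tiled[keep, 3]
  zsum <- matrix(0, nx, ny); wsum <- matrix(0, nx, ny)
  acc <- function(i, j, wt) {
    ok <- i >= 0 & i < nx & j >= 0 & j < ny & wt > 0
    if (!any(ok)) return(invisible())
    lin <- i[ok] + 1L + j[ok] * nx
    zs <- rowsum(cbind(wt[ok] * tz[ok], wt[ok]), group = lin)
    li <- as.integer(rownames(zs))
    zsum[li] <<- zsum[li] + zs[, 1]
    wsum[li] <<- wsum[li] + zs[, 2]
    invisible()
  }
  i0 <- floor(fx); j0 <- floor(fy)
  for (di in (-w + 1L):w) for (dj in (-w + 1L):w) {
    ii <- i0 + di; jj <- j0 + dj
    wt <- pmax(0, 1 - abs(fx - ii) / w) * pmax(0, 1 - abs(fy - jj) / w)
    acc(ii, jj, wt)
  }
  z <- zsum / wsum
  if (any(!is.finite(z))) {
    # fill stray empty gridpoints harmonically (repeated neighbor means)
    if (!any(is.finite(z))) stop("no gridpoint received any point weight")
    for (it in 1:100) {
      empty <- !is.finite(z)
      if (!any(empty)) break
      zf <- z; zf[empty] <- 0
      cnt <- matrix(0, nx, ny); cnt[!empty] <- 1
      nb_sum <- .shift_sum(zf); nb_cnt <- .shift_sum(cnt)
      repl <- empty & nb_cnt > 0
      z[repl] <- nb_sum[repl] / nb_cnt[repl]
    }
    if (any(!is.finite(z))) stop("grid has unreachable empty regions")
  }
  # sharpening: the triangular deposit kernel has variance (w*spacing)^2/6
  # per axis; subtracting (w^2/12) * discrete Laplacian removes the induced
  # second-order low-pass bias.
  z <- z - (w^2 / 12) * .discrete_laplacian(z)

  k <- if (is.null(kernel)) kernel_size_rule(nx, ny) else as.integer(kernel)
  if (smooth) z <- .uniform_filter_wrap(z, k)
  structure(list(z = z, x = gx, y = gy, spacing = spacing, nx = nx, ny = ny,
                 smoothed = smooth, kernel = if (smooth) k else NA_integer_),
            class = "headgroup_grid")
}

# Sum of the 4 orthogonal neighbors, replicated edges.
.shift_sum <- function(z) {
  nx <- nrow(z); ny <- ncol(z)
  z[c(1, seq_len(nx - 1)), ] + z[c(seq_len(nx - 1) + 1, nx), ] +
    z[, c(1, seq_len(ny - 1))] + z[, c(seq_len(ny - 1) + 1, ny)]
}

# 5-point discrete Laplacian in grid units, replicated edges.
.discrete_laplacian <- function(z) {
  nx <- nrow(z); ny <- ncol(z)
  up <- z[c(1, seq_len(nx - 1)), ]; dn <- z[c(seq_len(nx - 1) + 1, nx), ]
  lf <- z[, c(1, seq_len(ny - 1))]; rt <- z[, c(seq_len(ny - 1) + 1, ny)]
  up + dn + lf + rt - 4 * z
}

#' Tile points into the 8 adjacent x-y periodic images
#'
#' @param points n x 3 matrix; @param box box lengths (first two used).
#' @return 9n x 3 matrix (original points first).
#' @export
tile_points_xy <- function(points, box) {
  shifts <- expand.grid(sx = -1:1, sy = -1:1)
  shifts <- shifts[order(abs(shifts$sx) + abs(shifts$sy)), ]
  do.call(rbind, lapply(seq_len(nrow(shifts)), function(k) {
    p <- points
    p[, 1] <- p[, 1] + shifts$sx[k] * box[1]
    p[, 2] <- p[, 2] + shifts$sy[k] * box[2]
    p
  }))
}

#' Fit the radial Gaussian dome to a height grid
#'
#' Least-squares fit of \eqn{z_0 + z_h \exp(-((x-r_x)^2+(y-r_y)^2)/\sigma^2)}
#' by Levenberg-Marquardt. Deterministic initialization: z0 = grid median,
#' zh = (extremum - median), (rx, ry) = grid extremum position, sigma = a
#' quarter of the smaller grid extent; sigma bounded in (1 Angstrom, grid
#' diagonal).
#'
#' @param grid \code{"headgroup_grid"}.
#' @param flat_tol |zh| below which the membrane is reported flat (R
#'   infinite sentinel); default 1e-3 Angstrom.
#' @return object of class \code{"dome_fit"}: list(z0, zh, rx, ry, sigma,
#'   d, R, residual_A, converged).
#' @export
fit_dome <- function(grid, flat_tol = 1e-3) {
  z <- grid$z
  if (any(!is.finite(z))) stop("grid contains non-finite heights")
  if (length(z) < 5) stop("need at least 5 gridpoints to fit 5 parameters")
  df <- data.frame(x = rep(grid$x, times = grid$ny),
                   y = rep(grid$y, each = grid$nx),
                   z = as.numeric(z))
  if (diff(range(df$z)) < 1e-8) {
    # flat membrane: no dome to fit
    return(structure(list(z0 = mean(df$z), zh = 0, rx = mean(grid$x),
                          ry = mean(grid$y), sigma = NA_real_, d = 0,
                          R = Inf, residual_A = stats::sd(df$z),
                          converged = TRUE), class = "dome_fit"))
  }
  zmed <- stats::median(df$z)
  # extremum: farthest grid value from the median (dome may point up or down)
  iext <- which.max(abs(df$z - zmed))
  z0_0 <- zmed
  zh_0 <- df$z[iext] - zmed
  rx_0 <- df$x[iext]; ry_0 <- df$y[iext]
  ext_x <- diff(range(grid$x)); ext_y <- diff(range(grid$y))
  sig_0 <- max(2 * grid$spacing, min(ext_x, ext_y) / 4)
  sig_hi <- sqrt(ext_x^2 + ext_y^2)
  starts <- list(
    c(z0 = z0_0, zh = zh_0, rx = rx_0, ry = ry_0, sigma = sig_0),
    c(z0 = z0_0, zh = zh_0 / 2, rx = rx_0, ry = ry_0, sigma = sig_0 * 2),
    c(z0 = mean(df$z), zh = -diff(range(df$z)), rx = mean(grid$x),
      ry = mean(grid$y), sigma = sig_0))
  best <- NULL
  for (s in starts) {
    fit <- tryCatch(
      minpack.lm::nlsLM(
        z ~ z0 + zh * exp(-((x - rx)^2 + (y - ry)^2) / sigma^2),
        data = df, start = as.list(s),
        lower = c(-Inf, -Inf, -Inf, -Inf, 1),
        upper = c(Inf, Inf, Inf, Inf, sig_hi),
        control = minpack.lm::nls.lm.control(maxiter = 200)),
      error = function(e) NULL)
    if (is.null(fit)) next
    rss <- sum(stats::residuals(fit)^2)
    if (is.null(best) || rss < best$rss) best <- list(fit = fit, rss = rss)
  }
  if (is.null(best))
    stop("dome fit did not converge from any start (grid ", grid$nx, "x",
         grid$ny, ")")
  p <- stats::coef(best$fit)
  resid <- sqrt(best$rss / length(df$z))
  cr <- curvature_radius(zh = p[["zh"]], sigma = p[["sigma"]],
                         flat_tol = flat_tol)
  structure(list(z0 = p[["z0"]], zh = p[["zh"]], rx = p[["rx"]],
                 ry = p[["ry"]], sigma = p[["sigma"]], d = cr$d, R = cr$R,
                 residual_A = resid, converged = TRUE),
            class = "dome_fit")
}

#' Curvature radius at the dome apex
#'
#' Exact closed form from the fitted dome: \eqn{d = -2 z_h/\sigma^2} (the
#' surface second derivative at the apex, in 1/Angstrom) and
#' \eqn{R = (1+d^2)^{3/2}/d} (Angstrom, signed; the sign of R follows the
#' sign of d). A flat membrane (|zh| <= flat_tol) yields an infinite
#' sentinel.
#'
#' @param zh indentation depth (Angstrom, signed); or a \code{"dome_fit"}.
#' @param sigma Gaussian width (Angstrom, > 0).
#' @param flat_tol flat-membrane threshold on |zh|.
#' @return list(d, R).
#' @export
curvature_radius <- function(zh, sigma = NULL, flat_tol = 0) {
  if (inherits(zh, "dome_fit")) { sigma <- zh$sigma; zh <- zh$zh }
  if (is.null(sigma) || sigma <= 0) stop("sigma must be positive")
  if (abs(zh) <= flat_tol) return(list(d = 0, R = Inf))
  d <- -2 * zh / sigma^2
  list(d = d, R = (1 + d^2)^(3 / 2) / d)
}

#' Per-frame, per-leaflet curvature radius time series
#'
#' Runs the full curvature pipeline on every frame and both leaflets.
#' Frames whose dome fit fails are recorded as missing values, not fatal.
#' The reported radius column is |R| (in Angstrom and nm); the signed value
#' is kept in \code{R_signed_A}. An optional LOESS smoother over time with
#' configurable span (default 0.047, i.e. 4.7 percent of the series) is
#' emitted as \code{R_nm_smoothed}.
#'
#' @param traj trajectory.
#' @param lipid_config list(resname, head_names, tail_name) naming the lipid
#'   residue, its headgroup atoms (COM atoms) and its designated tail atom.
#'   May be a YAML file path with those keys.
#' @param spacing grid spacing (Angstrom).
#' @param span LOESS span fraction; NA disables the smoother.
#' @param smooth apply the local-mean grid kernel (default TRUE).
#' @param frames frame indices to analyze (default all).
#' @return data.frame (class \code{"curvature_series"}): time_ns, leaflet,
#'   R_A, R_nm, R_signed_A, residual_A, R_nm_smoothed.
#' @export
curvature_timeseries <- function(traj, lipid_config, spacing = 4.6,
                                 span = 0.047, smooth = TRUE, frames = NULL) {
  cfg <- .lipid_config(lipid_config)
  if (is.null(frames)) frames <- seq_len(traj$n_frames)
  la <- assign_leaflets(traj, frame = frames[1], lipid_resname = cfg$resname,
                        head_names = cfg$head_names, tail_name = cfg$tail_name)
  at <- traj$top$atoms
  rows <- list()
  for (f in frames) {
    xyz <- frame_coords(traj, f)
    box <- if (!is.null(traj$box)) traj$box[f, ] else
      c(diff(range(xyz[, 1])), diff(range(xyz[, 2])), diff(range(xyz[, 3])))
    for (leaf in c("upper", "lower")) {
      mols <- la$molno[la$leaflet == leaf]
      pts <- headgroup_com_points(traj, f, mols, cfg)
      res <- tryCatch({
        g <- build_height_grid(pts, box, spacing = spacing, smooth = smooth)
        fit_dome(g)
      }, error = function(e) NULL)
      rows[[length(rows) + 1L]] <- data.frame(
        time_ns = traj$time[f], leaflet = leaf,
        R_A = if (is.null(res)) NA_real_ else abs(res$R),
        R_nm = if (is.null(res)) NA_real_ else abs(res$R) / 10,
        R_signed_A = if (is.null(res)) NA_real_ else res$R,
        residual_A = if (is.null(res)) NA_real_ else res$residual_A)
    }
  }
  out <- do.call(rbind, rows)
  out$R_nm_smoothed <- NA_real_
  if (!is.na(span) && length(frames) >= 10) {
    for (leaf in c("upper", "lower")) {
      i <- which(out$leaflet == leaf & is.finite(out$R_nm))
      if (length(i) >= 10) {
        sp <- max(span, 10 / length(i))
        lo <- try(stats::loess(R_nm ~ time_ns, data = out[i, ], span = sp,
                               degree = 2), silent = TRUE)
        if (!inherits(lo, "try-error"))
          out$R_nm_smoothed[i] <- stats::predict(lo)
      }
    }
  }
  class(out) <- c("curvature_series", "data.frame")
  out
}

#' Headgroup center-of-mass points for a set of lipid molecules
#' @param traj trajectory; @param frame frame index; @param mols molecule ids;
#' @param cfg lipid config list (see \code{curvature_timeseries}).
#' @return m x 3 matrix of mass-weighted headgroup COMs.
#' @export
headgroup_com_points <- function(traj, frame, mols, cfg) {
  cfg <- .lipid_config(cfg)
  at <- traj$top$atoms
  xyz <- frame_coords(traj, frame)
  sel <- which(at$molno %in% mols & at$resname == cfg$resname &
                 at$name %in% cfg$head_names)
  grp <- at$molno[sel]
  w <- atomic_mass(at$elem[sel])
  sw <- rowsum(cbind(xyz[sel, , drop = FALSE] * w, w), group = grp)
  sw[, 1:3, drop = FALSE] / sw[, 4]
}

.lipid_config <- function(cfg) {
  if (is.character(cfg) && length(cfg) == 1 && file.exists(cfg)) {
    if (!requireNamespace("yaml", quietly = TRUE))
      stop("reading a lipid config file requires the 'yaml' package")
    cfg <- yaml::read_yaml(cfg)
  }
  stopifnot(is.list(cfg), !is.null(cfg$resname), !is.null(cfg$head_names),
            !is.null(cfg$tail_name))
  cfg
}

#' Write a curvature series to CSV
#' @param x \code{"curvature_series"}; @param path output CSV.
#' @export
write_curvature_csv <- function(x, path) {
  utils::write.csv(as.data.frame(x), path, row.names = FALSE)
  invisible(path)
}
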
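#' Ligand mobility analysis: windowed RMSF, stability ranking, contacts and
#' membrane leaflet of entry
#'
#' Spontaneously binding ligands settle into pockets and their positional
#' fluctuations collapse; ranking ligands by time-averaged windowed RMSF
#' identifies stable binders among a freely diffusing ensemble.
#'
#' @name ligand_mobility
NULL

#' Windowed RMSF time course per ligand
#'
#' For each non-overlapping window of \code{window} frames, RMSF is the
#' square root of the mean (over ligand heavy atoms and window frames) of
#' the squared deviation from the window-mean atomic positions. The
#' trajectory must already be superposed on the protein so that ligand
#' motion is measured in the protein frame.
#'
#' @param traj superposed trajectory.
#' @param ligands named list of atom-position vectors, or a selection-string
#'   template: passing resname "YOD" selects each ligand molecule of that
#'   residue name separately, labelled L1, L2, ...
#' @param window window length in frames (default 20, i.e. 24 ns at the
#'   1.2 ns output interval).
#' @param heavy_only drop hydrogens (default TRUE).
#' @return data.frame (class \code{"ligand_rmsf"}): ligand, window_start_ns,
#'   rmsf_A.
#' @export
ligand_rmsf_timecourse <- function(traj, ligands, window = 20L,
                                   heavy_only = TRUE) {
  if (window < 2) stop("window must span at least 2 frames")
  sels <- .ligand_selections(traj$top, ligands, heavy_only)
  if (!length(sels)) stop("ligand selection is empty")
  nw <- traj$n_frames %/% window
  if (nw < 1) stop("trajectory shorter than one window")
  rows <- list()
  for (lab in names(sels)) {
    idx <- sels[[lab]]
    if (!length(idx)) stop("ligand selection '", lab, "' is empty")
    cols <- as.integer(t(outer(3 * (idx - 1), 1:3, "+")))
    for (w in seq_len(nw)) {
      fr <- ((w - 1L) * window + 1L):(w * window)
      X <- traj$xyz[fr, cols, drop = FALSE]
      dev <- sweep(X, 2, colMeans(X))
      rmsf <- sqrt(sum(dev^2) / (length(fr) * length(idx)))
      rows[[length(rows) + 1L]] <- data.frame(
        ligand = lab, window_start_ns = traj$time[fr[1]], rmsf_A = rmsf)
    }
  }
  out <- do.call(rbind, rows)
  class(out) <- c("ligand_rmsf", "data.frame")
  out
}

.ligand_selections <- function(top, ligands, heavy_only = TRUE) {
  if (is.list(ligands)) {
    sels <- ligands
  } else {
    at <- top$atoms
    idx <- which(at$resname == ligands)
    if (!length(idx)) stop("no atoms with resname ", ligands)
    grp <- split(idx, at$molno[idx])
    sels <- stats::setNames(grp, paste0("L", seq_along(grp)))
  }
  if (heavy_only)
    sels <- lapply(sels, function(i) i[top$atoms$elem[i] != "H"])
  sels
}

#' Rank ligands by time-averaged RMSF
#'
#' Ascending order of mean RMSF over a tail interval of the series (stable
#' binders first). Ties are broken by ligand label order and flagged.
#'
#' @param rmsf \code{"ligand_rmsf"} data.frame.
#' @param tail_fraction fraction of each series (from the end) averaged
#'   (default 0.5).
#' @return data.frame: rank, ligand, mean_rmsf_A, tied.
#' @export
rank_ligand_stability <- function(rmsf, tail_fraction = 0.5) {
  stopifnot(nrow(rmsf) >= 1, tail_fraction > 0, tail_fraction <= 1)
  labs <- unique(rmsf$ligand)
  stat <- vapply(labs, function(l) {
    v <- rmsf$rmsf_A[rmsf$ligand == l]
    k <- max(1L, ceiling(length(v) * tail_fraction))
    mean(utils::tail(v, k))
  }, numeric(1))
  ord <- order(stat, match(labs, labs))   # stable: ties keep label order
  out <- data.frame(rank = seq_along(labs), ligand = labs[ord],
                    mean_rmsf_A = stat[ord])
  out$tied <- duplicated(out$mean_rmsf_A) |
    duplicated(out$mean_rmsf_A, fromLast = TRUE)
  out
}

#' Residue contacts of a ligand over an interval
#'
#' Contact fraction of a residue = share of interval frames in which any
#' ligand heavy atom is within \code{cutoff} of any heavy atom of the
#' residue. Residues at or above \code{threshold} form the reported binding
#' site.
#'
#' @param traj trajectory.
#' @param ligand atom positions or a selection string for one ligand.
#' @param interval frame indices to analyze (default all frames).
#' @param cutoff heavy-atom distance cutoff in Angstrom (default 4.0).
#' @param threshold contact-fraction threshold (default 0.5).
#' @param residue_sel selection restricting candidate residues (default
#'   "protein").
#' @return object of class \code{"binding_site_report"}: list(ligand
#'   positions, contact_fractions data.frame(chain, resno, resname,
#'   fraction), site residues data.frame, cutoff, threshold).
#' @export
binding_contacts <- function(traj, ligand, interval = NULL, cutoff = 4.0,
                             threshold = 0.5, residue_sel = "protein") {
  if (is.character(ligand)) ligand <- select_atoms(traj$top, ligand)
  if (!length(ligand)) stop("ligand selection is empty")
  if (is.null(interval)) interval <- seq_len(traj$n_frames)
  if (!length(interval)) stop("empty analysis interval")
  at <- traj$top$atoms
  lig <- ligand[at$elem[ligand] != "H"]
  cand <- select_atoms(traj$top, residue_sel)
  cand <- setdiff(cand[at$elem[cand] != "H"], lig)
  key <- paste(at$chain[cand], at$resno[cand], sep = "|")
  resids <- unique(key)
  hits <- stats::setNames(numeric(length(resids)), resids)
  for (f in interval) {
    xyz <- frame_coords(traj, f)
    if (cutoff > 0) {
      d <- pair_dists(xyz[cand, , drop = FALSE], xyz[lig, , drop = FALSE])
      close <- apply(d <= cutoff, 1, any)
      touched <- unique(key[close])
      hits[touched] <- hits[touched] + 1
    }
  }
  frac <- hits / length(interval)
  meta <- at[cand[!duplicated(key)], c("chain", "resno", "resname")]
  cf <- data.frame(meta, fraction = as.numeric(frac[paste(meta$chain,
    meta$resno, sep = "|")]), row.names = NULL)
  cf <- cf[order(-cf$fraction, cf$resno), ]
  structure(list(ligand = ligand,
                 contact_fractions = cf,
                 site = cf[cf$fraction >= threshold & cf$fraction > 0, ],
                 cutoff = cutoff, threshold = threshold),
            class = "binding_site_report")
}

#' @export
print.binding_site_report <- function(x, ...) {
  cat(sprintf("Binding site report: %d residue(s) >= %.2f contact fraction (cutoff %.1f A)\n",
              nrow(x$site), x$threshold, x$cutoff))
  if (nrow(x$site)) print(utils::head(x$site, 10))
  invisible(x)
}

#' Classify the membrane leaflet through which a ligand enters
#'
#' The membrane slab at each frame is bounded by the mean phosphate (head
#' atom) z of the lower and upper leaflets. The first frame at which the
#' ligand COM crosses from bulk solvent into the slab determines the entry
#' side; a ligand that never enters is classified "none".
#'
#' @param traj trajectory.
#' @param ligand atom positions or selection string.
#' @param slab_z matrix/data.frame with per-frame columns lower and upper
#'   (mean phosphate z, Angstrom); or NULL to compute from
#'   \code{lipid_config}.
#' @param lipid_config lipid config (see \code{\link{curvature_timeseries}})
#'   used when \code{slab_z} is NULL.
#' @return list(leaflet = "upper"/"lower"/"none", entry_frame, entry_time_ns).
#' @export
classify_entry_leaflet <- function(traj, ligand, slab_z = NULL,
                                   lipid_config = NULL) {
  if (is.character(ligand)) ligand <- select_atoms(traj$top, ligand)
  if (!length(ligand)) stop("ligand selection is empty")
  if (is.null(slab_z)) {
    cfg <- .lipid_config(lipid_config)
    la <- assign_leaflets(traj, 1L, cfg$resname, cfg$head_names, cfg$tail_name)
    slab_z <- t(vapply(seq_len(traj$n_frames), function(f) {
      up <- headgroup_com_points(traj, f, la$molno[la$leaflet == "upper"], cfg)
      lo <- headgroup_com_points(traj, f, la$molno[la$leaflet == "lower"], cfg)
      c(lower = mean(lo[, 3]), upper = mean(up[, 3]))
    }, numeric(2)))
  }
  slab_z <- as.matrix(slab_z)
  elem <- traj$top$atoms$elem[ligand]
  for (f in seq_len(traj$n_frames)) {
    z <- center_of_mass(frame_coords(traj, f)[ligand, , drop = FALSE], elem)[3]
    lo <- slab_z[f, "lower"]; up <- slab_z[f, "upper"]
    if (z >= lo && z <= up) {
      side <- if (f == 1L) {
        if (abs(z - up) < abs(z - lo)) "upper" else "lower"
      } else {
        zprev <- center_of_mass(frame_coords(traj, f - 1L)[ligand, , drop = FALSE],
                                elem)[3]
        if (zprev > slab_z[f - 1L, "upper"]) "upper" else "lower"
      }
      return(list(leaflet = side, entry_frame = f,
                  entry_time_ns = traj$time[f]))
    }
  }
  list(leaflet = "none", entry_frame = NA_integer_, entry_time_ns = NA_real_)
}

#' Write ligand RMSF series and a binding-site report
#' @param rmsf \code{"ligand_rmsf"}; @param report
#'   \code{"binding_site_report"} or NULL; @param dir output directory.
#' @export
write_ligand_outputs <- function(rmsf, report = NULL, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  for (l in unique(rmsf$ligand))
    utils::write.csv(rmsf[rmsf$ligand == l, c("window_start_ns", "rmsf_A")],
                     file.path(dir, paste0(l, "_rmsf.csv")), row.names = FALSE)
  if (!is.null(report))
    jsonlite::write_json(
      list(cutoff_A = report$cutoff, threshold = report$threshold,
           site = report$site, contact_fractions = report$contact_fractions),
      file.path(dir, "binding_site.json"), auto_unbox = TRUE, digits = NA)
  invisible(dir)
}
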
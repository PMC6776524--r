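#' Synthetic-data generators with known ground truth
#'
#' Every input class the pipeline consumes can be generated with known
#' ground truth: curved bilayers on an analytic Gaussian dome, ensembles of
#' bound and free ligands, C-alpha chains with planted correlated-motion
#' communities, rigid arms under prescribed tilt/twist schedules, ion boxes
#' biased around fixed charges, and assay readouts from known parameters.
#' All generators are seed-deterministic and emit their ground truth
#' alongside the data.
#'
#' @name synthetic_data
NULL

# Build a topology from per-atom vectors; one molecule per unique molno.
.synth_topology <- function(name, elem, resno, resname, chain, molno) {
  topology(data.frame(name = name, elem = elem, resno = resno,
                      resname = resname, chain = chain,
                      stringsAsFactors = FALSE),
           molno = molno)
}

#' Analytic dome surface height
#' @param x,y coordinates (Angstrom); @param z0 plateau height; @param zh
#'   indentation depth (signed); @param sigma Gaussian width; @param center
#'   c(rx, ry).
#' @return surface z.
#' @export
dome_surface <- function(x, y, z0, zh, sigma, center = c(0, 0)) {
  z0 + zh * exp(-((x - center[1])^2 + (y - center[2])^2) / sigma^2)
}

#' Synthetic curved bilayer on a Gaussian dome
#'
#' Two leaflets of 2-atom (head "P", tail "T") pseudo-lipids on jittered
#' lattices. Head z follows the analytic dome surface offset by half the
#' bilayer thickness (+ for the upper leaflet, - for the lower) plus
#' Gaussian noise; tails sit on the membrane-interior side of their heads
#' so leaflet assignment has a known answer. An optional flattening
#' schedule takes zh linearly to 0 over the frames (membrane-tension
#' response). The analytic curvature radius per frame is emitted.
#'
#' Defaults place the dome in the regime of the Piezo1 simulations: box
#' 190.1 x 190.1 x 177.5 Angstrom^3, z0 = 20, zh = -30, sigma = 70
#' (analytic |R| about 81.7 Angstrom, i.e. ~8.2 nm), lattice spacing 8
#' Angstrom (one lipid per (8 A)^2), noise sd 1 Angstrom.
#'
#' @param seed integer seed.
#' @param box c(Lx, Ly, Lz) Angstrom.
#' @param n_frames number of frames.
#' @param z0,zh,sigma,center dome parameters (Angstrom).
#' @param lattice lipid lattice spacing (Angstrom).
#' @param noise_sd Gaussian noise sd on head positions (Angstrom).
#' @param thickness bilayer thickness (Angstrom, > 0).
#' @param flatten if TRUE, zh goes linearly to 0 across the frames.
#' @param dt frame interval (ns).
#' @return list(traj, truth = list(R_A per frame [signed, upper leaflet
#'   convention], zh_t, params, leaflets data.frame(molno, leaflet))).
#' @export
make_dome_membrane <- function(seed = 1L, box = c(190.1, 190.1, 177.5),
                               n_frames = 1L, z0 = 20, zh = -30, sigma = 70,
                               center = c(0, 0), lattice = 8, noise_sd = 1,
                               thickness = 34, flatten = FALSE, dt = 1.2) {
  stopifnot(lattice > 0, lattice <= 10, sigma > 0)
  if (thickness <= 0) stop("leaflets self-intersect: thickness must be > 0")
  if (6 * noise_sd >= thickness)
    stop("leaflets self-intersect: noise sd too large for the thickness")
  with_seed(seed, {
    half <- thickness / 2
    nxl <- floor(box[1] / lattice); nyl <- floor(box[2] / lattice)
    gx <- (seq_len(nxl) - (nxl + 1) / 2) * lattice
    gy <- (seq_len(nyl) - (nyl + 1) / 2) * lattice
    base <- as.matrix(expand.grid(x = gx, y = gy))
    n_lip <- nrow(base)
    jit <- function() base + matrix(stats::runif(2 * n_lip, -lattice / 4,
                                                 lattice / 4), ncol = 2)
    xy_up <- jit(); xy_lo <- jit()
    n_atoms <- 4L * n_lip   # head+tail per lipid, two leaflets
    molno <- rep(seq_len(2L * n_lip), each = 2L)
    name <- rep(c("P", "T"), 2L * n_lip)
    elem <- rep(c("P", "C"), 2L * n_lip)
    resno <- rep(seq_len(2L * n_lip), each = 2L)
    top <- .synth_topology(name, elem, resno, rep("POPC", n_atoms),
                           rep("M", n_atoms), molno)
    zh_t <- if (flatten && n_frames > 1)
      zh * (1 - (seq_len(n_frames) - 1) / (n_frames - 1)) else
        rep(zh, n_frames)
    tail_off <- min(8, half)
    xyz <- matrix(0, n_frames, 3 * n_atoms)
    for (f in seq_len(n_frames)) {
      su <- dome_surface(xy_up[, 1], xy_up[, 2], z0, zh_t[f], sigma, center)
      sl <- dome_surface(xy_lo[, 1], xy_lo[, 2], z0, zh_t[f], sigma, center)
      hz_u <- su + half + stats::rnorm(n_lip, 0, noise_sd)
      hz_l <- sl - half + stats::rnorm(n_lip, 0, noise_sd)
      co <- matrix(0, n_atoms, 3)
      iu <- seq_len(n_lip)
      # upper leaflet: head above tail
      co[4 * (iu - 1) + 1, ] <- cbind(xy_up, hz_u)
      co[4 * (iu - 1) + 2, ] <- cbind(xy_up, hz_u - tail_off)
      # lower leaflet: head below tail
      co[4 * (iu - 1) + 3, ] <- cbind(xy_lo, hz_l)
      co[4 * (iu - 1) + 4, ] <- cbind(xy_lo, hz_l + tail_off)
      xyz[f, ] <- as.numeric(t(co))
    }
    R_t <- vapply(zh_t, function(z)
      curvature_radius(zh = z, sigma = sigma, flat_tol = 1e-12)$R, numeric(1))
    # molecules alternate upper/lower per lattice lipid: odd mols upper
    leaf <- data.frame(molno = seq_len(2L * n_lip),
                       leaflet = ifelse(seq_len(2L * n_lip) %% 2L == 1L,
                                        "upper", "lower"))
    list(traj = trajectory(top, xyz, box = matrix(box, n_frames, 3,
                                                  byrow = TRUE), dt = dt),
         truth = list(R_A = R_t, zh_t = zh_t,
                      params = list(z0 = z0, zh = zh, sigma = sigma,
                                    center = center, thickness = thickness,
                                    noise_sd = noise_sd, lattice = lattice),
                      leaflets = leaf))
  })
}

#' Synthetic ligand ensemble: bound (mean-reverting) and free (diffusive)
#'
#' Bound ligands follow a discrete-time first-order mean-reverting (AR(1))
#' process around fixed pocket sites with stationary standard deviation
#' \code{tether_sd} per axis; free ligands random-walk laterally in the
#' membrane slab with per-frame step sd \code{step_sd}. Three pocket
#' residues (heavy-atom triads) surround the first bound site so contact
#' analysis has a known answer. Optionally one free ligand is scripted to
#' enter the slab from a given side at a given frame.
#'
#' @param seed integer seed.
#' @param n_bound,n_free ligand counts.
#' @param tether_sd stationary sd of bound-ligand displacement (Angstrom).
#' @param step_sd per-frame random-walk step sd of free ligands (Angstrom).
#' @param n_frames frames; @param box c(Lx, Ly, Lz).
#' @param slab_half half-thickness of the membrane slab around z = 0.
#' @param entry NULL, or list(side = "lower"/"upper", frame = integer):
#'   script the last free ligand to enter the slab at that frame.
#' @param phi AR(1) coefficient of the bound process (0 <= phi < 1).
#' @param dt frame interval (ns).
#' @return list(traj, truth = list(labels data.frame(ligand, kind),
#'   pocket_resnos, slab_z [frames x 2], entry)).
#' @export
make_ligand_ensemble <- function(seed = 1L, n_bound = 2L, n_free = 18L,
                                 tether_sd = 0.4, step_sd = 3, n_frames = 120L,
                                 box = c(190.1, 190.1, 177.5), slab_half = 17,
                                 entry = NULL, phi = 0.8, dt = 1.2) {
  if (tether_sd >= step_sd)
    stop("bound tether sd must be smaller than the free step sd")
  with_seed(seed, {
    n_lig <- n_bound + n_free
    # ligand template: 5 heavy atoms (rigid), a flat ring-ish shape
    templ <- matrix(c(0, 0, 0, 1.4, 0, 0, 2.1, 1.2, 0, 1.4, 2.4, 0,
                      0, 2.4, 0), ncol = 3, byrow = TRUE)
    n_la <- nrow(templ)
    # pocket: 3 residues of 3 atoms around the first bound site
    site1 <- c(-30, 10, 0)
    sites <- rbind(site1,
                   if (n_bound > 1)
                     cbind(stats::runif(n_bound - 1, -60, 60),
                           stats::runif(n_bound - 1, -60, 60),
                           stats::runif(n_bound - 1, -8, 8)))
    n_pa <- 3L * 3L
    name <- c(rep(c("CB", "CG1", "CG2"), 3),
              rep(c("C1", "C2", "C3", "C4", "C5"), n_lig))
    elem <- rep("C", n_pa + n_lig * n_la)
    resno <- c(rep(1718L:1720L, each = 3L), rep(100L + seq_len(n_lig),
                                                each = n_la))
    resname <- c(rep("ALA", n_pa), rep("YOD", n_lig * n_la))
    molno <- c(rep(1L, n_pa), rep(1L + seq_len(n_lig), each = n_la))
    top <- .synth_topology(name, elem, resno, resname,
                           c(rep("A", n_pa), rep("L", n_lig * n_la)), molno)
    # each pocket residue's first atom sits 3 Angstrom outward from one
    # ligand atom, so all three residues are in contact at rest
    lig0 <- sweep(templ, 2, site1 - colMeans(templ), "+")
    pocket_xyz <- do.call(rbind, lapply(c(1L, 3L, 5L), function(ai) {
      dir <- lig0[ai, ] - site1
      dir <- if (sum(dir^2) < 1e-9) c(0, 0, 1) else dir / sqrt(sum(dir^2))
      ctr <- lig0[ai, ] + 3 * dir
      rbind(ctr, ctr + c(0.8, 0.4, 0), ctr + c(-0.4, 0.8, 0))
    }))
    eps <- tether_sd * sqrt(1 - phi^2)
    xyz <- matrix(0, n_frames, 3 * (n_pa + n_lig * n_la))
    com <- matrix(0, n_lig, 3)
    for (l in seq_len(n_lig)) {
      com[l, ] <- if (l <= n_bound) sites[l, ] else
        c(stats::runif(1, -box[1] / 2, box[1] / 2),
          stats::runif(1, -box[2] / 2, box[2] / 2),
          stats::runif(1, -slab_half * 0.8, slab_half * 0.8))
    }
    dev <- matrix(stats::rnorm(n_bound * 3, 0, tether_sd), ncol = 3)
    entry_lig <- if (!is.null(entry)) n_lig else 0L
    for (f in seq_len(n_frames)) {
      co <- pocket_xyz
      for (l in seq_len(n_lig)) {
        if (l <= n_bound) {
          if (f > 1)
            dev[l, ] <- phi * dev[l, ] + stats::rnorm(3, 0, eps)
          pos <- sites[l, ] + dev[l, ]
        } else if (l == entry_lig) {
          zout <- if (entry$side == "lower") -slab_half - 25 else slab_half + 25
          pos <- c(com[l, 1:2],
                   if (f < entry$frame) zout else
                     (if (entry$side == "lower") -slab_half + 2
                      else slab_half - 2))
        } else {
          if (f > 1) {
            com[l, 1:2] <- com[l, 1:2] + stats::rnorm(2, 0, step_sd)
            com[l, 3] <- max(min(com[l, 3] + stats::rnorm(1, 0, step_sd / 3),
                                 slab_half * 0.9), -slab_half * 0.9)
          }
          pos <- com[l, ]
        }
        co <- rbind(co, sweep(templ, 2, pos - colMeans(templ), "+"))
      }
      xyz[f, ] <- as.numeric(t(co))
    }
    labels <- data.frame(ligand = paste0("L", seq_len(n_lig)),
                         kind = c(rep("bound", n_bound), rep("free", n_free)))
    if (entry_lig) labels$kind[entry_lig] <- "entry"
    slab_z <- matrix(rep(c(-slab_half, slab_half), each = n_frames),
                     ncol = 2, dimnames = list(NULL, c("lower", "upper")))
    list(traj = trajectory(top, xyz, box = matrix(box, n_frames, 3,
                                                  byrow = TRUE), dt = dt),
         truth = list(labels = labels, pocket_resnos = 1718L:1720L,
                      slab_z = slab_z, entry = entry,
                      tether_sd = tether_sd, step_sd = step_sd))
  })
}

#' Synthetic trajectory with planted correlated-motion communities
#'
#' Each community's residues (single C-alpha pseudo-atoms) share a latent
#' 3-D displacement process of amplitude \code{intra_amp}; an optional
#' shared cross-community component of amplitude \code{inter_coupling} and
#' independent per-residue noise of sd \code{noise} are added. The contact
#' mask connects all within-community pairs plus the configured bridge
#' pairs (first residues of the two communities).
#'
#' @param seed integer seed.
#' @param sizes integer vector of community sizes.
#' @param intra_amp latent community amplitude a (Angstrom); must exceed
#'   \code{noise}.
#' @param inter_coupling shared cross-community amplitude c (Angstrom).
#' @param noise independent per-residue noise sd b (Angstrom).
#' @param n_frames frames; @param dt frame interval (ns).
#' @param bridges list of 2-vectors of community indices to bridge in the
#'   contact mask (default: consecutive communities).
#' @return list(traj, truth = list(partition [integer per residue], mask,
#'   bridges)).
#' @export
make_community_trajectory <- function(seed = 1L, sizes = c(8L, 8L, 8L),
                                      intra_amp = 1.5, inter_coupling = 0,
                                      noise = 0.3, n_frames = 200L, dt = 1.2,
                                      bridges = NULL) {
  if (intra_amp <= noise)
    stop("intra-community amplitude must exceed the noise sd")
  with_seed(seed, {
    k <- length(sizes)
    n <- sum(sizes)
    commun <- rep(seq_len(k), sizes)
    if (is.null(bridges) && k > 1)
      bridges <- lapply(seq_len(k - 1), function(i) c(i, i + 1))
    base <- cbind(40 * commun + 4 * stats::rnorm(n),
                  4 * seq_len(n) %% 20, 4 * stats::rnorm(n))
    top <- .synth_topology(rep("CA", n), rep("C", n), seq_len(n),
                           rep("GLY", n), rep("A", n), rep(1L, n))
    xyz <- matrix(0, n_frames, 3 * n)
    for (f in seq_len(n_frames)) {
      lat <- matrix(stats::rnorm(3 * k, 0, intra_amp), k, 3)
      shared <- stats::rnorm(3, 0, 1)
      co <- base + lat[commun, ] +
        inter_coupling * matrix(shared, n, 3, byrow = TRUE) +
        matrix(stats::rnorm(3 * n, 0, noise), n, 3)
      xyz[f, ] <- as.numeric(t(co))
    }
    ids <- paste("A", seq_len(n), sep = "|")
    mask <- matrix(FALSE, n, n, dimnames = list(ids, ids))
    for (cc in seq_len(k)) {
      i <- which(commun == cc)
      mask[i, i] <- TRUE
    }
    for (br in bridges) {
      i <- which(commun == br[1])[1]; j <- which(commun == br[2])[1]
      mask[i, j] <- mask[j, i] <- TRUE
    }
    diag(mask) <- FALSE
    list(traj = trajectory(top, xyz, dt = dt),
         truth = list(partition = commun, mask = mask, bridges = bridges))
  })
}

#' Synthetic rigid arms under a prescribed tilt/twist schedule
#'
#' Three (or more) rigid rods of C-alpha pseudo-atoms radiate from a hinge
#' at the origin, initially at polar angle \code{theta0} from the membrane
#' normal and azimuths spread evenly. Each frame applies the scheduled
#' tilt (polar-angle increase) and twist (azimuth change) for each arm,
#' plus isotropic Gaussian noise. The analytic tilt/twist series is
#' emitted.
#'
#' @param seed integer seed.
#' @param tilt_max per-arm maximum tilt (degrees), e.g. c(80, 65, 68).
#' @param twist_max per-arm maximum twist (degrees), default 0.
#' @param schedule "linear" (tilt and twist ramp together) or
#'   "twist-tilt-twist" (twist away in the first quarter of frames, tilt
#'   through the middle, twist back up in the last quarter).
#' @param n_atoms atoms per arm (>= 5); @param arm_length Angstrom.
#' @param theta0 initial polar angle (degrees) of every arm.
#' @param noise_sd isotropic positional noise sd (Angstrom).
#' @param n_frames frames; @param dt frame interval (ns).
#' @return list(traj, truth = list(tilt [frames x arms], twist, arms =
#'   per-arm list(proximal, distal atom positions)), arm_defs usable by
#'   \code{\link{tilt_twist_angles}}).
#' @export
make_arm_tilt_trajectory <- function(seed = 1L, tilt_max = c(80, 65, 68),
                                     twist_max = rep(0, length(tilt_max)),
                                     schedule = "linear", n_atoms = 6L,
                                     arm_length = 40, theta0 = 30,
                                     noise_sd = 0, n_frames = 60L, dt = 1.2) {
  stopifnot(n_atoms >= 5)
  n_arms <- length(tilt_max)
  if (length(twist_max) == 1) twist_max <- rep(twist_max, n_arms)
  with_seed(seed, {
    u <- seq(0, 1, length.out = n_frames)
    sched <- switch(schedule,
      linear = list(tilt = u, twist = u),
      `twist-tilt-twist` = list(
        # twisted pose at both ends, untwisted through the tilt sweep
        tilt = pmin(pmax((u - 0.25) / 0.5, 0), 1),
        twist = ifelse(u < 0.25, 1 - u / 0.25,
                       ifelse(u < 0.75, 0, (u - 0.75) / 0.25))),
      stop("unknown schedule: ", schedule))
    radii <- seq(arm_length / n_atoms, arm_length, length.out = n_atoms)
    phi0 <- (seq_len(n_arms) - 1) * 360 / n_arms
    n <- n_arms * n_atoms
    top <- .synth_topology(rep("CA", n), rep("C", n), seq_len(n),
                           rep("GLY", n), rep(LETTERS[rep(seq_len(n_arms),
                                                          each = n_atoms)], 1),
                           rep(1L, n))
    xyz <- matrix(0, n_frames, 3 * n)
    tilt_true <- matrix(0, n_frames, n_arms)
    twist_true <- matrix(0, n_frames, n_arms)
    for (f in seq_len(n_frames)) {
      co <- matrix(0, 0, 3)
      for (a in seq_len(n_arms)) {
        th <- (theta0 + tilt_max[a] * sched$tilt[f]) * pi / 180
        ph <- (phi0[a] + twist_max[a] * sched$twist[f]) * pi / 180
        axis <- c(sin(th) * cos(ph), sin(th) * sin(ph), cos(th))
        pts <- outer(radii, axis)
        if (noise_sd > 0)
          pts <- pts + matrix(stats::rnorm(3 * n_atoms, 0, noise_sd), ncol = 3)
        co <- rbind(co, pts)
        tilt_true[f, a] <- tilt_max[a] * sched$tilt[f]
        twist_true[f, a] <- twist_max[a] * sched$twist[f]
      }
      xyz[f, ] <- as.numeric(t(co))
    }
    arm_defs <- stats::setNames(lapply(seq_len(n_arms), function(a) {
      first <- (a - 1L) * n_atoms
      list(proximal = first + 1:2, distal = first + (n_atoms - 1L):n_atoms)
    }), paste0("arm", seq_len(n_arms)))
    list(traj = trajectory(top, xyz, dt = dt),
         truth = list(tilt = tilt_true, twist = twist_true,
                      theta0 = theta0, schedule = schedule),
         arm_defs = arm_defs)
  })
}

#' Synthetic ion box with fixed negative charge sites
#'
#' Cation positions are drawn with density enhanced by a factor exp(beta)
#' within 5 Angstrom of any charge site (rejection sampling); anions with
#' the reciprocal suppression exp(-beta); uniform elsewhere. Charge sites
#' are emitted as fixed glutamate-like pseudo-atoms (name OE1, resname GLU)
#' so region selections work unchanged.
#'
#' @param seed integer seed.
#' @param box c(Lx, Ly, Lz); @param n_frames frames.
#' @param charge_sites k x 3 matrix of site positions (default 3 sites near
#'   the origin, mimicking a trio of pore-lining glutamates).
#' @param beta coupling strength (dimensionless, >= 0).
#' @param n_cat,n_an ion counts; @param site_cut enhancement radius
#'   (Angstrom, default 5).
#' @param dt frame interval (ns).
#' @return list(traj, truth = list(beta, charge_sites, site_cut)).
#' @export
make_ion_box <- function(seed = 1L, box = c(50, 50, 50), n_frames = 60L,
                         charge_sites = NULL, beta = 1, n_cat = 40L,
                         n_an = 40L, site_cut = 5, dt = 1.2) {
  with_seed(seed, {
    if (is.null(charge_sites))
      charge_sites <- matrix(c(0, 0, 0, 6, 0, 0, 0, 6, 0), ncol = 3,
                             byrow = TRUE)
    k <- nrow(charge_sites)
    n_ion <- n_cat + n_an
    name <- c(rep("OE1", k), rep("K", n_cat), rep("CL", n_an))
    elem <- c(rep("O", k), rep("K", n_cat), rep("CL", n_an))
    resname <- c(rep("GLU", k), rep("K", n_cat), rep("CL", n_an))
    top <- .synth_topology(name, elem, seq_len(k + n_ion), resname,
                           rep("A", k + n_ion),
                           c(rep(1L, k), 1L + seq_len(n_ion)))
    draw <- function(n, bias) {
      # rejection sampling against the max density factor
      out <- matrix(0, 0, 3)
      while (nrow(out) < n) {
        m <- 4L * (n - nrow(out)) + 8L
        p <- cbind(stats::runif(m, -box[1] / 2, box[1] / 2),
                   stats::runif(m, -box[2] / 2, box[2] / 2),
                   stats::runif(m, -box[3] / 2, box[3] / 2))
        d <- pair_dists(p, charge_sites)
        near <- apply(d <= site_cut, 1, any)
        f <- exp(bias * near)
        acc <- stats::runif(m) < f / exp(max(bias, 0))
        out <- rbind(out, p[acc, , drop = FALSE])
      }
      out[seq_len(n), , drop = FALSE]
    }
    xyz <- matrix(0, n_frames, 3 * (k + n_ion))
    for (f in seq_len(n_frames)) {
      co <- rbind(charge_sites, draw(n_cat, beta), draw(n_an, -beta))
      xyz[f, ] <- as.numeric(t(co))
    }
    list(traj = trajectory(top, xyz, box = matrix(box, n_frames, 3,
                                                  byrow = TRUE), dt = dt),
         truth = list(beta = beta, charge_sites = charge_sites,
                      site_cut = site_cut))
  })
}

#' Synthetic assay data: fluorescence traces, pressure-response table and
#' two-group samples
#'
#' The fluorescence trace is flat at \code{F0} before the stimulus and
#' rises exponentially to the plateau \code{F0 * (1 + dff)} after it
#' (known delta F/F0 = dff at zero noise). The pressure-response table is a
#' Boltzmann \eqn{I = scale/(1+exp((P50-P)/k))} plus noise. The two-group
#' samples are normal with a prescribed location shift.
#'
#' @param seed integer seed.
#' @param f0 baseline fluorescence; @param dff true plateau delta F/F0;
#' @param stim_time stimulus time (s, default 10); @param tau rise time
#'   constant (s); @param t_end trace end (s); @param f_noise trace noise sd.
#' @param p50,k,scale Boltzmann parameters; @param pressures mmHg vector;
#' @param i_noise current noise sd.
#' @param n_group group sample size; @param shift group-B location shift;
#' @param group_sd group sd.
#' @return list(trace, boltzmann = data.frame(pressure_mmHg, I),
#'   groups = list(a, b), truth).
#' @export
make_assay_data <- function(seed = 1L, f0 = 100, dff = 1.5, stim_time = 10,
                            tau = 1, t_end = 60, f_noise = 0,
                            p50 = -45, k = -8, scale = 1,
                            pressures = seq(-100, 0, by = 10), i_noise = 0,
                            n_group = 10L, shift = 0, group_sd = 1) {
  with_seed(seed, {
    tt <- seq(0, t_end, by = 0.5)
    F <- ifelse(tt < stim_time, f0,
                f0 * (1 + dff * (1 - exp(-(tt - stim_time) / tau))))
    F <- F + stats::rnorm(length(tt), 0, f_noise)
    trace <- data.frame(time = tt, F = F, roi = "roi1")
    I <- scale / (1 + exp((p50 - pressures) / k)) +
      stats::rnorm(length(pressures), 0, i_noise)
    a <- stats::rnorm(n_group, 0, group_sd)
    b <- stats::rnorm(n_group, shift, group_sd)
    list(trace = trace,
         boltzmann = data.frame(pressure_mmHg = pressures, I = I),
         groups = list(a = a, b = b),
         truth = list(dff = dff, p50 = p50, k = k, scale = scale,
                      shift = shift))
  })
}

#' Ligand concentration from box volume
#'
#' \eqn{c = n / (N_A V)} with V the box volume, reported in mM. The
#' simulation box of 190.1 x 190.1 x 177.5 Angstrom^3 holding 20 ligands
#' corresponds to about 5 mM.
#'
#' @param box c(Lx, Ly, Lz) in Angstrom; @param n molecule count.
#' @return concentration in mM.
#' @export
ligand_concentration <- function(box, n) {
  stopifnot(all(box > 0), n >= 0)
  avogadro <- 6.02214076e23
  vol_l <- prod(box[1:3]) * 1e-27
  n / (avogadro * vol_l) * 1e3
}
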
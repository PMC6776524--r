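# Focused PCA and tilt/twist angle series.

test_that("pure 1-D collective oscillation loads entirely on PC1", {
  top <- toy_topology(4, molno = rep(1, 4))
  base <- matrix(seq_len(4) * 5, 4, 3)
  frames <- lapply(seq(0, 2 * pi, length.out = 20), function(a)
    base + cbind(rep(3 * sin(a), 4), 0, 0))
  tr <- toy_trajectory(frames, top)
  p <- fit_pca(tr, 1:4, superpose = FALSE)
  expect_equal(p$fractions[1], 1, tolerance = 1e-9)
})

test_that("isotropic independent jitter spreads variance across modes", {
  set.seed(6)
  top <- toy_topology(3, molno = rep(1, 3))
  base <- matrix(c(0, 0, 0, 10, 0, 0, 0, 10, 0), 3, byrow = TRUE)
  frames <- lapply(1:10000, function(f) base + matrix(rnorm(9, 0, 0.5), 3))
  tr <- toy_trajectory(frames, top)
  p <- fit_pca(tr, 1:3, superpose = FALSE)
  expect_lte(p$fractions[1], 0.25)
})

test_that("eigenpairs match a brute-force power-iteration oracle", {
  set.seed(7)
  top <- toy_topology(5, molno = rep(1, 5))
  base <- matrix(rnorm(15, 0, 8), 5, 3)
  # anisotropic correlated jitter for a non-trivial spectrum
  M <- matrix(rnorm(15 * 4), 15, 4)
  frames <- lapply(1:300, function(f)
    base + matrix(M %*% rnorm(4) + rnorm(15, 0, 0.1), 5, 3, byrow = FALSE))
  tr <- toy_trajectory(frames, top)
  p <- fit_pca(tr, 1:5, superpose = FALSE)
  X <- sweep(tr$xyz, 2, colMeans(tr$xyz))
  S <- crossprod(X) / (nrow(X) - 1)
  # power iteration with deflation
  v <- rep(1, 15) / sqrt(15)
  for (k in 1:3) {
    v <- rep(1, 15) + seq_len(15) / 15
    v <- v - if (k > 1) p$vectors[, seq_len(k - 1), drop = FALSE] %*%
      crossprod(p$vectors[, seq_len(k - 1), drop = FALSE], v) else 0
    v <- v / sqrt(sum(v^2))
    for (it in 1:2000) {
      v <- S %*% v
      if (k > 1) v <- v - p$vectors[, seq_len(k - 1), drop = FALSE] %*%
          crossprod(p$vectors[, seq_len(k - 1), drop = FALSE], v)
      v <- v / sqrt(sum(v^2))
    }
    lam <- as.numeric(crossprod(v, S %*% v))
    expect_equal(lam, p$values[k], tolerance = 1e-6)
    expect_equal(abs(as.numeric(crossprod(v, p$vectors[, k]))), 1,
                 tolerance = 1e-5)
  }
})

test_that("PCA invariants: orthonormal vectors, fractions, reconstruction", {
  set.seed(8)
  top <- toy_topology(6, molno = rep(1, 6))
  frames <- lapply(1:40, function(f) matrix(rnorm(18, 0, 2), 6, 3))
  tr <- toy_trajectory(frames, top)
  p <- fit_pca(tr, 1:6, superpose = FALSE)
  V <- p$vectors
  expect_lt(max(abs(crossprod(V) - diag(ncol(V)))), 1e-8)
  expect_equal(sum(p$fractions), 1, tolerance = 1e-9)
  expect_true(all(diff(p$values) <= 1e-12))
  expect_true(all(p$values >= 0))
  # full-mode reconstruction of any frame is exact
  x10 <- tr$xyz[10, ] - p$mean
  rec <- as.numeric(V %*% crossprod(V, x10))
  expect_lt(max(abs(rec - x10)), 1e-6)
})

test_that("mode projections: mean maps to zero, mean + 2 v1 maps to (2, 0)", {
  set.seed(9)
  top <- toy_topology(4, molno = rep(1, 4))
  frames <- lapply(1:30, function(f) matrix(rnorm(12, 0, 1.5), 4, 3))
  tr <- toy_trajectory(frames, top)
  p <- fit_pca(tr, 1:4, superpose = FALSE)
  mk <- function(vec) trajectory(top, rbind(tr$xyz[1:2, ], vec))
  pr_mean <- project_onto_modes(mk(p$mean), p, 1:2, interval = 3,
                                superpose = FALSE)
  expect_equal(as.numeric(pr_mean[1, c("PC1", "PC2")]), c(0, 0),
               tolerance = 1e-9)
  pr_v1 <- project_onto_modes(mk(p$mean + 2 * p$vectors[, 1]), p, 1:2,
                              interval = 3, superpose = FALSE)
  expect_equal(as.numeric(pr_v1[1, c("PC1", "PC2")]), c(2, 0),
               tolerance = 1e-9)
  expect_error(project_onto_modes(tr, p, modes = 99), "out of range")
})

test_that("constructed rotations give exact tilt and twist readings", {
  # rigid arm along +x tilted 30 degrees toward the membrane plane
  arm <- outer(1:6, c(1, 0, 0)) * 5 + outer(rep(1, 6), c(0, 0, 10))
  arm0 <- sweep(arm, 2, c(0, 0, 10))        # axis along +x, polar angle 90
  top <- toy_topology(6, molno = rep(1, 6))
  # start the arm at polar angle 45 so both tilt directions are visible
  start <- arm0 %*% t(rot_y(-45))
  tilted <- start %*% t(rot_y(30))          # +30 more polar angle
  zspun <- start %*% t(rot_z(15))           # azimuth only
  tr <- toy_trajectory(list(start, tilted, zspun), top)
  arms <- list(arm1 = list(proximal = 1:2, distal = 5:6))
  tt <- tilt_twist_angles(tr, arms, ref_frame = 1)
  expect_equal(tt$tilt_deg[1], 0, tolerance = 1e-9)
  expect_equal(tt$tilt_deg[2], 30, tolerance = 1e-6)
  expect_equal(tt$twist_deg[2], 0, tolerance = 1e-6)
  expect_equal(tt$tilt_deg[3], 0, tolerance = 1e-6)
  expect_equal(tt$twist_deg[3], 15, tolerance = 1e-6)
})

test_that("tilt/twist: translation invariant, twist equivariant under z spin", {
  at <- make_arm_tilt_trajectory(seed = 3, tilt_max = c(40, 25),
                                 twist_max = c(10, 5), noise_sd = 0.05,
                                 n_frames = 12)
  tt1 <- tilt_twist_angles(at$traj, at$arm_defs)
  shifted <- transform_traj(at$traj, shift = c(30, -12, 7))
  tt2 <- tilt_twist_angles(shifted, at$arm_defs)
  expect_equal(tt1$tilt_deg, tt2$tilt_deg, tolerance = 1e-9)
  expect_equal(tt1$twist_deg, tt2$twist_deg, tolerance = 1e-9)
  # spinning every frame but the reference about z adds to the twist
  spun <- at$traj
  for (f in 2:spun$n_frames)
    spun <- piezotraj:::.set_frame(spun, f,
                                   frame_coords(at$traj, f) %*% t(rot_z(20)))
  tt3 <- tilt_twist_angles(spun, at$arm_defs)
  nonref <- tt3$time_ns > 0
  expect_equal(tt3$twist_deg[nonref] - tt1$twist_deg[nonref],
               rep(20, sum(nonref)), tolerance = 1e-6)
  expect_equal(tt3$tilt_deg, tt1$tilt_deg, tolerance = 1e-9)
})

test_that("scheduled arm maxima are recovered and pure tilt loads on PC1", {
  at <- make_arm_tilt_trajectory(seed = 4, tilt_max = c(80, 65, 68),
                                 noise_sd = 0.1, n_frames = 50)
  tt <- tilt_twist_angles(at$traj, at$arm_defs)
  mx <- tapply(tt$tilt_deg, tt$arm, max)
  expect_equal(as.numeric(mx[c("arm1", "arm2", "arm3")]), c(80, 65, 68),
               tolerance = 1 / 80)   # within 1 degree
  p <- fit_pca(at$traj, "name CA")
  expect_gte(p$fractions[1], 0.9)
})

test_that("twist-tilt-twist schedule traces a U in the PC1/PC2 plane", {
  # arms twist in different directions (a same-sense twist of all arms is a
  # global z-rotation that superposition removes)
  at <- make_arm_tilt_trajectory(seed = 5, tilt_max = c(70, 70, 70),
                                 twist_max = c(25, -25, 25),
                                 schedule = "twist-tilt-twist",
                                 noise_sd = 0.05, n_frames = 80)
  p <- fit_pca(at$traj, "name CA")
  pr <- project_onto_modes(at$traj, p, 1:2)
  n <- nrow(pr)
  third <- floor(n / 3)
  mid <- (third + 1):(n - third)
  # PC1 sweeps with time (tilt); PC2 extrema sit at both ends of the sweep
  expect_gt(cor(pr$PC1, seq_len(n)), 0.9)
  expect_gt(min(pr$PC2[c(1, n)]), max(pr$PC2[mid]))
})
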
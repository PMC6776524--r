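# Membrane curvature pipeline: leaflets, gridding, dome fit, closed form.

test_that("leaflet assignment follows head-above-tail and generator labels", {
  # 4 hand-built lipids: two head-up, two head-down
  top <- topology(data.frame(
    name = rep(c("P", "T"), 4), elem = rep(c("P", "C"), 4),
    resno = rep(1:4, each = 2), resname = "POPC", chain = "M"),
    molno = rep(1:4, each = 2))
  z <- c(10, 0,  12, 2,  -10, 0,  -12, -2)
  co <- cbind(rep(1:4, each = 2), 0, z)
  tr <- toy_trajectory(list(co), top)
  la <- assign_leaflets(tr, 1)
  expect_equal(la$leaflet, c("upper", "upper", "lower", "lower"))

  # all head-up
  z2 <- c(10, 0, 12, 2, 10, 0, 12, 2)
  tr2 <- toy_trajectory(list(cbind(rep(1:4, each = 2), 0, z2)), top)
  expect_true(all(assign_leaflets(tr2, 1)$leaflet == "upper"))

  # generator dome at noise sd 1: >= 99% agreement with planted labels
  d <- make_dome_membrane(seed = 21, n_frames = 1, noise_sd = 1)
  la3 <- assign_leaflets(d$traj, 1)
  m <- merge(la3, d$truth$leaflets, by = "molno")
  expect_gte(mean(m$leaflet.x == m$leaflet.y), 0.99)
})

test_that("missing head or tail atoms are reported by lipid", {
  top <- topology(data.frame(name = c("P", "T", "P"), elem = c("P", "C", "P"),
                             resno = c(1, 1, 2), resname = "POPC",
                             chain = "M"), molno = c(1, 1, 2))
  tr <- toy_trajectory(list(matrix(0, 3, 3)), top)
  expect_error(assign_leaflets(tr, 1), "no tail atom")
})

test_that("periodic tiling produces exactly 9x the points", {
  set.seed(1)
  p <- cbind(runif(17, -20, 20), runif(17, -20, 20), rnorm(17))
  t9 <- tile_points_xy(p, c(40, 40))
  expect_equal(nrow(t9), 9 * 17)
  expect_equal(t9[1:17, ], p)   # originals first
})

test_that("flat plane grids to a constant field before and after smoothing", {
  set.seed(2)
  p <- cbind(runif(400, -30, 30), runif(400, -30, 30), 12.0)
  g0 <- build_height_grid(p, c(60, 60), smooth = FALSE)
  g1 <- build_height_grid(p, c(60, 60), smooth = TRUE)
  expect_lt(max(abs(g0$z - 12)), 1e-9)
  expect_lt(max(abs(g1$z - 12)), 1e-9)
})

test_that("wrap-mode local-mean smoothing preserves the grid mean", {
  d <- make_dome_membrane(seed = 5, n_frames = 1, noise_sd = 1)
  la <- d$truth$leaflets
  pts <- headgroup_com_points(d$traj, 1, la$molno[la$leaflet == "upper"],
                              default_lipid_cfg)
  g0 <- build_height_grid(pts, c(190.1, 190.1), smooth = FALSE)
  g1 <- build_height_grid(pts, c(190.1, 190.1), smooth = TRUE)
  expect_equal(mean(g1$z), mean(g0$z), tolerance = 1e-9)
})

test_that("gridding is equivariant under a constant height offset", {
  set.seed(3)
  p <- cbind(runif(300, -25, 25), runif(300, -25, 25), rnorm(300, 5, 2))
  g0 <- build_height_grid(p, c(50, 50), smooth = TRUE)
  p2 <- p; p2[, 3] <- p2[, 3] + 7.5
  g2 <- build_height_grid(p2, c(50, 50), smooth = TRUE)
  expect_equal(g2$z, g0$z + 7.5, tolerance = 1e-9)
  f0 <- fit_dome(g0); f2 <- fit_dome(g2)
  expect_equal(f2$z0, f0$z0 + 7.5, tolerance = 1e-3)
  expect_equal(f2$zh, f0$zh, tolerance = 1e-3)
})

test_that("degenerate grid inputs are refused", {
  expect_error(build_height_grid(cbind(0, 0:5, 1), c(10, 10)), "collinear")
  expect_error(build_height_grid(cbind(runif(9), runif(9), 1), c(10, 10),
                                 spacing = -1), "positive")
  expect_error(build_height_grid(cbind(1, 1, 1), c(10, 10)), "at least 4")
})

test_that("kernel size rule is ceil(sqrt(nx*ny)/4)", {
  expect_identical(kernel_size_rule(52, 50), 13L)
  expect_identical(kernel_size_rule(4, 4), 1L)
  expect_identical(kernel_size_rule(10, 40), 5L)
})

test_that("dome fit recovers noiseless analytic parameters", {
  gx <- seq(-95, 95, by = 4.6); gy <- seq(-90, 90, by = 4.6)
  z <- outer(gx, gy, function(x, y) dome_surface(x, y, 20, -30, 70))
  grid <- structure(list(z = z, x = gx, y = gy, spacing = 4.6,
                         nx = length(gx), ny = length(gy), smoothed = FALSE,
                         kernel = NA_integer_), class = "headgroup_grid")
  f <- fit_dome(grid)
  expect_equal(f$z0, 20, tolerance = 1e-3)
  expect_equal(f$zh, -30, tolerance = 1e-3)
  expect_equal(f$sigma, 70, tolerance = 1e-3)
  expect_equal(abs(f$rx) + abs(f$ry), 0, tolerance = 1e-2)

  # translation of the frame shifts only the center
  z2 <- outer(gx + 50, gy, function(x, y) dome_surface(x, y, 20, -30, 70,
                                                       center = c(50, 0)))
  grid2 <- grid; grid2$x <- gx + 50; grid2$z <- z2
  f2 <- fit_dome(grid2)
  expect_equal(f2$sigma, f$sigma, tolerance = 1e-6)
  expect_equal(f2$zh, f$zh, tolerance = 1e-6)
  expect_equal(f2$rx, f$rx + 50, tolerance = 1e-2)
})

test_that("flat grids yield the infinite-radius sentinel", {
  gx <- seq(-20, 20, by = 4.6)
  grid <- structure(list(z = matrix(5, length(gx), length(gx)), x = gx,
                         y = gx, spacing = 4.6, nx = length(gx),
                         ny = length(gx), smoothed = FALSE,
                         kernel = NA_integer_), class = "headgroup_grid")
  f <- fit_dome(grid)
  expect_lt(abs(f$zh), 1e-3)
  expect_identical(f$R, Inf)
  expect_identical(curvature_radius(zh = 0, sigma = 50)$R, Inf)
})

test_that("curvature radius follows the closed form exactly", {
  cr <- curvature_radius(zh = -30, sigma = 70)
  expect_equal(cr$d, 60 / 4900, tolerance = 1e-12)
  expect_equal(cr$R, (1 + cr$d^2)^1.5 / cr$d, tolerance = 1e-12)
  expect_equal(cr$R, 81.69, tolerance = 1e-3)   # ~8.2 nm regime
  expect_error(curvature_radius(zh = -30, sigma = -1), "positive")
  # doubling sigma at fixed zh quadruples R when d << 1
  r1 <- curvature_radius(zh = -30, sigma = 70)$R
  r2 <- curvature_radius(zh = -30, sigma = 140)$R
  expect_equal(r2 / r1, 4, tolerance = 1e-3)
})

test_that("closed form matches independent numerical differentiation", {
  # independent oracle: curvature of the surface z(x) along the apex from
  # finite differences, R = (1 + z'^2)^(3/2) / z'' with z' = 0 at the apex
  set.seed(42)
  for (i in 1:25) {
    zh <- runif(1, -60, -10); sig <- runif(1, 40, 120)
    h <- 1e-3
    zxx <- (dome_surface(h, 0, 0, zh, sig) - 2 * dome_surface(0, 0, 0, zh, sig) +
              dome_surface(-h, 0, 0, zh, sig)) / h^2
    cr <- curvature_radius(zh = zh, sigma = sig)
    expect_equal(cr$d, zxx, tolerance = 1e-4)
    expect_equal(cr$R, (1 + zxx^2)^1.5 / zxx, tolerance = 1e-4)
  }
})

test_that("upper and lower leaflet pipelines are independent", {
  d <- make_dome_membrane(seed = 9, n_frames = 1, noise_sd = 0.5)
  la <- d$truth$leaflets
  up <- la$molno[la$leaflet == "upper"]
  lo <- la$molno[la$leaflet == "lower"]
  pts_up <- headgroup_com_points(d$traj, 1, up, default_lipid_cfg)
  # permuting the lower-leaflet molecule order changes nothing upstairs
  pts_up2 <- headgroup_com_points(d$traj, 1, sample(up), default_lipid_cfg)
  f1 <- fit_dome(build_height_grid(pts_up, c(190.1, 190.1), smooth = FALSE))
  f2 <- fit_dome(build_height_grid(pts_up2[order(pts_up2[, 1],
                                                 pts_up2[, 2]), ],
                 c(190.1, 190.1), smooth = FALSE))
  expect_equal(nrow(pts_up), nrow(pts_up2))
  expect_equal(sort(pts_up[, 3]), sort(pts_up2[, 3]), tolerance = 1e-12)
  expect_equal(abs(f1$R), abs(f2$R), tolerance = 1e-6)
})

test_that("static dome gives a constant R series; flattening increases R", {
  d <- make_dome_membrane(seed = 7, n_frames = 5, noise_sd = 0,
                          box = c(190.1, 190.1, 177.5))
  cs <- curvature_timeseries(d$traj, default_lipid_cfg, smooth = FALSE,
                             span = NA)
  for (leaf in c("upper", "lower")) {
    r <- cs$R_A[cs$leaflet == leaf]
    expect_lt(diff(range(r)) / mean(r), 1e-6)
  }
  dfl <- make_dome_membrane(seed = 8, n_frames = 12, noise_sd = 1,
                            flatten = TRUE)
  expect_true(all(diff(abs(dfl$truth$R_A[-12])) > 0))
  cf <- curvature_timeseries(dfl$traj, default_lipid_cfg, smooth = FALSE,
                             span = NA, frames = 1:8)
  up <- cf[cf$leaflet == "upper", ]
  # recovered R tracks the analytic schedule within 5% while the dome is
  # well-formed (later frames approach flatness where R diverges)
  expect_lt(max(abs(up$R_A - abs(dfl$truth$R_A[1:8])) /
                  abs(dfl$truth$R_A[1:8])), 0.05)
})

test_that("LOESS smoother at span 1 approximates the global trend", {
  d <- make_dome_membrane(seed = 13, n_frames = 15, noise_sd = 1,
                          flatten = TRUE)
  cs <- curvature_timeseries(d$traj, default_lipid_cfg, smooth = FALSE,
                             span = 1)
  up <- cs[cs$leaflet == "upper" & is.finite(cs$R_nm), ]
  expect_gte(nrow(up), 10)
  # direct quadratic weighted least squares as the independent comparison
  fitq <- lm(R_nm ~ poly(time_ns, 2), data = up)
  expect_lt(max(abs(up$R_nm_smoothed - fitted(fitq))) /
              diff(range(up$R_nm)), 0.25)
})
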
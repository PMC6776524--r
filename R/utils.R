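# Shared numeric helpers.

.masses <- c(H = 1.008, C = 12.011, N = 14.007, O = 15.999, P = 30.974,
             S = 32.06, K = 39.098, CL = 35.45, NA. = 22.99, MG = 24.305,
             F = 18.998, BR = 79.904, FE = 55.845, ZN = 65.38, X = 12.011)

atomic_mass <- function(elem) {
  m <- .masses[toupper(elem)]
  m[is.na(m)] <- .masses[["X"]]
  unname(m)
}

# Mass-weighted center of an n x 3 coordinate block.
center_of_mass <- function(coords, elem = NULL) {
  if (is.null(elem)) return(colMeans(coords))
  w <- atomic_mass(elem)
  colSums(coords * w) / sum(w)
}

# Minimum-image displacement components for an orthorhombic box.
min_image <- function(d, box_len) d - box_len * round(d / box_len)

# All pairwise minimum-image distances between rows of a (na x 3) and
# b (nb x 3); box NULL means no periodicity. Returns na x nb matrix.
pair_dists <- function(a, b, box = NULL) {
  dx <- outer(a[, 1], b[, 1], "-")
  dy <- outer(a[, 2], b[, 2], "-")
  dz <- outer(a[, 3], b[, 3], "-")
  if (!is.null(box)) {
    dx <- min_image(dx, box[1]); dy <- min_image(dy, box[2])
    dz <- min_image(dz, box[3])
  }
  sqrt(dx^2 + dy^2 + dz^2)
}

# Deterministic RNG scope: runs expr under a seed without disturbing the
# caller's RNG stream.
with_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit({
    if (is.null(old)) rm(".Random.seed", envir = globalenv())
    else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  expr
}

# 3-D rotation matrices about principal axes (degrees).
rot_x <- function(deg) {
  a <- deg * pi / 180
  matrix(c(1, 0, 0, 0, cos(a), sin(a), 0, -sin(a), cos(a)), 3, 3)
}
rot_y <- function(deg) {
  a <- deg * pi / 180
  matrix(c(cos(a), 0, -sin(a), 0, 1, 0, sin(a), 0, cos(a)), 3, 3)
}
rot_z <- function(deg) {
  a <- deg * pi / 180
  matrix(c(cos(a), sin(a), 0, -sin(a), cos(a), 0, 0, 0, 1), 3, 3)
}

# Wrap an angle difference into (-180, 180].
wrap_angle <- function(deg) {
  w <- (deg + 180) %% 360 - 180
  ifelse(w == -180, 180, w)
}
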
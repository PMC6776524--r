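# Correlation networks and Girvan-Newman communities.

traj_from_disp <- function(disp_list, base = NULL) {
  # disp_list: per-frame n x 3 displacement matrices
  n <- nrow(disp_list[[1]])
  if (is.null(base)) base <- matrix(seq_len(n) * 10, n, 3)
  top <- toy_topology(n, molno = rep(1, n))
  toy_trajectory(lapply(disp_list, function(d) base + d), top)
}

test_that("correlations hit +1 for identical and -1 for mirrored motion", {
  set.seed(1)
  disp <- lapply(1:50, function(f) {
    v <- rnorm(3)
    rbind(v, v, -v * c(1, 0, 0))
  })
  # node 3 mirrors node 1 along x only; restrict motion to x for the -1 case
  dispx <- lapply(1:50, function(f) {
    v <- c(rnorm(1), 0, 0)
    rbind(v, v, -v)
  })
  C <- correlation_matrix(traj_from_disp(disp), 1:3)
  expect_equal(C[1, 2], 1, tolerance = 1e-9)
  Cx <- correlation_matrix(traj_from_disp(dispx), 1:3)
  expect_equal(Cx[1, 3], -1, tolerance = 1e-9)
  expect_true(all(abs(C) <= 1 + 1e-12))
  expect_equal(diag(C), rep(1, 3), ignore_attr = TRUE)
})

test_that("independently fluctuating atoms decorrelate at large frame counts", {
  # independent stationary displacement processes: |C| is O(1/sqrt(frames))
  set.seed(2)
  nf <- 10000
  dispi <- lapply(seq_len(nf), function(f) matrix(rnorm(6), 2))
  Ci <- correlation_matrix(traj_from_disp(dispi), 1:2)
  expect_lt(abs(Ci[1, 2]), 0.05)
  # same bound for independent mean-reverting (tethered) motion
  ar <- function() {
    x <- matrix(0, nf, 3)
    for (f in 2:nf) x[f, ] <- 0.8 * x[f - 1, ] + rnorm(3, 0, 0.6)
    x
  }
  a1 <- ar(); a2 <- ar()
  dispa <- lapply(seq_len(nf), function(f) rbind(a1[f, ], a2[f, ]))
  Ca <- correlation_matrix(traj_from_disp(dispa), 1:2)
  expect_lt(abs(Ca[1, 2]), 0.1)
})

test_that("zero-variance nodes are zeroed and flagged", {
  disp <- lapply(1:20, function(f) rbind(rnorm(3), c(0, 0, 0)))
  expect_warning(C <- correlation_matrix(traj_from_disp(disp), 1:2),
                 "zero-variance")
  expect_equal(C[1, 2], 0)
  expect_equal(diag(C), rep(1, 2), ignore_attr = TRUE)
})

test_that("contact mask matches a brute-force frame count on a toy chain", {
  set.seed(4)
  n <- 5
  top <- toy_topology(n, resname = "GLY")
  frames <- lapply(1:12, function(f)
    cbind(seq_len(n) * 4 + rnorm(n, 0, 0.8), 0, 0))
  tr <- toy_trajectory(frames, top)
  mask <- contact_mask(tr, "all", cutoff = 4.5, min_fraction = 0.75)
  for (i in 1:(n - 1)) for (j in (i + 1):n) {
    cnt <- sum(vapply(1:12, function(f) {
      x <- frame_coords(tr, f)
      sqrt(sum((x[i, ] - x[j, ])^2)) <= 4.5
    }, logical(1)))
    expect_identical(unname(mask[i, j]), cnt / 12 >= 0.75)
  }
  expect_false(any(diag(mask)))
  expect_identical(mask, t(mask))
})

test_that("adjacent residues connect, distant ones do not", {
  top <- toy_topology(3)
  frames <- rep(list(cbind(c(0, 3, 40), 0, 0)), 8)
  tr <- toy_trajectory(frames, top)
  mask <- contact_mask(tr, "all")
  expect_true(mask[1, 2])
  expect_false(mask[1, 3])
})

test_that("graph weights are -log|C| on masked pairs only", {
  C <- matrix(c(1, 1, exp(-1), 0.9,
                1, 1, 0.2, 0,
                exp(-1), 0.2, 1, 0.5,
                0.9, 0, 0.5, 1), 4, 4)
  mask <- matrix(TRUE, 4, 4); diag(mask) <- FALSE
  mask[1, 4] <- mask[4, 1] <- FALSE     # masked-out pair
  net <- build_graph(C, mask)
  g <- net$graph
  w <- igraph::E(g)$weight
  ends <- igraph::as_edgelist(g, names = FALSE)
  key <- paste(pmin(ends[, 1], ends[, 2]), pmax(ends[, 1], ends[, 2]))
  expect_equal(w[key == "1 2"], 0)                  # |C| = 1 -> weight 0
  expect_equal(w[key == "1 3"], 1)                  # |C| = 1/e -> weight 1
  expect_false("1 4" %in% key)                      # masked out
  expect_false("2 4" %in% key)                      # |C| = 0 -> no edge
  expect_true(all(w >= 0))
})

test_that("disconnected components come back as separate communities", {
  # two triangles, no connection
  C <- diag(6)
  for (p in list(c(1, 2), c(2, 3), c(1, 3), c(4, 5), c(5, 6), c(4, 6))) {
    C[p[1], p[2]] <- C[p[2], p[1]] <- 0.8
  }
  mask <- (C != 0) & !diag(TRUE, 6)
  part <- detect_communities(build_graph(C, mask))
  expect_equal(part$n_communities, 2)
  expect_equal(length(unique(part$membership[1:3])), 1)
  expect_equal(length(unique(part$membership[4:6])), 1)
})

test_that("barbell partition and modularity match exhaustive enumeration", {
  n <- 8
  C <- diag(n)
  within <- function(i, j) (i <= 4 && j <= 4) || (i >= 5 && j >= 5)
  edges <- NULL; wts <- NULL
  for (i in 1:(n - 1)) for (j in (i + 1):n) {
    if (within(i, j)) { C[i, j] <- C[j, i] <- 0.8 }
  }
  C[4, 5] <- C[5, 4] <- 0.6    # single bridge
  mask <- (abs(C) > 0) & !diag(TRUE, n)
  net <- build_graph(C, mask)
  part <- detect_communities(net)
  expect_equal(part$n_communities, 2)
  expect_equal(length(unique(part$membership[1:4])), 1)
  expect_equal(length(unique(part$membership[5:8])), 1)
  # exhaustive oracle: max modularity over all 4140 partitions of 8 nodes
  el <- igraph::as_edgelist(net$graph, names = FALSE)
  w <- igraph::E(net$graph)$absC
  best <- -Inf
  for (p in all_partitions(n)) {
    memb <- integer(n)
    for (k in seq_along(p)) memb[p[[k]]] <- k
    best <- max(best, modularity_oracle(el, w, memb))
  }
  expect_equal(part$modularity, best, tolerance = 1e-12)
  # first removed edge is the bridge (highest betweenness)
  expect_equal(sort(unlist(part$removal_history[1, ], use.names = FALSE)),
               c("4", "5"))
})

test_that("betweenness ties break deterministically (lowest node pair)", {
  # 4-cycle with equal weights: all edges tie on betweenness
  C <- diag(4)
  for (p in list(c(1, 2), c(2, 3), c(3, 4), c(1, 4)))
    C[p[1], p[2]] <- C[p[2], p[1]] <- 0.5
  mask <- (C != 0) & !diag(TRUE, 4)
  p1 <- detect_communities(build_graph(C, mask))
  p2 <- detect_communities(build_graph(C, mask))
  expect_identical(p1$removal_history, p2$removal_history)
  expect_equal(unlist(p1$removal_history[1, ], use.names = FALSE),
               c("1", "2"))
})

test_that("partition agrees with igraph's edge-betweenness clustering", {
  ct <- make_community_trajectory(seed = 91)
  C <- correlation_matrix(ct$traj, "name CA")
  net <- build_graph(C, ct$truth$mask)
  mine <- detect_communities(net)
  # igraph scores its cut with a different weight convention, so compare
  # the removal dendrogram: the cut at the same community count must agree
  ig <- suppressWarnings(igraph::cluster_edge_betweenness(
    net$graph, weights = igraph::E(net$graph)$weight, modularity = TRUE))
  cut <- igraph::cut_at(ig, no = mine$n_communities)
  expect_equal(adjusted_rand(mine$membership, cut), 1)
})

test_that("returned modularity is at least the single-community modularity", {
  set.seed(5)
  ct <- make_community_trajectory(seed = 5, sizes = c(6L, 6L))
  C <- correlation_matrix(ct$traj, "name CA")
  net <- build_graph(C, ct$truth$mask)
  part <- detect_communities(net)
  one <- rep(1L, length(net$nodes))
  names(one) <- net$nodes
  expect_gte(part$modularity,
             igraph::modularity(net$graph, one,
                                weights = igraph::E(net$graph)$absC))
  expect_true(part$modularity >= -0.5 && part$modularity <= 1)
})

test_that("planted three-community structure is recovered exactly", {
  hits <- vapply(1:10, function(s) {
    ct <- make_community_trajectory(seed = 400 + s)
    C <- correlation_matrix(ct$traj, "name CA")
    part <- detect_communities(build_graph(C, ct$truth$mask))
    adjusted_rand(part$membership, ct$truth$partition) == 1
  }, logical(1))
  expect_gte(mean(hits), 0.9)
})

test_that("inter-community contact summary counts bridges and flags none", {
  ct <- make_community_trajectory(seed = 77, sizes = c(5L, 5L),
                                  bridges = list(c(1, 2)))
  C <- correlation_matrix(ct$traj, "name CA")
  net <- build_graph(C, ct$truth$mask)
  part <- list(membership = stats::setNames(ct$truth$partition, net$nodes))
  class(part) <- "community_partition"
  s <- intercommunity_contact(part, net, 1, 2)
  expect_equal(s$edge_count, 1L)
  expect_false(s$no_contact)
  expect_gt(s$total_absC, 0)
  # with the bridge masked out there is no direct contact
  ct0 <- make_community_trajectory(seed = 77, sizes = c(5L, 5L),
                                   bridges = list())
  C0 <- correlation_matrix(ct0$traj, "name CA")
  net0 <- build_graph(C0, ct0$truth$mask)
  s0 <- intercommunity_contact(part, net0, 1, 2)
  expect_true(s0$no_contact)
  expect_equal(s0$edge_count, 0L)
  expect_error(intercommunity_contact(part, net, 1, 99), "unknown")
})
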
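#' Dynamical residue networks and Girvan-Newman communities
#'
#' Residues are nodes; the Pearson correlation of C-alpha displacements
#' weights the edges of a contact-masked graph (edge length -log|C|, so
#' tightly coupled residues are "close"). Communities are found by
#' iteratively removing the edge of highest weighted betweenness and
#' keeping the partition of maximal modularity along the removal sequence.
#'
#' @name dynamic_network
NULL

#' Pearson correlation matrix of C-alpha motions
#'
#' \eqn{C_{ij} = <dr_i . dr_j> / sqrt(<dr_i^2><dr_j^2>)} with dr the
#' displacement from the time-mean position (scalar dot-product convention).
#' Zero-variance nodes get zero off-diagonal entries and are flagged via the
#' \code{"zero_variance"} attribute.
#'
#' @param traj superposed trajectory.
#' @param sel C-alpha selection (string or positions), default "calpha".
#' @return symmetric matrix with unit diagonal; rownames are
#'   chain|resno node ids.
#' @export
correlation_matrix <- function(traj, sel = "calpha") {
  if (is.character(sel)) sel <- select_atoms(traj$top, sel)
  if (traj$n_frames < 10) stop("need >= 10 frames for correlations")
  n <- length(sel)
  if (!n) stop("empty selection")
  cols <- as.integer(t(outer(3 * (sel - 1), 1:3, "+")))
  X <- traj$xyz[, cols, drop = FALSE]
  X <- sweep(X, 2, colMeans(X))
  # inner products of 3-D displacement vectors, summed over frames
  G <- matrix(0, n, n)
  for (d in 1:3) {
    Xd <- X[, seq(d, 3 * n, by = 3), drop = FALSE]
    G <- G + crossprod(Xd)
  }
  v <- diag(G)
  zero <- v < 1e-12
  den <- sqrt(outer(pmax(v, 1e-300), pmax(v, 1e-300)))
  C <- G / den
  C[zero, ] <- 0; C[, zero] <- 0
  diag(C) <- 1
  C <- pmin(pmax(C, -1), 1)
  at <- traj$top$atoms
  ids <- paste(at$chain[sel], at$resno[sel], sep = "|")
  dimnames(C) <- list(ids, ids)
  attr(C, "zero_variance") <- ids[zero]
  if (any(zero)) warning(sum(zero), " zero-variance node(s) zeroed")
  C
}

#' Residue-residue contact mask
#'
#' TRUE iff any heavy-atom pair of the two residues is within \code{cutoff}
#' for at least \code{min_fraction} of the interval frames.
#'
#' @param traj trajectory.
#' @param residue_sel selection defining the residues (default "protein").
#' @param cutoff Angstrom (default 4.5); @param min_fraction default 0.75.
#' @param interval frame indices (default all).
#' @return symmetric logical matrix, FALSE diagonal; node ids as dimnames.
#' @export
contact_mask <- function(traj, residue_sel = "protein", cutoff = 4.5,
                         min_fraction = 0.75, interval = NULL) {
  if (is.null(interval)) interval <- seq_len(traj$n_frames)
  if (!length(interval)) stop("empty interval")
  at <- traj$top$atoms
  cand <- select_atoms(traj$top, residue_sel)
  cand <- cand[at$elem[cand] != "H"]
  key <- paste(at$chain[cand], at$resno[cand], sep = "|")
  ids <- unique(key)
  n <- length(ids)
  counts <- matrix(0L, n, n, dimnames = list(ids, ids))
  grp <- match(key, ids)
  for (f in interval) {
    xyz <- frame_coords(traj, f)[cand, , drop = FALSE]
    d <- pair_dists(xyz, xyz)
    close <- d <= cutoff
    # residue-block any(): TRUE if any atom pair within cutoff
    blk <- rowsum(close + 0, grp) > 0
    blk <- t(rowsum(t(blk) + 0, grp)) > 0
    counts <- counts + blk
  }
  mask <- counts / length(interval) >= min_fraction
  diag(mask) <- FALSE
  mask
}

#' Build the correlation network graph
#'
#' Edges exist only where the contact mask is TRUE and |C| > 0; edge weight
#' (treated as a path length) is -log|C|, so |C| = 1 gives weight 0
#' (tightest coupling). |C| = 0 pairs get no edge (infinite length).
#'
#' @param C correlation matrix; @param mask contact mask (same shape).
#' @return object of class \code{"correlation_network"}: list(graph
#'   [igraph, undirected, attrs weight = -log|C|, absC], C, mask, nodes).
#' @export
build_graph <- function(C, mask) {
  stopifnot(all(dim(C) == dim(mask)))
  n <- nrow(C)
  ids <- rownames(C)
  if (is.null(ids)) ids <- as.character(seq_len(n))
  A <- abs(C)
  keep <- mask & A > 0
  keep[lower.tri(keep, diag = TRUE)] <- FALSE
  ij <- which(keep, arr.ind = TRUE)
  g <- igraph::make_empty_graph(n = n, directed = FALSE)
  g <- igraph::set_vertex_attr(g, "name", value = ids)
  if (nrow(ij)) {
    g <- igraph::add_edges(g, as.integer(t(ij)))
    igraph::E(g)$absC <- A[ij]
    igraph::E(g)$weight <- -log(A[ij])
  }
  structure(list(graph = g, C = C, mask = mask, nodes = ids),
            class = "correlation_network")
}

#' Girvan-Newman community detection
#'
#' Iteratively removes the edge of highest betweenness (shortest paths use
#' the -log|C| lengths; ties broken by lexicographically lowest node-index
#' pair for reproducibility) and returns the partition along the removal
#' sequence that maximizes weighted modularity Q. Q is computed on |C|
#' coupling-strength weights.
#'
#' @param net \code{"correlation_network"}.
#' @return object of class \code{"community_partition"}: list(membership
#'   [named integer], modularity, removal_history data.frame(from, to),
#'   n_communities).
#' @export
detect_communities <- function(net) {
  g0 <- net$graph
  if (igraph::vcount(g0) == 0) stop("empty graph")
  g <- g0
  best_Q <- -Inf
  best_memb <- igraph::components(g)$membership
  hist_from <- character(); hist_to <- character()
  Q_of <- function(memb) .weighted_modularity(g0, memb)
  Q0 <- Q_of(best_memb)
  if (Q0 > best_Q) { best_Q <- Q0 }
  while (igraph::ecount(g) > 0) {
    eb <- igraph::edge_betweenness(g, weights = igraph::E(g)$weight)
    mx <- max(eb)
    cand <- which(eb >= mx - 1e-12)
    if (length(cand) > 1) {
      el <- igraph::as_edgelist(g, names = FALSE)[cand, , drop = FALSE]
      el <- t(apply(el, 1, sort))
      cand <- cand[order(el[, 1], el[, 2])][1]
    }
    ends <- igraph::ends(g, cand, names = TRUE)
    hist_from <- c(hist_from, ends[1]); hist_to <- c(hist_to, ends[2])
    g <- igraph::delete_edges(g, cand)
    memb <- igraph::components(g)$membership
    Q <- Q_of(memb)
    if (Q > best_Q + 1e-12) { best_Q <- Q; best_memb <- memb }
  }
  structure(list(membership = best_memb, modularity = best_Q,
                 removal_history = data.frame(from = hist_from, to = hist_to),
                 n_communities = length(unique(best_memb))),
            class = "community_partition")
}

# Weighted modularity of a membership vector on graph g's absC weights.
.weighted_modularity <- function(g, memb) {
  if (igraph::ecount(g) == 0) return(0)
  igraph::modularity(g, memb, weights = igraph::E(g)$absC)
}

#' @export
print.community_partition <- function(x, ...) {
  cat(sprintf("Community partition: %d communities, Q = %.4f\n",
              x$n_communities, x$modularity))
  print(table(x$membership))
  invisible(x)
}

#' Inter-community contact summary
#'
#' Aggregates the network edges spanning two communities: edge count, total
#' |C| and mean edge length. Zero spanning edges raises the
#' "no direct contact" flag.
#'
#' @param partition \code{"community_partition"}.
#' @param net \code{"correlation_network"}.
#' @param a,b community labels (as in \code{partition$membership}).
#' @return list(edge_count, total_absC, mean_weight, no_contact).
#' @export
intercommunity_contact <- function(partition, net, a, b) {
  memb <- partition$membership
  if (!(a %in% memb)) stop("unknown community label: ", a)
  if (!(b %in% memb)) stop("unknown community label: ", b)
  g <- net$graph
  el <- igraph::as_edgelist(g, names = TRUE)
  if (nrow(el) == 0)
    return(list(edge_count = 0L, total_absC = 0, mean_weight = NA_real_,
                no_contact = TRUE))
  ma <- memb[el[, 1]]; mb <- memb[el[, 2]]
  span <- (ma == a & mb == b) | (ma == b & mb == a)
  if (!any(span))
    return(list(edge_count = 0L, total_absC = 0, mean_weight = NA_real_,
                no_contact = TRUE))
  list(edge_count = sum(span),
       total_absC = sum(igraph::E(g)$absC[span]),
       mean_weight = mean(igraph::E(g)$weight[span]),
       no_contact = FALSE)
}

#' Write network outputs (correlation CSV, GraphML, edge list, partition)
#' @param net \code{"correlation_network"}; @param partition optional
#'   \code{"community_partition"}; @param dir output directory.
#' @export
write_network_outputs <- function(net, partition = NULL, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  utils::write.csv(as.data.frame(net$C), file.path(dir, "correlation.csv"))
  igraph::write_graph(net$graph, file.path(dir, "network.graphml"),
                      format = "graphml")
  el <- igraph::as_edgelist(net$graph, names = TRUE)
  ed <- data.frame(from = el[, 1], to = el[, 2],
                   weight = igraph::E(net$graph)$weight,
                   absC = igraph::E(net$graph)$absC)
  utils::write.table(ed, file.path(dir, "edges.tsv"), sep = "\t",
                     row.names = FALSE, quote = FALSE)
  if (!is.null(partition))
    utils::write.table(
      data.frame(residue = names(partition$membership),
                 community = as.integer(partition$membership)),
      file.path(dir, "communities.tsv"), sep = "\t", row.names = FALSE,
      quote = FALSE)
  invisible(dir)
}
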
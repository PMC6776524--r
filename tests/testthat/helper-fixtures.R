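# Shared fixture builders. Everything is constructed in code; no stored
# binary data.

# Minimal topology of n single-atom CA "residues", one molecule each.
toy_topology <- function(n, chain = "A", resname = "GLY", name = "CA",
                         elem = "C", molno = seq_len(n)) {
  piezotraj::topology(
    data.frame(name = rep(name, n), elem = rep(elem, n), resno = seq_len(n),
               resname = rep(resname, n), chain = rep(chain, n),
               stringsAsFactors = FALSE),
    molno = molno)
}

toy_trajectory <- function(coords_list, top, box = NULL) {
  xyz <- do.call(rbind, lapply(coords_list, function(m) as.numeric(t(m))))
  piezotraj::trajectory(top, xyz, box = box)
}

# Write a small hand-built PDB file; rows is a data.frame with columns
# serial, name, resname, chain, resno, x, y, z; ter_after gives row indices
# after which TER records are emitted.
write_toy_pdb <- function(path, rows, ter_after = integer()) {
  con <- file(path, "w")
  on.exit(close(con))
  for (i in seq_len(nrow(rows))) {
    r <- rows[i, ]
    writeLines(sprintf(
      "ATOM  %5d  %-3s %-4s%1s%4d    %8.3f%8.3f%8.3f  1.00  0.00           %1s",
      r$serial, r$name, r$resname, r$chain, r$resno, r$x, r$y, r$z,
      substr(r$name, 1, 1)), con)
    if (i %in% ter_after) writeLines("TER", con)
  }
  writeLines("END", con)
  path
}

default_lipid_cfg <- list(resname = "POPC", head_names = "P", tail_name = "T")

# Rigid transform applied to every frame of a trajectory.
transform_traj <- function(traj, R = diag(3), shift = c(0, 0, 0)) {
  for (f in seq_len(traj$n_frames)) {
    x <- piezotraj::frame_coords(traj, f)
    traj$xyz[f, ] <- as.numeric(t(sweep(x %*% t(R), 2, shift, "+")))
  }
  traj
}

# Exhaustive set-partition enumeration (Bell-number search) for small n.
all_partitions <- function(n) {
  if (n == 1) return(list(list(1L)))
  out <- list()
  for (p in all_partitions(n - 1)) {
    for (k in seq_along(p)) {
      q <- p; q[[k]] <- c(q[[k]], n)
      out[[length(out) + 1L]] <- q
    }
    out[[length(out) + 1L]] <- c(p, list(n))
  }
  out
}

# Weighted modularity of a membership vector over an edge list (matches the
# package's |C|-weight convention but computed independently of igraph).
modularity_oracle <- function(edges, w, memb) {
  W <- sum(w)
  n <- length(memb)
  deg <- numeric(n)
  for (e in seq_len(nrow(edges))) {
    deg[edges[e, 1]] <- deg[edges[e, 1]] + w[e]
    deg[edges[e, 2]] <- deg[edges[e, 2]] + w[e]
  }
  q <- 0
  for (e in seq_len(nrow(edges)))
    if (memb[edges[e, 1]] == memb[edges[e, 2]]) q <- q + w[e] / W
  for (cc in unique(memb)) {
    s <- sum(deg[memb == cc])
    q <- q - (s / (2 * W))^2
  }
  q
}

# Adjusted Rand index between two labelings.
adjusted_rand <- function(a, b) {
  tab <- table(a, b)
  comb2 <- function(x) x * (x - 1) / 2
  sij <- sum(comb2(tab))
  si <- sum(comb2(rowSums(tab)))
  sj <- sum(comb2(colSums(tab)))
  n <- comb2(sum(tab))
  expd <- si * sj / n
  (sij - expd) / ((si + sj) / 2 - expd)
}
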
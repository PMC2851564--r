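# Shared fixtures and independent oracles. Oracles deliberately use a
# different route than the implementation (dense linear solves, MASS::ginv,
# exhaustive enumeration, simulation).

## coarse model straight from coordinates (heavy atoms = the node itself)
toy_from_coords <- function(xyz, chain = rep("A", nrow(xyz)), b = NULL,
                            heavy = NULL) {
  n <- nrow(xyz)
  aakdyn:::new_coarse_model(
    label = sprintf("%s:GLY%d", chain, seq_len(n)),
    kind = rep("residue", n), chain = chain, resno = seq_len(n),
    resid = rep("GLY", n), xyz = xyz,
    b = b %||% rep(NA_real_, n),
    heavy = heavy %||% lapply(seq_len(n), function(i) xyz[i, , drop = FALSE]))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

## the canonical 3-bead path fixture
p3_model <- function(spacing = 1) {
  suppressWarnings(make_toy("chain", n = 3, spacing = spacing))
}

p3_affinity <- function() {
  affinity_from_matrix(matrix(c(0, 1, 0, 1, 0, 1, 0, 1, 0), 3))
}

## a deformation object with a prescribed 3M displacement (identity mapping)
fake_deformation <- function(dr, n) {
  structure(list(dr = dr, mapping = alignment_map(seq_len(n), seq_len(n)),
                 rmsd = sqrt(mean(matrix(dr, ncol = 3, byrow = TRUE)^2) * 3),
                 m = n),
            class = "deformation")
}

## hand-built PDB record (fixed-width); record = "ATOM" or "HETATM"
pdb_line <- function(serial, name, resid, chain, resno, x, y, z,
                     occ = 1, b = 0, element = "C", altloc = " ",
                     record = "ATOM") {
  name_fmt <- if (nchar(name) < 4) sprintf(" %-3s", name) else name
  sprintf("%-6s%5d %4s%1s%3s %1s%4d    %8.3f%8.3f%8.3f%6.2f%6.2f          %2s",
          record, serial, name_fmt, altloc, resid, chain, resno,
          x, y, z, occ, b, element)
}

## two chains x three GLY residues, CA + CB heavy atoms each
two_chain_pdb <- function() {
  lines <- character(0)
  serial <- 0
  for (ch in c("A", "B")) {
    xoff <- if (ch == "A") 0 else 20
    for (r in 1:3) {
      serial <- serial + 1
      lines <- c(lines, pdb_line(serial, "CA", "GLY", ch, r,
                                 xoff + 3.8 * r, 0, 0, b = 10 + r))
      serial <- serial + 1
      lines <- c(lines, pdb_line(serial, "CB", "GLY", ch, r,
                                 xoff + 3.8 * r, 1.5, 0, b = 12 + r))
    }
  }
  c(lines, "END")
}

## ---- oracles -------------------------------------------------------------

## hitting times to `target` by first-step analysis: h = 1 + P h on the
## non-target nodes, P the row-stochastic walk matrix
first_step_hitting <- function(amat, target) {
  d <- rowSums(amat)
  p <- amat / d
  n <- nrow(amat)
  keep <- setdiff(seq_len(n), target)
  h <- rep(0, n)
  h[keep] <- solve(diag(length(keep)) - p[keep, keep, drop = FALSE],
                   rep(1, length(keep)))
  h
}

## full hitting-time matrix H[j, i] from the first-step oracle
first_step_hitting_matrix <- function(amat) {
  n <- nrow(amat)
  h <- matrix(0, n, n)
  for (j in seq_len(n)) h[j, ] <- first_step_hitting(amat, j)
  h
}

## effective resistance via an SVD pseudoinverse independent of the package
effective_resistance <- function(amat, i, j) {
  lap <- diag(rowSums(amat)) - amat
  g <- MASS::ginv(lap)
  g[i, i] + g[j, j] - 2 * g[i, j]
}

## random connected weighted graph: ring backbone plus random chords
random_connected_affinity <- function(n, seed) {
  set.seed(seed)
  amat <- matrix(0, n, n)
  ring <- cbind(seq_len(n), c(seq_len(n)[-1], 1))
  chords <- cbind(sample(n, n, replace = TRUE), sample(n, n, replace = TRUE))
  edges <- rbind(ring, chords)
  edges <- edges[edges[, 1] != edges[, 2], , drop = FALSE]
  w <- stats::runif(nrow(edges), 0.5, 2)
  for (k in seq_len(nrow(edges))) {
    amat[edges[k, 1], edges[k, 2]] <- w[k]
    amat[edges[k, 2], edges[k, 1]] <- w[k]
  }
  amat
}

## minimum -log-likelihood path cost by exhaustive simple-path enumeration
enumerate_path_cost <- function(mmat, from, to) {
  n <- nrow(mmat)
  g <- igraph::graph_from_adjacency_matrix(mmat > 0, mode = "directed")
  paths <- igraph::all_simple_paths(g, from = from, to = to, mode = "out")
  costs <- vapply(paths, function(p) {
    p <- as.integer(p)
    steps <- cbind(p[-length(p)], p[-1])
    -sum(log(mmat[cbind(steps[, 2], steps[, 1])]))
  }, 0)
  min(costs)
}
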
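#' Build the residue-interaction affinity matrix
#'
#' The affinity between nodes i and j is \code{a_ij = N_ij / sqrt(N_i N_j)},
#' where \code{N_ij} counts heavy-atom pairs (one atom from each node)
#' within the threshold distance and \code{N_i}, \code{N_j} are the heavy-
#' atom counts of the two nodes. Sequence neighbours receive no special
#' treatment; ligand nodes participate exactly like residue nodes.
#'
#' @param model A \code{coarse_model} with heavy atoms on every node.
#' @param threshold Atom-atom contact distance in Angstrom (default 4).
#' @return An \code{affinity_model}: list with \code{A} (N x N symmetric,
#'   zero diagonal), \code{d} (degrees, column sums), \code{laplacian}
#'   (\code{D - A}), \code{threshold}, \code{labels}.
#' @export
build_affinity <- function(model, threshold = 4) {
  stopifnot(inherits(model, "coarse_model"))
  n <- model$N
  n_at <- vapply(model$heavy, nrow, 0L)
  if (any(n_at == 0)) stopf("node(s) without heavy atoms")
  ## search radius: node pairs whose representatives are farther apart than
  ## threshold + both nodes' atom extents cannot share an atom contact
  extent <- vapply(seq_len(n), function(i) {
    sqrt(max(rowSums(sweep(model$heavy[[i]], 2, model$xyz[i, ])^2)))
  }, 0)
  d2 <- dist2_xy(model$xyz, model$xyz)
  reach <- outer(extent, extent, "+") + threshold
  cand <- which(d2 <= reach^2 & upper.tri(d2), arr.ind = TRUE)
  amat <- matrix(0, n, n)
  t2 <- threshold^2
  for (p in seq_len(nrow(cand))) {
    i <- cand[p, 1]; j <- cand[p, 2]
    nij <- sum(dist2_xy(model$heavy[[i]], model$heavy[[j]]) <= t2)
    if (nij > 0) {
      a <- nij / sqrt(n_at[i] * n_at[j])
      amat[i, j] <- a
      amat[j, i] <- a
    }
  }
  d <- colSums(amat)
  if (any(d == 0)) {
    stopf("isolated node(s) with zero total affinity: %s",
          paste(model$label[d == 0], collapse = ", "))
  }
  structure(list(A = amat, d = d, laplacian = diag(d) - amat,
                 threshold = threshold, labels = model$label),
            class = "affinity_model")
}

#' Affinity model from an explicit affinity matrix
#'
#' Convenience constructor for graph-level tests and examples.
#'
#' @param amat Symmetric non-negative matrix with zero diagonal.
#' @param labels Optional node labels.
#' @return An \code{affinity_model}.
#' @export
affinity_from_matrix <- function(amat, labels = NULL) {
  if (!isSymmetric(unname(amat))) stopf("affinity matrix must be symmetric")
  if (any(amat < 0) || any(diag(amat) != 0)) {
    stopf("affinities must be non-negative with zero diagonal")
  }
  d <- colSums(amat)
  if (any(d == 0)) stopf("isolated node(s) with zero total affinity")
  structure(list(A = unname(amat), d = d, laplacian = diag(d) - unname(amat),
                 threshold = NA_real_,
                 labels = labels %||% as.character(seq_len(nrow(amat)))),
            class = "affinity_model")
}

#' Markov transition matrix of the communication model
#'
#' \code{m_ij = a_ij / d_j}: the conditional probability that a signal at
#' node j moves to node i in one step. Columns sum to one.
#'
#' @param affinity An \code{affinity_model}.
#' @return A \code{markov_model}: list with \code{M} (column-stochastic),
#'   \code{d}, \code{labels}.
#' @export
build_markov <- function(affinity) {
  stopifnot(inherits(affinity, "affinity_model"))
  if (any(affinity$d == 0)) stopf("zero-degree column")
  m <- sweep(affinity$A, 2, affinity$d, "/")
  structure(list(M = m, d = affinity$d, labels = affinity$labels),
            class = "markov_model")
}

#' Hitting and commute times of the communication model
#'
#' Expected number of random-walk steps \code{H(j|i)} to first reach node j
#' from node i, computed spectrally from the pseudoinverse \code{G} of the
#' weighted Laplacian \code{D - A} (zero mode excluded):
#' \code{H(j|i) = sum_k d_k (G_ki - G_ji - G_kj + G_jj)}. The commute time
#' \code{tau_ij = H(j|i) + H(i|j) = Vol (G_ii + G_jj - 2 G_ij)} with
#' \code{Vol = sum_k d_k}, i.e. communication is slow between nodes whose
#' inter-node distance fluctuations are large.
#'
#' @param affinity An \code{affinity_model} with a connected graph.
#' @return A \code{communication} object: list with \code{H} (\code{H[j, i]}
#'   = hitting time from i to j), \code{tau}, \code{Gplus}, \code{d},
#'   \code{vol}, \code{labels}.
#' @export
hitting_times <- function(affinity) {
  stopifnot(inherits(affinity, "affinity_model"))
  comp <- graph_components(affinity$A > 0)
  if (max(comp) > 1) {
    stopf("disconnected affinity graph: %d components of sizes %s",
          max(comp), paste(table(comp), collapse = ", "))
  }
  g <- pinv_sym(affinity$laplacian)
  d <- affinity$d
  vol <- sum(d)
  s <- as.vector(d %*% g)                    # s_i = sum_k d_k G_ki
  n <- length(d)
  h <- vol * (outer(diag(g), rep(1, n)) - g) +
    outer(rep(1, n), s) - outer(s, rep(1, n))
  h[abs(h) < 1e-9] <- 0
  structure(list(H = h, tau = h + t(h), Gplus = g, d = d, vol = vol,
                 labels = affinity$labels),
            class = "communication")
}

#' Mean hitting-time profile per node
#'
#' Receiver convention (default): for node i, the average over source nodes
#' of the time to hit i; minima mark the most efficient signal receivers.
#' The broadcast convention averages instead over targets reached from i.
#' The self term (zero) is included in the average, matching the
#' \code{(1/N) sum_j} normalization.
#'
#' @param comm A \code{communication} object.
#' @param convention \code{"receiver"} or \code{"broadcast"}.
#' @return Numeric vector of length N.
#' @export
mean_receive_time <- function(comm, convention = c("receiver", "broadcast")) {
  convention <- match.arg(convention)
  switch(convention,
         receiver = rowMeans(comm$H),
         broadcast = colMeans(comm$H))
}

#' Self/cross decomposition of hitting times and state difference maps
#'
#' Splits \code{H(j|i)} into the "self" part contributed by the target
#' node's own mean-square fluctuation, \code{Vol * G_jj} (the terms of the
#' spectral form containing the diagonal element \code{G_jj}), and the
#' "cross" remainder carried by cross-correlations. With two states over the
#' same node labelling, also returns the cross-part difference map
#' (state A minus state B), highlighting couplings gained or lost between
#' states (e.g. open versus closed+ligands).
#'
#' @param comm_a A \code{communication} object.
#' @param comm_b Optional second state over the same (mapped) nodes.
#' @param mapping Optional \code{\link{alignment_map}} when the two states
#'   resolve different node sets.
#' @return List with \code{self}, \code{cross} (for state A; \code{self +
#'   cross == H} exactly) and, given \code{comm_b}, \code{difference}.
#' @export
decompose_hitting <- function(comm_a, comm_b = NULL, mapping = NULL) {
  n <- length(comm_a$d)
  self_a <- comm_a$vol * outer(diag(comm_a$Gplus), rep(1, n))
  out <- list(self = self_a, cross = comm_a$H - self_a)
  if (!is.null(comm_b)) {
    nb <- length(comm_b$d)
    if (is.null(mapping)) {
      if (nb != n) stopf("states have different node counts; provide a mapping")
      mapping <- alignment_map(seq_len(n), seq_len(nb))
    }
    self_b <- comm_b$vol * outer(diag(comm_b$Gplus), rep(1, nb))
    cross_b <- comm_b$H - self_b
    ia <- mapping[, "a"]; ib <- mapping[, "b"]
    out$difference <- out$cross[ia, ia] - cross_b[ib, ib]
  }
  out
}

#' Maximum-likelihood communication pathway (Dijkstra)
#'
#' Edge "distance" for the step j -> i is \code{-log(m_ij)}, so the
#' minimum-cost path is the maximum-likelihood signalling route. Among
#' equal-cost paths the one with fewer hops is preferred.
#'
#' @param markov A \code{markov_model}.
#' @param from,to Source and target node indices (or labels).
#' @return List with \code{path} (node indices), \code{labels},
#'   \code{cost} (= -log of the product of step probabilities).
#' @export
shortest_path <- function(markov, from, to) {
  stopifnot(inherits(markov, "markov_model"))
  n <- nrow(markov$M)
  resolve <- function(x) {
    if (is.character(x)) {
      i <- match(x, markov$labels)
      if (is.na(i)) stopf("unknown node label: %s", x)
      i
    } else as.integer(x)
  }
  from <- resolve(from); to <- resolve(to)
  if (from == to) stopf("source and target must differ")
  edges <- which(markov$M > 0, arr.ind = TRUE)   # row i <- col j
  w <- -log(markov$M[edges])
  ## tiny per-hop penalty breaks cost ties in favour of fewer hops without
  ## perturbing strict cost comparisons
  eps <- 1e-12 * max(1, max(w))
  g <- igraph::graph_from_edgelist(cbind(edges[, 2], edges[, 1]),
                                   directed = TRUE)
  g <- igraph::add_vertices(g, max(0, n - igraph::vcount(g)))
  sp <- suppressWarnings(
    igraph::shortest_paths(g, from = from, to = to, weights = w + eps,
                           mode = "out"))
  path <- as.integer(sp$vpath[[1]])
  if (length(path) == 0) stopf("target unreachable from source")
  steps <- cbind(path[-length(path)], path[-1])
  cost <- -sum(log(markov$M[cbind(steps[, 2], steps[, 1])]))
  list(path = path, labels = markov$labels[path], cost = cost)
}

#' Mean and spread of hitting times between two node groups
#'
#' Aggregates \code{H(j|i)} over all ordered pairs with i in one group and
#' j in the other, in both directions (the "average path length" between two
#' protein regions and its standard deviation).
#'
#' @param comm A \code{communication} object.
#' @param group_a,group_b Disjoint non-empty node index vectors.
#' @return List with \code{mean}, \code{sd}, \code{n_pairs}.
#' @export
group_path_stats <- function(comm, group_a, group_b) {
  group_a <- as.integer(group_a); group_b <- as.integer(group_b)
  if (length(group_a) == 0 || length(group_b) == 0) stopf("empty group")
  if (length(intersect(group_a, group_b)) > 0) {
    stopf("groups must be disjoint")
  }
  vals <- c(comm$H[group_b, group_a], comm$H[group_a, group_b])
  list(mean = mean(vals),
       sd = if (length(vals) > 1) stats::sd(vals) else 0,
       n_pairs = length(vals))
}
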
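#' Build the GNM Kirchhoff (connectivity) matrix
#'
#' Two nodes are connected when their representative coordinates lie within
#' the cutoff (closed interval, distances exactly at the cutoff included).
#' Off-diagonal entries of contacting pairs are \code{-gamma}; the diagonal
#' is fixed by zero row sums.
#'
#' @param model A \code{coarse_model}.
#' @param cutoff Contact cutoff in Angstrom (default 10, the community
#'   standard for C-alpha Gaussian networks).
#' @param gamma Uniform spring constant (dimensionless scale, default 1).
#' @return A \code{kirchhoff} object: list with \code{mat} (N x N),
#'   \code{cutoff}, \code{gamma}, \code{labels}, \code{chain},
#'   \code{connected} flag.
#' @export
build_kirchhoff <- function(model, cutoff = 10, gamma = 1) {
  stopifnot(inherits(model, "coarse_model"), model$N >= 2)
  d2 <- dist2_xy(model$xyz, model$xyz)
  adj <- (d2 <= cutoff^2)
  diag(adj) <- FALSE
  gmat <- -gamma * adj
  diag(gmat) <- -rowSums(gmat)
  comp <- graph_components(adj)
  if (max(comp) > 1) {
    warning(sprintf("contact network is disconnected (%d components)",
                    max(comp)))
  }
  structure(list(mat = gmat, cutoff = cutoff, gamma = gamma,
                 labels = model$label, chain = model$chain,
                 components = comp, connected = max(comp) == 1),
            class = "kirchhoff")
}

graph_components <- function(adj) {
  g <- igraph::graph_from_adjacency_matrix(adj != 0, mode = "undirected")
  igraph::components(g)$membership
}

#' Build the ANM Hessian matrix
#'
#' For each contacting pair the 3x3 off-diagonal super-element is
#' \code{-gamma} times the outer product of the unit inter-node vector with
#' itself; diagonal super-elements are minus the sum of the row's
#' off-diagonal blocks, so every block row sums to zero.
#'
#' @param model A \code{coarse_model}.
#' @param cutoff Contact cutoff in Angstrom (default 15, the community
#'   standard for C-alpha anisotropic networks).
#' @param gamma Uniform spring constant (default 1).
#' @return A \code{hessian} object: list with \code{mat} (3N x 3N),
#'   \code{cutoff}, \code{gamma}, \code{labels}, \code{N}.
#' @export
build_hessian <- function(model, cutoff = 15, gamma = 1) {
  stopifnot(inherits(model, "coarse_model"), model$N >= 2)
  n <- model$N
  xyz <- model$xyz
  d2 <- dist2_xy(xyz, xyz)
  adj <- (d2 <= cutoff^2)
  diag(adj) <- FALSE
  pairs <- which(adj & upper.tri(adj), arr.ind = TRUE)
  h <- matrix(0, 3 * n, 3 * n)
  for (p in seq_len(nrow(pairs))) {
    i <- pairs[p, 1]; j <- pairs[p, 2]
    rij <- xyz[j, ] - xyz[i, ]
    dd <- sum(rij^2)
    if (dd == 0) {
      stopf("coincident nodes within a contact: %s and %s",
            model$label[i], model$label[j])
    }
    blk <- -gamma * tcrossprod(rij) / dd
    ii <- (3 * i - 2):(3 * i); jj <- (3 * j - 2):(3 * j)
    h[ii, jj] <- blk
    h[jj, ii] <- blk
    h[ii, ii] <- h[ii, ii] - blk
    h[jj, jj] <- h[jj, jj] - blk
  }
  structure(list(mat = h, cutoff = cutoff, gamma = gamma,
                 labels = model$label, chain = model$chain, N = n),
            class = "hessian")
}

#' Eigen-decompose a network matrix into a mode set
#'
#' Full spectrum in ascending order. Numerically zero modes are counted with
#' the relative threshold \code{lambda <= 1e-10 * lambda_max}; internal
#' ("non-zero") modes are numbered from 1 starting at the first mode above
#' the threshold, so "mode 1" is always the slowest internal mode.
#'
#' A connected GNM network must yield exactly one zero mode; more than one
#' raises a disconnected-network error listing the components. A
#' non-degenerate ANM network yields six zero modes (rigid translations and
#' rotations); any other count triggers a degeneracy warning.
#'
#' @param x A \code{kirchhoff} or \code{hessian} object (or a plain
#'   symmetric matrix, treated generically).
#' @param c Scale constant multiplying all fluctuation quantities
#'   (\code{3 k_B T / gamma}; default 1, so profiles are relative).
#' @return A \code{mode_set}: list with \code{values} (all eigenvalues,
#'   ascending), \code{vectors} (columns matching \code{values}),
#'   \code{n_zero}, \code{kind} ("gnm", "anm" or "generic"), \code{c},
#'   \code{N} nodes, \code{labels}.
#' @export
decompose_modes <- function(x, c = 1) {
  kind <- if (inherits(x, "kirchhoff")) "gnm"
          else if (inherits(x, "hessian")) "anm" else "generic"
  mat <- if (is.matrix(x)) x else x$mat
  if (!isSymmetric(unname(mat), tol = 1e-8)) stopf("matrix is not symmetric")
  e <- eigen(mat, symmetric = TRUE)
  values <- rev(e$values)
  vectors <- e$vectors[, rev(seq_along(e$values)), drop = FALSE]
  lmax <- max(abs(values))
  n_zero <- sum(values <= 1e-10 * lmax)
  if (kind == "gnm" && n_zero > 1) {
    comp <- x$components %||% graph_components(mat != 0 & !diag(nrow(mat)))
    sizes <- table(comp)
    stopf("disconnected network: %d components of sizes %s",
          length(sizes), paste(sizes, collapse = ", "))
  }
  if (kind == "anm" && n_zero != 6) {
    warning(sprintf(
      "degenerate ANM geometry: %d zero modes instead of 6", n_zero))
  }
  labels <- if (is.matrix(x)) NULL else x$labels
  nnode <- if (kind == "anm") x$N else nrow(mat)
  structure(list(values = values, vectors = vectors, n_zero = n_zero,
                 kind = kind, c = c, N = nnode, labels = labels),
            class = "mode_set")
}

#' @export
print.mode_set <- function(x, ...) {
  cat(sprintf("mode_set (%s): %d modes, %d zero; slowest internal lambda = %.4g\n",
              x$kind, length(x$values), x$n_zero, mode_values(x)[1]))
  invisible(x)
}

#' Number of internal (non-zero) modes in a mode set
#' @param modes A \code{mode_set}.
#' @export
n_modes <- function(modes) length(modes$values) - modes$n_zero

#' Eigenvalues of the internal modes (ascending)
#' @param modes A \code{mode_set}.
#' @export
mode_values <- function(modes) modes$values[-seq_len(modes$n_zero)]

#' Eigenvector of internal mode k (unit length)
#' @param modes A \code{mode_set}.
#' @param k Internal mode index (1 = slowest non-zero mode).
#' @export
mode_vector <- function(modes, k) {
  check_mode_index(modes, k)
  modes$vectors[, modes$n_zero + k]
}

check_mode_index <- function(modes, k) {
  if (any(k < 1) || any(k > n_modes(modes))) {
    stopf("mode index out of range: internal modes are 1..%d (zero modes excluded)",
          n_modes(modes))
  }
  invisible(k)
}

#' Per-node mean-square fluctuation profile
#'
#' GNM: \code{MSF_i = c * sum_k (u_k)_i^2 / lambda_k}. ANM: the x, y, z
#' components of each node are summed. The sum runs over all internal modes
#' unless \code{subset} restricts it (per-mode mobility profiles).
#'
#' @param modes A \code{mode_set}.
#' @param subset Optional internal mode indices to restrict the sum to.
#' @return Numeric vector of length N.
#' @export
msf_profile <- function(modes, subset = NULL) {
  ks <- subset %||% seq_len(n_modes(modes))
  check_mode_index(modes, ks)
  cols <- modes$n_zero + ks
  u2 <- modes$vectors[, cols, drop = FALSE]^2
  w <- modes$c / modes$values[cols]
  per_dof <- as.vector(u2 %*% w)
  if (modes$kind == "anm" || length(per_dof) == 3 * modes$N) {
    per_dof <- rowSums(matrix(per_dof, ncol = 3, byrow = TRUE))
  }
  per_dof
}

#' Cross-correlations of residue fluctuations
#'
#' \code{C_ij = c * sum_k (u_k)_i (u_k)_j / lambda_k} over internal modes
#' (for the ANM the 3x3 block trace is taken per node pair). The diagonal
#' equals \code{\link{msf_profile}}; for the GNM each row sums to zero.
#'
#' @param modes A \code{mode_set}.
#' @param subset Optional internal mode indices.
#' @return N x N symmetric matrix.
#' @export
cross_correlations <- function(modes, subset = NULL) {
  ks <- subset %||% seq_len(n_modes(modes))
  check_mode_index(modes, ks)
  cols <- modes$n_zero + ks
  v <- modes$vectors[, cols, drop = FALSE]
  cc <- modes$c * (v %*% (t(v) / modes$values[cols]))
  if (modes$kind == "anm" || nrow(cc) == 3 * modes$N) {
    n <- nrow(cc) / 3
    ix <- 3 * seq_len(n) - 2
    cc <- cc[ix, ix] + cc[ix + 1, ix + 1] + cc[ix + 2, ix + 2]
  }
  (cc + t(cc)) / 2
}

#' Predict B-factors from a fluctuation profile
#'
#' \code{B_i = (8 pi^2 / 3) MSF_i}, uniformly rescaled so the mean of the
#' prediction matches the mean of the experimental B-factors; the Pearson
#' correlation is scale-invariant.
#'
#' @param msf Per-node mean-square fluctuations.
#' @param experimental Per-node experimental B-factors (NAs dropped
#'   pairwise).
#' @return List with \code{predicted} (rescaled B-factors, NA where the
#'   experimental value was NA it is still predicted), and \code{r}
#'   (Pearson correlation over nodes with experimental values).
#' @export
predict_bfactors <- function(msf, experimental) {
  if (length(msf) != length(experimental)) stopf("length mismatch")
  ok <- is.finite(experimental)
  if (sum(ok) < 3) stopf("need at least 3 nodes with experimental B-factors")
  if (stats::sd(experimental[ok]) == 0) {
    stopf("correlation undefined: experimental B-factors are all equal")
  }
  raw <- (8 * pi^2 / 3) * msf
  pred <- raw * mean(experimental[ok]) / mean(raw[ok])
  list(predicted = pred, r = stats::cor(pred[ok], experimental[ok]))
}

#' Locate hinge sites in a slow GNM mode shape
#'
#' A hinge separates regions moving in opposite directions: the shape
#' changes sign between sequence neighbours within a chain. The reported
#' node is the one of the pair with the smaller absolute amplitude (tie:
#' lower index). Additionally, local minima of the squared shape that fall
#' below a low-mobility quantile are reported (mechanically constrained
#' sites without a strict sign flip).
#'
#' @param shape Signed per-node mode shape (a GNM eigenvector).
#' @param chain Optional per-node chain identifiers; sign changes are only
#'   considered between neighbours on the same chain.
#' @param min_quantile Mobility quantile below which squared-shape local
#'   minima are also reported (default 0.1).
#' @return Sorted integer vector of hinge node indices (possibly empty).
#' @export
find_hinges <- function(shape, chain = NULL, min_quantile = 0.1) {
  n <- length(shape)
  if (is.null(chain)) chain <- rep("A", n)
  hinges <- integer(0)
  for (i in seq_len(n - 1)) {
    if (chain[i] != chain[i + 1]) next
    if (shape[i] == 0) { hinges <- c(hinges, i); next }
    if (shape[i] * shape[i + 1] < 0) {
      pick <- if (abs(shape[i + 1]) < abs(shape[i])) i + 1L else i
      hinges <- c(hinges, pick)
    }
  }
  if (shape[n] == 0) hinges <- c(hinges, n)
  ## strict interior minima of the squared shape in the low-mobility tail:
  ## constrained sites even without an exact sign flip
  sq <- shape^2
  thr <- stats::quantile(sq, min_quantile, names = FALSE)
  for (i in seq_len(n)[-c(1, n)]) {
    if (chain[i - 1] != chain[i] || chain[i + 1] != chain[i]) next
    if (sq[i] < sq[i - 1] && sq[i] < sq[i + 1] && sq[i] <= thr) {
      hinges <- c(hinges, i)
    }
  }
  sort(unique(hinges))
}

#' Map GNM modes onto ANM modes by fluctuation shape
#'
#' Entry (k, l) is the Pearson correlation between the per-node squared
#' shape of GNM mode k and the per-node squared displacement of ANM mode l.
#' A one-to-one correspondence is not expected; the map shows which ANM
#' modes carry each GNM mode's mobility pattern.
#'
#' @param gnm,anm \code{mode_set}s over the same nodes.
#' @param n_modes_map Number of slow modes from each set to compare.
#' @return \code{n_modes_map} x \code{n_modes_map} correlation matrix
#'   (rows: GNM modes; columns: ANM modes).
#' @export
map_gnm_to_anm <- function(gnm, anm, n_modes_map = 3) {
  if (gnm$N != anm$N) stopf("mode sets are over different node counts")
  check_mode_index(gnm, n_modes_map); check_mode_index(anm, n_modes_map)
  per_node_sq <- function(modes, k) {
    u <- mode_vector(modes, k)
    if (length(u) == 3 * modes$N) rowSums(as_xyz(u)^2) else u^2
  }
  gp <- sapply(seq_len(n_modes_map), function(k) per_node_sq(gnm, k))
  ap <- sapply(seq_len(n_modes_map), function(l) per_node_sq(anm, l))
  m <- stats::cor(gp, ap)
  dimnames(m) <- list(paste0("gnm", seq_len(n_modes_map)),
                      paste0("anm", seq_len(n_modes_map)))
  m
}
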
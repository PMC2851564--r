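#' Schur complement of a symmetric matrix onto an index set
#'
#' \code{M_eff = M_SS - M_SE M_EE^+ M_ES}, with the environment block
#' inverted by pseudoinverse (rigid modes of the isolated environment
#' projected out with the same relative zero threshold used in mode
#' decomposition).
#'
#' @param mat Symmetric matrix.
#' @param idx Row/column indices of the retained (subsystem) block.
#' @param rel_tol Relative eigenvalue threshold for the pseudoinverse.
#' @return The effective matrix on \code{idx} (symmetrized).
#' @export
schur_complement <- function(mat, idx, rel_tol = 1e-10) {
  n <- nrow(mat)
  idx <- sort(unique(as.integer(idx)))
  if (length(idx) == 0 || length(idx) == n) {
    stopf("subsystem must be a proper non-empty subset (use plain NMA otherwise)")
  }
  env <- setdiff(seq_len(n), idx)
  mss <- mat[idx, idx, drop = FALSE]
  mse <- mat[idx, env, drop = FALSE]
  mee <- mat[env, env, drop = FALSE]
  if (all(mse == 0)) return(mss)
  eff <- mss - mse %*% pinv_sym(mee, rel_tol) %*% t(mse)
  (eff + t(eff)) / 2
}

#' Effective Hessian of a subsystem coupled to its environment
#'
#' Partitions the ANM Hessian into subsystem (S) and environment (E) blocks
#' and folds the elastic coupling to the environment into the subsystem via
#' the Schur complement \code{H_eff = H_SS - H_SE H_EE^+ H_ES}. Normal mode
#' analysis of \code{H_eff} describes the subsystem's collective dynamics in
#' the presence of the environment.
#'
#' @param hessian A \code{hessian} object (or plain symmetric matrix with
#'   one degree of freedom per node).
#' @param subsystem Node indices of the subsystem.
#' @return A \code{subsystem_partition}: list with \code{S}, \code{E},
#'   \code{Hss}, \code{Hse}, \code{Hee}, \code{Heff}, \code{labels}.
#' @export
effective_hessian <- function(hessian, subsystem) {
  subsystem <- sort(unique(as.integer(subsystem)))
  if (inherits(hessian, "hessian")) {
    n <- hessian$N
    mat <- hessian$mat
    expand <- dof_idx
    labels <- hessian$labels
  } else {
    mat <- hessian
    n <- nrow(mat)
    expand <- identity
    labels <- NULL
  }
  if (length(subsystem) == 0 || length(subsystem) == n) {
    stopf("subsystem must be a proper non-empty subset (use plain NMA otherwise)")
  }
  env <- setdiff(seq_len(n), subsystem)
  si <- expand(subsystem); ei <- expand(env)
  heff <- schur_complement(mat, si)
  structure(list(S = subsystem, E = env,
                 Hss = mat[si, si, drop = FALSE],
                 Hse = mat[si, ei, drop = FALSE],
                 Hee = mat[ei, ei, drop = FALSE],
                 Heff = heff,
                 labels = if (!is.null(labels)) labels[subsystem] else NULL),
            class = "subsystem_partition")
}

#' Normal modes of a subsystem in its coupled environment
#'
#' Eigen-decomposition of the effective Hessian. Rigid motions of the
#' subsystem remain zero-energy (the relaxed environment follows them), so
#' the null space persists; the zero-mode count is reported rather than
#' checked against 6, and internal mode numbering starts beyond it.
#'
#' @param partition A \code{subsystem_partition}.
#' @param c Fluctuation scale constant (default 1).
#' @return A \code{mode_set} over the subsystem nodes (kind
#'   \code{"subsystem"}).
#' @export
subsystem_modes <- function(partition, c = 1) {
  stopifnot(inherits(partition, "subsystem_partition"))
  ms <- decompose_modes(partition$Heff, c = c)
  ms$kind <- "subsystem"
  ms$N <- length(partition$S)
  ms$labels <- partition$labels
  ms
}

#' Correlation cosines between two sets of modes over aligned nodes
#'
#' Entry (k, l) is the absolute cosine between mode k of A and mode l of B,
#' each restricted to the mapped nodes and re-normalized. The structures
#' must be pre-superposed over the mapped C-alphas (directions are not
#' comparable otherwise); see \code{\link{superpose}}.
#'
#' @param modes_a,modes_b \code{mode_set}s with 3 degrees of freedom per
#'   node (ANM or subsystem modes).
#' @param mapping An \code{\link{alignment_map}} from A's to B's node space.
#' @param n Number of slow modes from each set to compare.
#' @return n x n matrix of absolute cosines in [0, 1].
#' @export
mode_correlation_matrix <- function(modes_a, modes_b, mapping = NULL, n = 10) {
  if (is.null(mapping)) {
    if (modes_a$N != modes_b$N) stopf("node counts differ; provide a mapping")
    mapping <- alignment_map(seq_len(modes_a$N), seq_len(modes_b$N))
  }
  if (nrow(mapping) < 3) stopf("mapping too small: need at least 3 pairs")
  check_mode_index(modes_a, n); check_mode_index(modes_b, n)
  ua <- sapply(seq_len(n), function(k) {
    u <- mode_vector(modes_a, k)[dof_idx(mapping[, "a"])]
    u / vnorm(u)
  })
  ub <- sapply(seq_len(n), function(l) {
    u <- mode_vector(modes_b, l)[dof_idx(mapping[, "b"])]
    u / vnorm(u)
  })
  m <- abs(crossprod(ua, ub))
  dimnames(m) <- list(paste0("a", seq_len(n)), paste0("b", seq_len(n)))
  m
}

#' Family slow-mode conservation summary
#'
#' For each of the first m modes of the reference set, the cumulative
#' overlap over the first m modes of the other set is
#' \code{CO_k = sqrt(min(1, sum_l cos^2(k, l)))}; the summary is the mean of
#' these, expressed as a percentage. Order-insensitive: permuting identical
#' modes still scores 100.
#'
#' @param cmat A correlation-cosine matrix from
#'   \code{\link{mode_correlation_matrix}}.
#' @param m Number of modes averaged (default 10).
#' @return Percentage in [0, 100].
#' @export
family_overlap_summary <- function(cmat, m = 10) {
  if (nrow(cmat) < m || ncol(cmat) < m) {
    stopf("correlation matrix smaller than m = %d", m)
  }
  co <- sqrt(pmin(1, rowSums(cmat[seq_len(m), seq_len(m), drop = FALSE]^2)))
  100 * mean(co)
}
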
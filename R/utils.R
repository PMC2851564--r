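# internal numerical helpers shared across modules

# symmetric pseudoinverse with a relative zero threshold on eigenvalues;
# returns the inverse on the non-null subspace
pinv_sym <- function(mat, rel_tol = 1e-10) {
  e <- eigen(mat, symmetric = TRUE)
  lmax <- max(abs(e$values))
  if (lmax == 0) return(matrix(0, nrow(mat), ncol(mat)))
  keep <- e$values > rel_tol * lmax
  if (!any(keep)) return(matrix(0, nrow(mat), ncol(mat)))
  v <- e$vectors[, keep, drop = FALSE]
  v %*% (t(v) / e$values[keep])
}

# squared Euclidean distance matrix between rows of a and rows of b
dist2_xy <- function(a, b) {
  an <- rowSums(a^2)
  bn <- rowSums(b^2)
  d2 <- outer(an, bn, "+") - 2 * tcrossprod(a, b)
  d2[d2 < 0] <- 0
  d2
}

vnorm <- function(x) sqrt(sum(x^2))

`%||%` <- function(a, b) if (is.null(a)) b else a

stopf <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)

# flatten an N x 3 coordinate matrix to the 3N vector (x1,y1,z1,x2,...)
as_flat <- function(xyz) as.vector(t(xyz))
as_xyz <- function(flat) matrix(flat, ncol = 3, byrow = TRUE)

# expand node indices to their 3 Cartesian degrees of freedom
dof_idx <- function(nodes) as.vector(rbind(3 * nodes - 2, 3 * nodes - 1, 3 * nodes))
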
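coords_of <- function(x) {
  if (inherits(x, "coarse_model")) x$xyz
  else if (is.matrix(x) && ncol(x) == 3) x
  else stopf("expected a coarse_model or an N x 3 coordinate matrix")
}

#' Least-squares rigid superposition (Kabsch)
#'
#' Finds the proper rotation (determinant +1) and translation that move the
#' mapped nodes of B onto those of A with minimum RMSD, eliminating the
#' external (rigid-body) degrees of freedom.
#'
#' @param a,b \code{coarse_model}s or N x 3 coordinate matrices.
#' @param mapping Optional \code{\link{alignment_map}} (default: identity,
#'   requiring equal node counts).
#' @return List with \code{rotation} (3 x 3), \code{translation} (length 3;
#'   fitted B = B \%*\% rotation + translation), \code{rmsd} over mapped
#'   pairs, and \code{b_fitted} (all of B transformed).
#' @export
superpose <- function(a, b, mapping = NULL) {
  xa <- coords_of(a); xb <- coords_of(b)
  if (is.null(mapping)) {
    if (nrow(xa) != nrow(xb)) stopf("node counts differ; provide a mapping")
    mapping <- alignment_map(seq_len(nrow(xa)), seq_len(nrow(xb)))
  }
  pa <- xa[mapping[, "a"], , drop = FALSE]
  pb <- xb[mapping[, "b"], , drop = FALSE]
  m <- nrow(pa)
  if (m < 3) stopf("superposition needs at least 3 mapped pairs, got %d", m)
  ca <- colMeans(pa); cb <- colMeans(pb)
  pa0 <- sweep(pa, 2, ca); pb0 <- sweep(pb, 2, cb)
  sv <- svd(crossprod(pb0, pa0))
  if (sv$d[2] <= 1e-10 * max(sv$d[1], .Machine$double.eps)) {
    stopf("mapped nodes are (near-)collinear; superposition is ill-defined")
  }
  s <- diag(c(1, 1, sign(det(tcrossprod(sv$v, sv$u)))))
  rot <- sv$u %*% s %*% t(sv$v)
  trans <- ca - as.vector(cb %*% rot)
  fitted_pb <- pb %*% rot + matrix(trans, m, 3, byrow = TRUE)
  rmsd <- sqrt(mean(rowSums((fitted_pb - pa)^2)))
  b_fitted <- xb %*% rot + matrix(trans, nrow(xb), 3, byrow = TRUE)
  list(rotation = rot, translation = trans, rmsd = rmsd, b_fitted = b_fitted)
}

#' Deformation vector between two conformations
#'
#' The 3M difference vector between mapped C-alpha coordinates of the
#' "closed" form, after optimal superposition onto the "open" form, and the
#' open form itself. \code{|dr| / sqrt(M)} equals the superposition RMSD.
#'
#' @param open,closed \code{coarse_model}s or coordinate matrices.
#' @param mapping Optional \code{\link{alignment_map}}.
#' @return A \code{deformation} object: list with \code{dr} (3M vector,
#'   Angstrom, node-major x/y/z order), \code{mapping}, \code{rmsd},
#'   \code{m}.
#' @export
deformation_vector <- function(open, closed, mapping = NULL) {
  xo <- coords_of(open); xc <- coords_of(closed)
  if (is.null(mapping)) {
    if (nrow(xo) != nrow(xc)) stopf("node counts differ; provide a mapping")
    mapping <- alignment_map(seq_len(nrow(xo)), seq_len(nrow(xc)))
  }
  fit <- superpose(xo, xc, mapping)
  dr <- fit$b_fitted[mapping[, "b"], , drop = FALSE] -
    xo[mapping[, "a"], , drop = FALSE]
  structure(list(dr = as_flat(dr), mapping = mapping, rmsd = fit$rmsd,
                 m = nrow(mapping)),
            class = "deformation")
}

#' @export
print.deformation <- function(x, ...) {
  cat(sprintf("deformation: %d mapped nodes, rmsd %.3f A\n", x$m, x$rmsd))
  invisible(x)
}

## slice a 3N mode vector to the mapped nodes (A side) and renormalize
slice_mode <- function(u, mapping, n_nodes) {
  if (length(u) == 3 * nrow(mapping)) return(u / vnorm(u))
  if (length(u) != 3 * n_nodes) stopf("mode length does not match model")
  us <- u[dof_idx(mapping[, "a"])]
  nu <- vnorm(us)
  if (nu == 0) stopf("mode vanishes on the mapped nodes")
  us / nu
}

#' Correlation cosine between an ANM mode and a deformation
#'
#' \code{cos = (u . dr) / (|u| |dr|)}, sign preserved. When the deformation
#' covers fewer nodes than the mode set (partial alignment), the mode vector
#' is restricted to the mapped nodes and re-normalized.
#'
#' @param modes An ANM \code{mode_set} (of the model on the A side of the
#'   deformation's mapping).
#' @param deformation A \code{\link{deformation_vector}} result.
#' @param k Internal mode index (or vector of indices).
#' @return Numeric vector of signed cosines, one per requested mode.
#' @export
mode_overlap <- function(modes, deformation, k) {
  stopifnot(inherits(deformation, "deformation"))
  nd <- vnorm(deformation$dr)
  if (nd < 1e-10) stopf("no conformational change: deformation vector is zero")
  check_mode_index(modes, k)
  vapply(k, function(kk) {
    u <- slice_mode(mode_vector(modes, kk), deformation$mapping, modes$N)
    sum(u * deformation$dr) / nd
  }, 0)
}

#' Cumulative overlap of the first m modes with a deformation
#'
#' \code{CO(m) = sqrt(sum_{k<=m} cos^2(u_k, dr))}: the fraction of the
#' observed conformational change captured by the m slowest internal modes.
#' Non-decreasing in m; equals 1 over the complete internal mode basis when
#' the mapping covers all nodes.
#'
#' @param modes An ANM \code{mode_set}.
#' @param deformation A \code{\link{deformation_vector}} result.
#' @param m Number of slow modes (default: all internal modes).
#' @return \code{CO(m)} (scalar). Use \code{\link{overlap_profile}} for the
#'   whole curve.
#' @export
cumulative_overlap <- function(modes, deformation, m = n_modes(modes)) {
  co <- overlap_profile(modes, deformation, m)$co
  co[length(co)]
}

#' Per-mode and cumulative overlap table
#'
#' @inheritParams cumulative_overlap
#' @param m Number of slow modes to tabulate.
#' @return Data frame with columns \code{mode}, \code{cosine},
#'   \code{co} (cumulative overlap up to that mode).
#' @export
overlap_profile <- function(modes, deformation, m = 20) {
  if (m < 1 || m > n_modes(modes)) {
    stopf("m must be between 1 and the number of internal modes (%d)",
          n_modes(modes))
  }
  cosines <- mode_overlap(modes, deformation, seq_len(m))
  data.frame(mode = seq_len(m), cosine = cosines,
             co = sqrt(cumsum(cosines^2)))
}

#' Generate conformer pairs along a normal mode
#'
#' \code{R(+/-) = R0 +/- s_k lambda_k^(-1/2) u_k}: the two excursions of a
#' harmonic mode at amplitude \code{s_k}. By default the amplitude is chosen
#' so the C-alpha RMSD from the input structure is \code{rmsd} Angstrom.
#' When an all-atom source structure is supplied, every atom of a residue is
#' displaced rigidly by that residue's C-alpha mode component (no
#' minimization is performed).
#'
#' @param model A \code{coarse_model}.
#' @param modes An ANM \code{mode_set} of the model.
#' @param k Internal mode index.
#' @param amplitude Mode amplitude \code{s_k}; overrides \code{rmsd}.
#' @param rmsd Target C-alpha RMSD from the input (default 1 Angstrom).
#' @param all_atom_source Optional \code{aak_structure} whose atoms are
#'   displaced per residue.
#' @return List with \code{plus} and \code{minus} (N x 3 coordinate
#'   matrices), \code{amplitude}, and when \code{all_atom_source} is given,
#'   \code{plus_atoms}/\code{minus_atoms} (full atom tables with displaced
#'   coordinates).
#' @export
generate_conformers <- function(model, modes, k, amplitude = NULL, rmsd = 1,
                                all_atom_source = NULL) {
  stopifnot(inherits(model, "coarse_model"))
  check_mode_index(modes, k)
  lam <- mode_values(modes)[k]
  u <- mode_vector(modes, k)
  if (is.null(amplitude)) {
    ## per-node displacement s * lam^-1/2 * u with |u| = 1 gives
    ## RMSD = s * lam^-1/2 / sqrt(N)
    amplitude <- rmsd * sqrt(model$N * lam)
  }
  disp <- as_xyz(amplitude * u / sqrt(lam))
  out <- list(plus = model$xyz + disp, minus = model$xyz - disp,
              amplitude = amplitude)
  if (!is.null(all_atom_source)) {
    stopifnot(inherits(all_atom_source, "aak_structure"))
    atom <- all_atom_source$atom
    key_atom <- paste(atom$chain, atom$resno, sep = "|")
    key_node <- paste(model$chain, model$resno, sep = "|")
    node_of <- match(key_atom, key_node)
    if (anyNA(node_of)) {
      stopf("%d atoms belong to residues absent from the coarse model",
            sum(is.na(node_of)))
    }
    shift <- function(sgn) {
      a2 <- atom
      a2$x <- a2$x + sgn * disp[node_of, 1]
      a2$y <- a2$y + sgn * disp[node_of, 2]
      a2$z <- a2$z + sgn * disp[node_of, 3]
      a2
    }
    out$plus_atoms <- shift(1)
    out$minus_atoms <- shift(-1)
  }
  out
}
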
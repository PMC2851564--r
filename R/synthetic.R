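#' Deterministic toy structures with known dynamics
#'
#' Generates coarse-grained toy models whose mechanical behaviour is known
#' by construction, so every analysis stage can be validated without
#' external structure files:
#' \itemize{
#'   \item \code{chain}: collinear beads (the 3-bead chain is the canonical
#'     path-graph fixture; deliberately degenerate in 3-D).
#'   \item \code{ring}: a planar circle.
#'   \item \code{helix}: an alpha-helix-like spiral (radius 2.3 A, rise
#'     1.5 A, 100 degrees per residue); the simplest non-degenerate 3-D
#'     topology.
#'   \item \code{dumbbell}: two compact lobes bridged by a short linker; the
#'     slowest ANM mode is the inter-lobe motion and the slowest GNM mode
#'     changes sign at the bridge (a known hinge).
#'   \item \code{two_chain_dimer}: two helical chains related by a C2 axis,
#'     for symmetric mode profiles and 3N-6 mode-count checks.
#' }
#' Every node is decorated with \code{n_atoms} pseudo heavy atoms placed
#' deterministically within \code{1.25 * atom_radius} of the node centre
#' (plus the centre itself), so heavy-atom contact counting is exercised
#' without real side chains. Synthetic B-factors mimic the empirical
#' anticorrelation between mobility and local packing density (loosely
#' packed nodes are more mobile) plus seeded Gaussian noise.
#'
#' @param topology One of \code{"chain"}, \code{"ring"}, \code{"helix"},
#'   \code{"dumbbell"}, \code{"two_chain_dimer"}.
#' @param n Number of nodes (per chain for the dimer).
#' @param spacing Inter-node spacing in Angstrom (chain/ring/linker).
#' @param seed Integer seed controlling the B-factor noise (the geometry is
#'   fully deterministic).
#' @param n_atoms Pseudo heavy atoms per node (besides the centre).
#' @param atom_radius Radial placement distance of pseudo-atoms (Angstrom).
#' @param lobe_radius Dumbbell lobe radius (Angstrom).
#' @param linker_length Number of linker nodes bridging the dumbbell lobes.
#' @return A \code{coarse_model} with an extra \code{info} field: list with
#'   \code{topology} and, for the dumbbell, \code{lobe1}, \code{lobe2},
#'   \code{bridge} (node index sets) and \code{bridge_center}.
#' @export
make_toy <- function(topology = c("chain", "ring", "helix", "dumbbell",
                                  "two_chain_dimer"),
                     n = 20, spacing = 3.8, seed = 1, n_atoms = 4,
                     atom_radius = 1.2, lobe_radius = 6, linker_length = 4) {
  topology <- match.arg(topology)
  if (n < 2) stopf("need at least 2 nodes")
  info <- list(topology = topology)
  chain <- rep("A", n)
  if (topology == "chain") {
    xyz <- cbind(spacing * (seq_len(n) - 1), 0, 0)
    if (n >= 3) warning("collinear geometry: degenerate for anisotropic NMA")
  } else if (topology == "ring") {
    r <- n * spacing / (2 * pi)
    th <- 2 * pi * (seq_len(n) - 1) / n
    xyz <- cbind(r * cos(th), r * sin(th), 0)
  } else if (topology == "helix") {
    xyz <- helix_coords(n)
  } else if (topology == "dumbbell") {
    n_lobe <- (n - linker_length) %/% 2
    if (n_lobe < 4) stopf("dumbbell needs at least 4 nodes per lobe")
    lobe <- ball_coords(n_lobe, lobe_radius)
    r_act <- sqrt(max(rowSums(lobe^2)))
    ## linker pitch 3.0 A keeps middle linker nodes within reach of both
    ## lobes (enough independent cross constraints to avoid floppy
    ## lobe-vs-lobe mechanisms) while the lobes stay out of direct contact
    pitch <- 3.0
    gap <- 2 * r_act + (linker_length + 1) * pitch
    l1 <- sweep(lobe, 2, c(-gap / 2, 0, 0), "+")
    l2 <- sweep(lobe, 2, c(+gap / 2, 0, 0), "+")
    x0 <- -gap / 2 + r_act
    ## small helical offset keeps the linker off the lobe-lobe axis, so
    ## rigid lobe rotations about that axis are elastically restrained
    ll <- seq_len(linker_length)
    link <- cbind(x0 + pitch * ll,
                  1.5 * cos(1.8 * ll), 1.5 * sin(1.8 * ll))
    xyz <- rbind(l1, link, l2)
    n <- nrow(xyz)
    chain <- rep("A", n)
    info$lobe1 <- seq_len(n_lobe)
    info$bridge <- n_lobe + seq_len(linker_length)
    info$lobe2 <- n_lobe + linker_length + seq_len(n_lobe)
    info$bridge_center <- n_lobe + (linker_length + 1L) %/% 2L
  } else { # two_chain_dimer
    a <- sweep(helix_coords(n), 2, c(5, 0, 0), "+")
    b <- cbind(-a[, 1], -a[, 2], a[, 3])
    xyz <- rbind(a, b)
    chain <- rep(c("A", "B"), each = n)
    n <- 2 * n
  }
  resno <- stats::ave(seq_len(n), chain, FUN = seq_along)
  ## synthetic B-factors emulate the empirical anticorrelation between
  ## atomic mobility and local packing density: loosely packed nodes get
  ## the largest temperature factors, plus seeded measurement noise
  d2 <- dist2_xy(xyz, xyz)
  contacts <- rowSums(d2 <= 8^2) - 1
  set.seed(seed)
  b <- 15 + 120 / pmax(contacts, 1) + stats::rnorm(n, sd = 2)
  model <- new_coarse_model(
    label = sprintf("%s:GLY%d", chain, resno),
    kind = rep("residue", n),
    chain = chain, resno = resno, resid = rep("GLY", n),
    xyz = xyz, b = b,
    heavy = decorate_heavy(xyz, n_atoms, atom_radius))
  model$info <- info
  model
}

helix_coords <- function(n, radius = 2.3, rise = 1.5, turn_deg = 100) {
  th <- (seq_len(n) - 1) * turn_deg * pi / 180
  cbind(radius * cos(th), radius * sin(th), rise * (seq_len(n) - 1))
}

## deterministic compact ball: cubic-grid points nearest the centre
ball_coords <- function(n, radius, grid = 3.4) {
  k <- ceiling((3 * n)^(1 / 3))
  g <- grid * (seq(-k, k))
  pts <- as.matrix(expand.grid(x = g, y = g, z = g))
  d <- rowSums(pts^2)
  pts <- pts[order(d, pts[, 1], pts[, 2], pts[, 3]), , drop = FALSE]
  pts <- pts[seq_len(n), , drop = FALSE]
  ## shrink to the requested radius if needed; never dilate (inter-node
  ## spacing must stay within physical contact range)
  rmax <- sqrt(max(rowSums(pts^2)))
  if (rmax > radius) pts <- pts * (radius / rmax)
  unname(pts)
}

## n_atoms pseudo-atoms on tetrahedral directions, rotated per node so
## consecutive nodes expose different faces; the node centre itself is the
## first heavy atom
decorate_heavy <- function(xyz, n_atoms, atom_radius) {
  tetra <- rbind(c(1, 1, 1), c(1, -1, -1), c(-1, 1, -1), c(-1, -1, 1),
                 c(0, 0, 1.5), c(0, 1.5, 0)) / sqrt(3)
  lapply(seq_len(nrow(xyz)), function(i) {
    ang <- (i - 1) * 2.399963  # golden angle, radians
    rot <- matrix(c(cos(ang), -sin(ang), 0,
                    sin(ang), cos(ang), 0,
                    0, 0, 1), 3, 3, byrow = TRUE)
    offs <- tetra[seq_len(min(n_atoms, nrow(tetra))), , drop = FALSE] %*% rot *
      atom_radius
    rbind(xyz[i, ], sweep(offs, 2, xyz[i, ], "+"))
  })
}

#' Deform a toy model along a normal mode
#'
#' Produces a synthetic "closed" conformation by displacing coordinates
#' along internal mode k, with optional seeded isotropic Gaussian noise.
#' Heavy atoms ride rigidly with their node.
#'
#' @param model A \code{coarse_model}.
#' @param modes An ANM \code{mode_set} of the model.
#' @param k Internal mode index.
#' @param amplitude Mode amplitude \code{s_k} (see
#'   \code{\link{generate_conformers}}).
#' @param rmsd Target C-alpha RMSD of the displacement when
#'   \code{amplitude} is not given (default 1 Angstrom).
#' @param noise_sd Isotropic Gaussian noise per coordinate (Angstrom).
#' @param seed Seed for the noise.
#' @return A new \code{coarse_model} with displaced coordinates.
#' @export
deform_toy <- function(model, modes, k, amplitude = NULL, rmsd = 1,
                       noise_sd = 0, seed = 1) {
  conf <- generate_conformers(model, modes, k, amplitude = amplitude,
                              rmsd = rmsd)
  new_xyz <- conf$plus
  if (noise_sd > 0) {
    set.seed(seed)
    new_xyz <- new_xyz + matrix(stats::rnorm(3 * model$N, sd = noise_sd),
                                ncol = 3)
  }
  shift <- new_xyz - model$xyz
  out <- model
  out$xyz <- new_xyz
  out$heavy <- lapply(seq_len(model$N), function(i) {
    sweep(model$heavy[[i]], 2, shift[i, ], "+")
  })
  out
}

#' Empirical hitting time by seeded random-walk simulation
#'
#' Independent Monte-Carlo verification of the analytic hitting times:
#' simulates walks under the Markov transition matrix and reports the mean
#' number of steps to first reach the target, with its standard error.
#'
#' @param markov A \code{markov_model}.
#' @param from,to Source and target node indices.
#' @param n_walks Number of walks (default 20000).
#' @param seed Integer seed.
#' @param max_total_steps Abort threshold across all walks (guards against
#'   unreachable targets).
#' @return List with \code{mean}, \code{se}, \code{n_walks}.
#' @export
random_walk_oracle <- function(markov, from, to, n_walks = 20000, seed = 1,
                               max_total_steps = 1e7) {
  stopifnot(inherits(markov, "markov_model"))
  if (from == to) return(list(mean = 0, se = 0, n_walks = n_walks))
  m <- markov$M
  n <- nrow(m)
  cum <- apply(m, 2, cumsum)
  set.seed(seed)
  steps <- numeric(n_walks)
  total <- 0
  for (w in seq_len(n_walks)) {
    node <- from
    k <- 0
    while (node != to) {
      node <- findInterval(stats::runif(1), cum[, node]) + 1L
      k <- k + 1
      total <- total + 1
      if (total > max_total_steps) {
        stopf("target apparently unreachable: step cap %g exceeded",
              max_total_steps)
      }
    }
    steps[w] <- k
  }
  list(mean = mean(steps), se = stats::sd(steps) / sqrt(n_walks),
       n_walks = n_walks)
}
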
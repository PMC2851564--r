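test_that("Schur complement reproduces the worked 1-D case", {
  m <- matrix(c(2, -1, 0, -1, 2, -1, 0, -1, 2), 3)
  eff <- schur_complement(m, 1)
  expect_equal(eff[1, 1], 4 / 3)
  # equal to the reciprocal of the (1,1) element of the full inverse
  expect_equal(eff[1, 1], 1 / solve(m)[1, 1])
})

test_that("Schur identity holds against full inversion on random PD matrices", {
  for (seed in 1:8) {
    set.seed(seed)
    n <- sample(10:60, 1)
    a <- matrix(stats::rnorm(n * n), n)
    m <- crossprod(a) + diag(n) * 0.1
    s <- sort(sample(n, sample(2:(n - 2), 1)))
    eff <- schur_complement(m, s)
    expect_equal(solve(eff), solve(m)[s, s], tolerance = 1e-9,
                 ignore_attr = TRUE)
  }
})

test_that("zero coupling returns the subsystem block unchanged", {
  m <- matrix(0, 4, 4)
  m[1:2, 1:2] <- matrix(c(2, -1, -1, 2), 2)
  m[3:4, 3:4] <- matrix(c(3, 1, 1, 3), 2)
  expect_identical(schur_complement(m, 1:2), m[1:2, 1:2])
  expect_error(schur_complement(m, 1:4), "proper non-empty subset")
  expect_error(schur_complement(m, integer(0)), "proper non-empty subset")
})

test_that("effective Hessian partitions the ANM Hessian consistently", {
  db <- make_toy("dumbbell", n = 30, seed = 3)
  hs <- build_hessian(db, cutoff = 15)
  part <- effective_hessian(hs, db$info$lobe1)
  expect_equal(dim(part$Heff), rep(3 * length(db$info$lobe1), 2))
  expect_true(isSymmetric(part$Heff, tol = 1e-9))
  # Schur complement of a PSD matrix is PSD
  ev <- eigen(part$Heff, symmetric = TRUE, only.values = TRUE)$values
  expect_gt(min(ev), -1e-10 * max(ev))
  expect_error(effective_hessian(hs, seq_len(db$N)), "proper non-empty")
})

test_that("effective stiffness equals the relaxed-environment energy", {
  db <- make_toy("dumbbell", n = 30, seed = 3)
  hs <- build_hessian(db, cutoff = 15)
  part <- effective_hessian(hs, db$info$lobe1)
  sub <- subsystem_modes(part)
  # rigid motions of the subsystem stay zero-energy: the environment follows
  expect_equal(sub$n_zero, 6)
  s_xyz <- db$xyz[db$info$lobe1, , drop = FALSE]
  translation <- as.vector(t(cbind(1, 0, 0)[rep(1, nrow(s_xyz)), ]))
  expect_lt(max(abs(part$Heff %*% translation)), 1e-9)
  # for any subsystem displacement, u' Heff u is the minimum full elastic
  # energy over environment placements (direct linear-solve oracle)
  set.seed(4)
  for (rep_i in 1:3) {
    u_s <- stats::rnorm(ncol(part$Heff))
    u_e <- -solve(part$Hee, t(part$Hse) %*% u_s)
    e_min <- drop(t(u_s) %*% part$Hss %*% u_s + 2 * t(u_s) %*% part$Hse %*% u_e +
                    t(u_e) %*% part$Hee %*% u_e)
    expect_equal(drop(t(u_s) %*% part$Heff %*% u_s), e_min, tolerance = 1e-8)
  }
})

test_that("decoupled subsystems reproduce their isolated modes", {
  # two dumbbells far apart: no coupling blocks between them
  db <- make_toy("dumbbell", n = 20, seed = 4)
  far <- toy_from_coords(rbind(db$xyz, sweep(db$xyz, 2, c(500, 0, 0), "+")))
  hs <- suppressWarnings(build_hessian(far, cutoff = 15))
  part <- effective_hessian(hs, seq_len(db$N))
  expect_identical(part$Heff, part$Hss)
  iso <- suppressWarnings(decompose_modes(build_hessian(db, cutoff = 15)))
  sub <- subsystem_modes(part)
  expect_equal(mode_values(sub)[1:5], mode_values(iso)[1:5], tolerance = 1e-9)
})

test_that("mode correlation matrices are bounded with unit self-diagonal", {
  hx <- make_toy("helix", n = 16)
  an <- decompose_modes(build_hessian(hx, cutoff = 12))
  self <- mode_correlation_matrix(an, an, n = 5)
  expect_equal(diag(self), rep(1, 5), tolerance = 1e-9)
  expect_true(all(self >= 0 & self <= 1 + 1e-12))
  expect_error(
    mode_correlation_matrix(an, an, alignment_map(1:2, 1:2), n = 3),
    "too small")
})

test_that("mode comparison is equivariant under rigid rotation", {
  hx <- make_toy("helix", n = 16)
  th <- 1.1
  rot <- matrix(c(cos(th), 0, sin(th), 0, 1, 0, -sin(th), 0, cos(th)), 3,
                byrow = TRUE)
  moved <- hx
  moved$xyz <- hx$xyz %*% rot + matrix(c(3, 4, -2), hx$N, 3, byrow = TRUE)
  fit <- superpose(hx, moved)
  back <- moved; back$xyz <- fit$b_fitted
  an_a <- decompose_modes(build_hessian(hx, cutoff = 12))
  an_b <- decompose_modes(build_hessian(back, cutoff = 12))
  cm <- mode_correlation_matrix(an_a, an_b, n = 4)
  expect_equal(diag(cm), rep(1, 4), tolerance = 1e-6)
})

test_that("family overlap summary scores identity, orthogonality, permutation", {
  expect_equal(family_overlap_summary(diag(10)), 100)
  expect_equal(family_overlap_summary(matrix(0, 10, 10)), 0)
  perm <- diag(10)[, sample(10)]
  expect_equal(family_overlap_summary(perm), 100)
  expect_error(family_overlap_summary(diag(4), m = 10), "smaller")
})

test_that("family overlap is approximately symmetric on perturbed pairs", {
  db <- make_toy("dumbbell", n = 24, seed = 6)
  noised <- db
  set.seed(3)
  noised$xyz <- db$xyz + matrix(stats::rnorm(3 * db$N, sd = 0.2), ncol = 3)
  an_a <- decompose_modes(build_hessian(db, cutoff = 15))
  an_b <- decompose_modes(build_hessian(noised, cutoff = 15))
  ab <- family_overlap_summary(mode_correlation_matrix(an_a, an_b, n = 10))
  ba <- family_overlap_summary(mode_correlation_matrix(an_b, an_a, n = 10))
  expect_lt(abs(ab - ba), 5)
})
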
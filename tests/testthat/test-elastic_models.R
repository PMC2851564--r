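test_that("Kirchhoff matrix of the 3-bead path has the known form", {
  p3 <- p3_model()
  kk <- build_kirchhoff(p3, cutoff = 1.5, gamma = 1)
  expect_equal(kk$mat, matrix(c(1, -1, 0, -1, 2, -1, 0, -1, 1), 3))
  # larger cutoff connects everything
  kk2 <- build_kirchhoff(p3, cutoff = 2.5)
  expect_equal(diag(kk2$mat), c(2, 2, 2))
  expect_true(all(kk2$mat[upper.tri(kk2$mat)] == -1))
  # contacts at exactly the cutoff are included (closed interval)
  kk3 <- build_kirchhoff(p3, cutoff = 1)
  expect_equal(kk3$mat[1, 2], -1)
})

test_that("path-graph spectrum and fluctuations match the pseudoinverse", {
  ms <- decompose_modes(build_kirchhoff(p3_model(), cutoff = 1.5))
  expect_equal(ms$n_zero, 1)
  expect_equal(mode_values(ms), c(1, 3))
  expect_equal(msf_profile(ms), c(5, 2, 5) / 9)
  cc <- cross_correlations(ms)
  expect_equal(cc[1, 2], -1 / 9)
  expect_equal(diag(cc), msf_profile(ms), tolerance = 1e-12)
  expect_equal(rowSums(cc), rep(0, 3), tolerance = 1e-12)
  # single-mode profile is the squared shape over its eigenvalue
  u1 <- mode_vector(ms, 1)
  expect_equal(msf_profile(ms, 1), u1^2 / mode_values(ms)[1])
  expect_error(msf_profile(ms, 0), "out of range")
})

test_that("row sums vanish and MSF equals the ginv diagonal on random toys", {
  for (seed in 1:5) {
    set.seed(seed)
    n <- sample(8:30, 1)
    xyz <- matrix(stats::rnorm(3 * n, sd = 4), ncol = 3)
    model <- toy_from_coords(xyz)
    kk <- suppressWarnings(build_kirchhoff(model, cutoff = 12))
    expect_lt(max(abs(rowSums(kk$mat))), 1e-12 * n)
    ms <- tryCatch(decompose_modes(kk), error = function(e) NULL)
    if (is.null(ms)) next  # disconnected draw
    gplus <- MASS::ginv(kk$mat)
    expect_equal(msf_profile(ms), diag(gplus), tolerance = 1e-9)
    spectral <- cross_correlations(ms)
    expect_equal(spectral, gplus, tolerance = 1e-9, ignore_attr = TRUE)
  }
})

test_that("two-bead Hessian has one stretching mode of stiffness 2", {
  two <- toy_from_coords(cbind(c(0, 1), 0, 0))
  hs <- build_hessian(two, cutoff = 2)
  expect_warning(ms <- decompose_modes(hs), "degenerate")
  expect_equal(ms$n_zero, 5)
  expect_equal(mode_values(ms), 2)
  # block row sums vanish
  expect_lt(max(abs(rowSums(hs$mat))), 1e-12)
})

test_that("non-degenerate geometries give exactly six rigid-body modes", {
  hx <- make_toy("helix", n = 15)
  ms <- decompose_modes(build_hessian(hx, cutoff = 12))
  expect_equal(ms$n_zero, 6)
  expect_equal(n_modes(ms), 3 * 15 - 6)
  # PSD within tolerance
  expect_gt(min(ms$values), -1e-10 * max(ms$values))
  # the GNM zero mode is uniform
  gn <- decompose_modes(build_kirchhoff(hx, cutoff = 10))
  u0 <- gn$vectors[, 1]
  expect_equal(abs(u0), rep(1 / sqrt(15), 15), tolerance = 1e-9)
})

test_that("GNM decomposition refuses disconnected networks", {
  apart <- toy_from_coords(rbind(cbind(c(0, 1, 2), 0, 0),
                                 cbind(c(100, 101, 102), 0, 0)))
  kk <- suppressWarnings(build_kirchhoff(apart, cutoff = 1.5))
  expect_error(decompose_modes(kk), "disconnected")
})

test_that("coincident nodes inside a contact are an error", {
  bad <- toy_from_coords(rbind(c(0, 0, 0), c(0, 0, 0), c(3, 0, 0)))
  expect_error(build_hessian(bad, cutoff = 5), "coincident")
})

test_that("B-factor prediction is affine-invariant and mean-matched", {
  ms <- decompose_modes(build_kirchhoff(make_toy("helix", n = 12),
                                        cutoff = 10))
  msf <- msf_profile(ms)
  bf <- predict_bfactors(msf, msf * 2.7)
  expect_equal(bf$r, 1)
  expect_equal(bf$predicted, msf * 2.7, tolerance = 1e-12)
  # anti-proportional experimental values give r = -1
  bf2 <- predict_bfactors(msf, 100 - 5 * msf)
  expect_equal(bf2$r, -1)
  # mismatched shapes lose correlation
  bf3 <- predict_bfactors(msf, rev(msf) + seq_along(msf) * 0.01)
  expect_lt(bf3$r, 1)
  expect_error(predict_bfactors(msf, rep(1, length(msf))), "undefined")
})

test_that("hinge detection follows the sign-change and tie-break rules", {
  expect_equal(find_hinges(c(1, 0.1, -0.1, -1)), 2)   # tie -> lower index
  expect_equal(find_hinges(c(1, 0.3, -0.1, -1)), 3)   # smaller amplitude wins
  expect_equal(find_hinges(c(1, 2, 3, 4)), integer(0)) # constant sign
  # sign changes across a chain break are not hinges
  expect_equal(find_hinges(c(1, 1, -1, -1), chain = c("A", "A", "B", "B")),
               integer(0))
  # dumbbell: slowest GNM mode flips sign at the bridge
  db <- make_toy("dumbbell", n = 30, seed = 2)
  gn <- decompose_modes(build_kirchhoff(db, cutoff = 10))
  hinge <- find_hinges(mode_vector(gn, 1), chain = db$chain)
  expect_true(any(hinge %in% db$info$bridge))
})

test_that("GNM-to-ANM mode map self-correlates and stays bounded", {
  hx <- make_toy("helix", n = 14)
  gn <- decompose_modes(build_kirchhoff(hx, cutoff = 10))
  an <- decompose_modes(build_hessian(hx, cutoff = 12))
  m <- map_gnm_to_anm(gn, an, n_modes_map = 3)
  expect_true(all(abs(m) <= 1 + 1e-12))
  self <- map_gnm_to_anm(gn, gn, n_modes_map = 3)
  expect_equal(diag(self), rep(1, 3), tolerance = 1e-12)
})
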
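test_that("affinities follow the contact-count formula", {
  # two nodes, 2 heavy atoms each, exactly one cross-pair within 4 A
  xyz <- rbind(c(0, 0, 0), c(5, 0, 0), c(8.5, 0, 0))
  heavy <- list(rbind(c(0, 0, 0), c(1.5, 0, 0)),
                rbind(c(5, 0, 0), c(9, 0, 0)),
                rbind(c(8.5, 0, 0), c(7, 0, 0)))
  model <- toy_from_coords(xyz, heavy = heavy)
  aff <- build_affinity(model, threshold = 4)
  expect_equal(aff$A[1, 2], 1 / sqrt(2 * 2))  # only 1.5 <-> 5 is within 4
  # all atom pairs beyond the threshold give zero affinity
  expect_equal(aff$A[1, 3], 0)
  expect_equal(diag(aff$A), rep(0, 3))
  # Laplacian rows sum to zero
  expect_lt(max(abs(rowSums(aff$laplacian))), 1e-12)
})

test_that("isolated nodes are refused by name", {
  xyz <- rbind(c(0, 0, 0), c(2, 0, 0), c(50, 0, 0))
  model <- toy_from_coords(xyz)
  expect_error(build_affinity(model, threshold = 4), "isolated.*GLY3")
})

test_that("Markov matrix is column-stochastic with detailed balance", {
  aff <- p3_affinity()
  expect_equal(aff$d, c(1, 2, 1))
  mk <- build_markov(aff)
  expect_equal(mk$M[, 2], c(1 / 2, 0, 1 / 2))
  expect_equal(colSums(mk$M), rep(1, 3), tolerance = 1e-12)
  # a_ij = m_ij d_j = m_ji d_i
  expect_equal(sweep(mk$M, 2, aff$d, "*"),
               t(sweep(t(mk$M), 1, aff$d, "*")), tolerance = 1e-12)
})

test_that("path-graph hitting times match first-step analysis", {
  cm <- hitting_times(p3_affinity())
  expect_equal(cm$H[3, 1], 4)
  expect_equal(cm$H[3, 2], 3)
  expect_equal(cm$H[2, 1], 1)
  expect_equal(cm$tau[1, 3], 8)
  # commute time = total degree x effective resistance
  expect_equal(cm$tau[1, 3], 4 * effective_resistance(p3_affinity()$A, 1, 3),
               tolerance = 1e-9)
  expect_true(all(abs(diag(cm$H)) < 1e-12))
  expect_equal(cm$tau, t(cm$tau))
})

test_that("spectral hitting times equal the linear-system oracle on random graphs", {
  for (seed in 1:50) {
    n <- 5 + (seed %% 10) * 5   # sizes 5..50
    amat <- random_connected_affinity(n, seed)
    cm <- hitting_times(affinity_from_matrix(amat))
    expect_equal(cm$H, first_step_hitting_matrix(amat), tolerance = 1e-8,
                 ignore_attr = TRUE)
  }
})

test_that("commute identity tau = Vol * R_eff holds on random graphs", {
  for (seed in 1:10) {
    amat <- random_connected_affinity(20, seed + 100)
    cm <- hitting_times(affinity_from_matrix(amat))
    i <- 1 + (seed %% 19); j <- 20 - (seed %% 5)
    expect_equal(cm$tau[i, j],
                 sum(rowSums(amat)) * effective_resistance(amat, i, j),
                 tolerance = 1e-9)
  }
})

test_that("Monte-Carlo walks agree with analytic hitting times", {
  aff <- p3_affinity()
  cm <- hitting_times(aff)
  mk <- build_markov(aff)
  rw <- random_walk_oracle(mk, 1, 3, n_walks = 20000, seed = 11)
  expect_lt(abs(rw$mean - cm$H[3, 1]), 3 * rw$se)
})

test_that("disconnected affinity graphs are refused", {
  amat <- matrix(0, 4, 4)
  amat[1, 2] <- amat[2, 1] <- 1
  amat[3, 4] <- amat[4, 3] <- 1
  expect_error(hitting_times(affinity_from_matrix(amat)), "disconnected")
})

test_that("mean hitting-time profiles follow their conventions", {
  cm <- hitting_times(p3_affinity())
  h <- first_step_hitting_matrix(p3_affinity()$A)
  expect_equal(mean_receive_time(cm, "receiver"), rowMeans(h))
  expect_equal(mean_receive_time(cm, "broadcast"), colMeans(h))
  expect_equal(mean_receive_time(cm, "broadcast"), c(5, 6, 5) / 3)
  # symmetric graph -> symmetric profile; best receiver is the hub
  star <- matrix(0, 5, 5); star[1, 2:5] <- star[2:5, 1] <- 1
  cs <- hitting_times(affinity_from_matrix(star))
  prof <- mean_receive_time(cs, "receiver")
  expect_equal(which.min(prof), 1L)
  expect_equal(prof[2], prof[5])
})

test_that("self/cross decomposition is exact and vanishes for equal states", {
  amat <- random_connected_affinity(12, 5)
  cm <- hitting_times(affinity_from_matrix(amat))
  dec <- decompose_hitting(cm)
  expect_equal(dec$self + dec$cross, cm$H, tolerance = 1e-9)
  # self part is Vol * G_jj, constant along each row's sources
  expect_equal(dec$self[3, 1], cm$vol * cm$Gplus[3, 3])
  expect_equal(dec$self[3, 7], dec$self[3, 2])
  both <- decompose_hitting(cm, cm)
  expect_equal(both$difference, matrix(0, 12, 12), tolerance = 1e-12,
               ignore_attr = TRUE)
})

test_that("optimal pathways minimize -log transition probability", {
  mk <- build_markov(p3_affinity())
  sp <- shortest_path(mk, 1, 3)
  expect_equal(sp$path, c(1, 2, 3))
  expect_equal(sp$cost, log(2))
  expect_error(shortest_path(mk, 2, 2), "must differ")
  # exhaustive enumeration oracle on random graphs
  for (seed in 1:5) {
    amat <- random_connected_affinity(8, seed + 40)
    mk2 <- build_markov(affinity_from_matrix(amat))
    sp2 <- shortest_path(mk2, 1, 8)
    expect_equal(sp2$cost, enumerate_path_cost(mk2$M, 1, 8),
                 tolerance = 1e-9)
    # cost equals -log of the step-probability product
    steps <- cbind(sp2$path[-length(sp2$path)], sp2$path[-1])
    expect_equal(sp2$cost,
                 -log(prod(mk2$M[cbind(steps[, 2], steps[, 1])])),
                 tolerance = 1e-12)
  }
})

test_that("group statistics aggregate ordered pairs in both directions", {
  cm <- hitting_times(p3_affinity())
  gs <- group_path_stats(cm, 1, 3)
  expect_equal(gs$mean, 4)   # H(3|1) = H(1|3) = 4 by symmetry
  expect_equal(gs$sd, 0)
  expect_equal(gs$n_pairs, 2)
  expect_error(group_path_stats(cm, c(1, 2), c(2, 3)), "disjoint")
  expect_error(group_path_stats(cm, integer(0), 3), "empty")
})
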
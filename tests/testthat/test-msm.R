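test_that("TICA identifies the slow coordinate", {
  set.seed(42)
  # single feature: TIC1 is the feature up to sign/scale
  n <- 2000
  x <- as.numeric(stats::arima.sim(list(ar = 0.9), n))
  t1 <- tica(cbind(x), lag = 5, n_dims = 1)
  expect_gt(abs(cor(t1$y[, 1], x)), 1 - 1e-10)

  # planted slow mode mixed with a fast one
  s <- as.numeric(stats::arima.sim(list(ar = 0.99), n))   # tau ~ 100
  f <- as.numeric(stats::arima.sim(list(ar = 0.60), n))   # tau ~ 2
  A <- matrix(c(1.2, -0.7, 0.4, 0.9), 2, 2)
  t2 <- tica(cbind(s, f) %*% A, lag = 10, n_dims = 2)
  expect_gte(abs(cor(t2$y[, 1], s)), 0.9)
  expect_true(all(diff(t2$eigenvalues) <= 1e-12))

  # white noise: all eigenvalues near zero
  W <- matrix(rnorm(n * 3), n, 3)
  t3 <- tica(W, lag = 5, n_dims = 3)
  expect_lt(max(abs(t3$eigenvalues)), 3 / sqrt(n))
})

test_that("microstate clustering is seeded and recovers planted blobs", {
  set.seed(8)
  X <- rbind(matrix(rnorm(200, 0, 0.5), ncol = 2),
             matrix(rnorm(200, 10, 0.5), ncol = 2))
  cl <- cluster_microstates(X, k = 2, seed = 3)
  expect_equal(length(unique(cl$assignments[1:100])), 1L)
  expect_equal(length(unique(cl$assignments[101:200])), 1L)
  cl2 <- cluster_microstates(X, k = 2, seed = 3)
  expect_identical(cl$assignments, cl2$assignments)
  expect_equal(unique(cluster_microstates(X, k = 1, seed = 1)$assignments),
               1L)
  expect_error(cluster_microstates(X[1:3, ], k = 10, seed = 1), "distinct")
})

test_that("count matrices enumerate sliding-window pairs per trajectory", {
  expect_equal(count_matrix(c(1, 2, 1, 2), lag = 1),
               matrix(c(0, 1, 2, 0), 2, 2))
  expect_equal(count_matrix(c(1, 1, 1), lag = 1), matrix(2L, 1, 1))
  # separate trajectories differ from concatenation by the boundary pair
  a <- c(1, 2, 2); b <- c(2, 1, 1)
  C_sep <- count_matrix(list(a, b), lag = 1)
  C_cat <- count_matrix(c(a, b), lag = 1)
  expect_equal(C_cat - C_sep, matrix(c(0, 0, 0, 1), 2, 2))  # boundary 2 -> 2
  expect_error(count_matrix(list(c(1, 2)), lag = 5), "no transition pairs")
})

test_that("transition matrices are row-stochastic with stationary pi", {
  C <- rbind(c(8, 2), c(1, 9))
  est <- transition_matrix(C, reversible = FALSE)
  expect_equal(est$P, rbind(c(0.8, 0.2), c(0.1, 0.9)))
  # symmetric counts: reversible and non-reversible agree
  S <- rbind(c(5, 3), c(3, 9))
  expect_equal(transition_matrix(S, TRUE)$P, transition_matrix(S, FALSE)$P)
  set.seed(2)
  for (i in 1:10) {
    Ck <- matrix(rpois(25, 6) + 1, 5, 5)
    for (rev in c(TRUE, FALSE)) {
      e <- transition_matrix(Ck, rev)
      expect_equal(rowSums(e$P), rep(1, 5), tolerance = 1e-12)
      expect_equal(as.numeric(e$pi %*% e$P), e$pi, tolerance = 1e-8)
      if (rev)   # detailed balance
        expect_equal(e$pi * e$P, t(e$pi * e$P), tolerance = 1e-8)
    }
  }
})

test_that("disconnected counts restrict to the largest strong component", {
  C <- matrix(0, 4, 4)
  C[1, 2] <- C[2, 1] <- 10
  C[3, 4] <- C[4, 3] <- 2
  C[1, 1] <- 5
  est <- transition_matrix(C)
  expect_equal(est$active, c(1L, 2L))
  expect_equal(est$n_dropped_counts, 4)
})

test_that("implied timescales match the closed-form two-state eigenvalue", {
  P <- rbind(c(0.9, 0.1), c(0.2, 0.8))   # lambda2 = 0.7
  sim <- simulate_markov_chain(P, centers = diag(2), n_steps = 2e5,
                               seed = 10)
  its <- implied_timescales(sim$dtraj, lags = c(1, 2, 4), n_timescales = 1)
  expect_equal(its$t1[1], -1 / log(0.7), tolerance = 0.05)
  # flat across lags for Markovian data
  expect_lt(max(abs(its$t1 - its$t1[1])) / its$t1[1], 0.15)
  # label permutation leaves timescales unchanged
  perm <- c(2L, 1L)[sim$dtraj]
  its_p <- implied_timescales(perm, lags = c(1, 2, 4), n_timescales = 1)
  expect_equal(its$t1, its_p$t1)
})

test_that("spectral lumping recovers planted blocks", {
  set.seed(3)
  k <- 9
  P <- matrix(0.001, k, k)
  blocks <- rep(1:3, each = 3)
  for (b in 1:3) P[blocks == b, blocks == b] <- 1
  P <- P / rowSums(P)
  lump <- lump_metastable(P, 3, seed = 4)
  expect_equal(mclust::adjustedRandIndex(lump, blocks), 1.0)
  # identity lumping at n_states = k
  expect_equal(lump_metastable(P, k), 1:k)
  # permuting microstates permutes the lumping
  perm <- sample(k)
  lump_p <- lump_metastable(P[perm, perm], 3, seed = 4)
  expect_equal(mclust::adjustedRandIndex(lump_p, blocks[perm]), 1.0)
})

test_that("MFPT solves the first-passage linear system", {
  P <- rbind(c(0.9, 0.1), c(0.2, 0.8))
  expect_equal(mfpt(P, 1, 2), 10)
  expect_equal(mfpt(P, 2, 1), 5)
  # immediate absorption: P[source, sink] = 1
  P2 <- rbind(c(0, 1), c(0.5, 0.5))
  expect_equal(mfpt(P2, 1, 2, lag_time = 3), 3)
  expect_error(mfpt(P, 1, 1), "disjoint")
  expect_error(mfpt(P, integer(0), 2), "non-empty")
})

test_that("linear-solve MFPT matches the Monte-Carlo oracle", {
  set.seed(77)
  P <- random_transition_matrix(5)
  m_lin <- mfpt(P, source = c(1, 2), sink = 5)
  mc <- mc_first_passage(P, source = c(1, 2), sink = 5,
                         n_walkers = 2e4, seed = 78)
  expect_lt(abs(m_lin - mc$mean), 2 * mc$se + 1e-9)
})

test_that("rates and dissociation constant derive from the MFPTs", {
  k1 <- rates_and_kd(10, 10)
  expect_equal(k1$k_d, 1)
  k2 <- rates_and_kd(10, 5)
  expect_equal(k2$k_d, 2)
  expect_equal(k2$k_on, 0.1)
  expect_equal(k2$k_off, 0.2)
  # time-unit invariance of k_d
  k3 <- rates_and_kd(5, 2.5)
  expect_equal(k3$k_d, k2$k_d)
  expect_error(rates_and_kd(Inf, 1), "finite")
})

test_that("parameter recovery from a simulated 3-state chain", {
  P_true <- rbind(c(0.90, 0.08, 0.02),
                  c(0.10, 0.80, 0.10),
                  c(0.02, 0.08, 0.90))
  sim <- simulate_markov_chain(P_true, centers = diag(3), n_steps = 1e5,
                               seed = 123)
  C <- count_matrix(sim$dtraj, lag = 1)
  est <- transition_matrix(C, reversible = FALSE)
  # entrywise within 3 binomial standard errors
  nrows <- rowSums(C)
  se <- sqrt(P_true * (1 - P_true) / nrows)
  expect_true(all(abs(est$P - P_true) <= 3 * se + 1e-12))
  m_on_true <- sim$mfpt_true(3, 1)
  m_off_true <- sim$mfpt_true(1, 3)
  m_on <- mfpt(est$P, 3, 1, pi = est$pi)
  m_off <- mfpt(est$P, 1, 3, pi = est$pi)
  expect_lt(abs(m_on - m_on_true) / m_on_true, 0.05)
  expect_lt(abs(m_off - m_off_true) / m_off_true, 0.05)
  kd <- rates_and_kd(m_on, m_off)$k_d
  kd_true <- m_on_true / m_off_true
  expect_lt(abs(kd - kd_true) / kd_true, 0.10)
})

test_that("Chapman-Kolmogorov deviations stay in band for Markovian data", {
  P <- rbind(c(0.95, 0.05), c(0.10, 0.90))
  sim <- simulate_markov_chain(P, centers = diag(2), n_steps = 5e4,
                               seed = 31)
  trajs <- split(sim$dtraj, rep(1:10, each = 5e3))
  ck <- ck_test(trajs, lag = 2, factors = c(2, 3, 4), n_macrostates = 2,
                n_boot = 100, seed = 32)
  expect_true(all(ck$within_band))
  expect_lt(max(ck$deviation), 0.05)
})

test_that("Chapman-Kolmogorov flags a heavy-tailed semi-Markov plant", {
  set.seed(55)
  # alternating 2-state process with Pareto dwell times: not Markovian
  dwell <- function(n) 1L + floor((runif(n)^(-1 / 1.1) - 1) * 3)
  states <- integer(0); s <- 1L
  while (length(states) < 5e4) {
    states <- c(states, rep(s, min(dwell(1), 2000L)))
    s <- 3L - s
  }
  states <- states[1:5e4]
  trajs <- split(states, rep(1:10, each = 5e3))
  ck <- ck_test(trajs, lag = 2, factors = c(2, 3, 4), n_macrostates = 2,
                n_boot = 100, seed = 56)
  expect_false(all(ck$within_band[ck$factor == 4]))
})
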
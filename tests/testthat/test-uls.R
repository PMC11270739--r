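test_that("fingerprints summarise distances with interpolated percentiles", {
  fp <- state_fingerprint(cbind(d = c(1, 2, 3, 4)))
  expect_equal(unname(fp), c(2.5, 1.75, 2.5, 3.25))

  const <- state_fingerprint(cbind(d = rep(7, 20)))
  expect_equal(unname(const), rep(7, 4))

  five <- state_fingerprint(matrix(3, nrow = 10, ncol = 5))
  expect_length(five, 20L)

  expect_error(state_fingerprint(matrix(numeric(0), 0, 5)), "empty")
})

test_that("fingerprints are permutation-invariant and ordered", {
  set.seed(31)
  for (i in 1:50) {
    ens <- matrix(runif(5 * 30, 0, 25), 30, 5)
    fp <- state_fingerprint(ens)
    fp_perm <- state_fingerprint(ens[sample(30), , drop = FALSE])
    expect_equal(fp, fp_perm)
    q <- matrix(fp, nrow = 4)   # rows: mean, p25, p50, p75
    expect_true(all(q[2, ] <= q[3, ] & q[3, ] <= q[4, ]))
  }
})

test_that("PCA reduction is deterministic with fixed sign and variance order", {
  set.seed(5)
  # rank-1 data: PC1 explains everything
  t <- runif(10)
  F1 <- outer(t, runif(20, -2, 2))
  r1 <- reduce_fingerprints(F1, scale. = FALSE)
  expect_gt(r1$explained[1], 1 - 1e-9)
  expect_lt(max(abs(r1$scores[, 2:3])), 1e-9)

  # duplicated rows give identical scores
  F2 <- matrix(runif(100), 5, 20)[c(1:5, 3), ]
  r2 <- reduce_fingerprints(F2)
  expect_equal(r2$scores[3, ], r2$scores[6, ])

  # reconstruction from all components reproduces the centered data
  F3 <- matrix(runif(200), 10, 20)
  r3 <- reduce_fingerprints(F3, n_components = 9, scale. = FALSE)
  rec <- r3$scores[, 1:9] %*% t(r3$loadings)
  expect_equal(rec, scale(F3, scale = FALSE), ignore_attr = TRUE,
               tolerance = 1e-9)

  # sign convention: largest-magnitude loading positive
  expect_true(all(apply(r3$loadings, 2,
                        function(v) v[which.max(abs(v))] > 0)))
  expect_error(reduce_fingerprints(F3[1, , drop = FALSE]), "at least 2")
})

test_that("ULS clustering recovers planted structure and handles noise", {
  set.seed(9)
  # two well-separated groups of 3 (gap 10x spread)
  sc <- rbind(matrix(rnorm(9, 0, 0.1), 3),
              sweep(matrix(rnorm(9, 0, 0.1), 3), 2, c(-10, 0, 0)))
  a <- cluster_uls(sc)
  expect_equal(length(unique(a$uls)), 2L)
  expect_equal(length(unique(a$uls[1:3])), 1L)
  expect_equal(length(unique(a$uls[4:6])), 1L)
  expect_false(any(a$singleton))

  # all points identical -> one ULS
  b <- cluster_uls(matrix(1, 5, 3))
  expect_equal(length(unique(b$uls)), 1L)

  # tight pair + far outlier -> pair clustered, outlier singleton
  d <- cluster_uls(rbind(c(0, 0, 0), c(0.1, 0, 0), c(50, 0, 0)))
  expect_equal(d$uls[1], d$uls[2])
  expect_true(d$singleton[3])
  expect_false(d$uls[3] %in% d$uls[1:2])

  # fewer points than min_cluster_size -> all singletons
  e <- cluster_uls(matrix(rnorm(3), 1, 3), min_cluster_size = 2)
  expect_true(all(e$singleton))
})

test_that("clustering is invariant under rotation of score space", {
  set.seed(13)
  sc <- rbind(matrix(rnorm(12, 0, 0.3), 4),
              sweep(matrix(rnorm(12, 0, 0.3), 4), 2, c(-8, 0, 0)),
              sweep(matrix(rnorm(12, 0, 0.3), 4), 2, c(0, -8, 0)))
  base <- cluster_uls(sc)$uls
  for (i in 1:5) {
    R <- random_rotation()
    rot <- cluster_uls(sc %*% R)$uls
    expect_equal(mclust::adjustedRandIndex(base, rot), 1.0)
  }
})

test_that("presence matrix records mean probabilities per replicate", {
  assign <- cluster_uls(rbind(c(0, 0), c(0.1, 0), c(10, 0), c(10.1, 0)),
                        state_ids = c("a", "b", "c", "d"))
  meta <- data.frame(state = c("a", "b", "c", "d"),
                     scheme = "s",
                     replicate = c(1, 1, 1, 2),
                     probability = c(0.2, 0.4, 0.3, 0.9))
  pm <- presence_matrix(assign, meta)
  uls_ab <- paste0("ULS", assign$uls[1])
  uls_cd <- paste0("ULS", assign$uls[3])
  expect_equal(pm[uls_ab, "s.1"], 0.3)       # mean of 0.2 and 0.4
  expect_equal(pm[uls_cd, "s.1"], 0.3)
  expect_equal(pm[uls_cd, "s.2"], 0.9)
  expect_true(is.na(pm[uls_ab, "s.2"]))

  # without probabilities: member counts
  pm2 <- presence_matrix(assign, meta[, 1:3])
  expect_equal(pm2[uls_ab, "s.1"], 2)
})

test_that("planted fingerprint profiles are recovered exactly across replicates", {
  profiles <- rbind(bound = c(2, 4, 11, 13, 15),
                    tunnel = c(10, 2, 6, 9, 12),
                    bulk = c(25, 14, 12, 10, 9))
  gen <- generate_metastable_ensembles(profiles, noise_sd = 0.2,
                                       n_reps = 3, n_frames = 150,
                                       seed = 21)
  Fm <- t(vapply(gen$ensembles, function(e) state_fingerprint(e$data),
                 numeric(20)))
  rownames(Fm) <- gen$metadata$state
  red <- reduce_fingerprints(Fm)
  a <- cluster_uls(red$scores)
  expect_equal(mclust::adjustedRandIndex(a$uls, gen$planted), 1.0)
})
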
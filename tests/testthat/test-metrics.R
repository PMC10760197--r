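test_that("neighbor loss: hand values, degenerate cases and invariances", {
  expect_equal(neighbor_loss(matrix(c(1, 1, 1, 2, 2, 2), 3)), 0)
  Z <- rbind(c(0, 0), c(3, 4))
  expect_equal(neighbor_loss(Z), 2)                 # 5 / ((0 + 5)/2)
  expect_equal(neighbor_loss_normalized(Z), 2)      # one transition
  # duplicating the transition pattern leaves the normalized value alone
  Z4 <- rbind(c(0, 0), c(3, 4), c(0, 0), c(3, 4))
  expect_equal(neighbor_loss_normalized(Z4), 2)
  expect_error(neighbor_loss(matrix(0, 4, 2)), "zbar = 0")
  expect_error(neighbor_loss(matrix(1, 1, 2)), "at least one")
  set.seed(3)
  Z <- matrix(rnorm(60), 30)
  base <- neighbor_loss(Z)
  for (i in 1:5) {
    Q <- rand_orth(2)
    expect_lt(abs(neighbor_loss(Z %*% Q * runif(1, 0.1, 10)) - base), 1e-10)
  }
  # gaps exclude their transition
  tr <- latent_trajectory(rbind(c(0, 0), c(3, 4), c(3, 4)), gaps = 0L)
  expect_equal(neighbor_loss(tr), 0)                # only the 1->2 step left
})

test_that("neighbor loss scales linearly in N on a stationary trajectory, its per-transition variant stabilizes", {
  set.seed(5)
  Z <- matrix(rnorm(2e4), ncol = 2)                 # iid points: stationary
  raw_small <- neighbor_loss(Z[1:2000, ])
  raw_big <- neighbor_loss(Z)
  expect_gt(raw_big / raw_small, 4)
  expect_lt(raw_big / raw_small, 6.5)
  expect_lt(abs(neighbor_loss_normalized(Z) /
                neighbor_loss_normalized(Z[1:2000, ]) - 1), 0.05)
})

test_that("ranking by summed step length matches Gaussian random-walk log-likelihood ranking", {
  set.seed(8)
  sds <- c(0.05, 0.1, 0.3, 0.6, 1, 1.5, 2.5, 4)
  sum_abs <- loglik <- numeric(length(sds))
  for (i in seq_along(sds)) {
    steps <- matrix(rnorm(500 * 2, sd = sds[i]), ncol = 2)
    Z <- apply(steps, 2, cumsum)
    d2 <- rowSums(steps^2)
    sum_abs[i] <- sum(sqrt(d2))
    loglik[i] <- sum(-d2 / 2 - log(2 * pi))   # unit step variance held fixed
  }
  expect_identical(order(sum_abs), order(-loglik))
})

test_that("silhouette matches the hand example and the brute-force oracle", {
  Z <- rbind(c(0, 0), c(0, 1), c(10, 0), c(10, 1))
  lab <- c(1, 1, 2, 2)
  r <- silhouette_score(Z, lab)
  b_hand <- (10 + sqrt(101)) / 2
  expect_equal(r$per_sample$a, rep(1, 4))
  expect_equal(r$per_sample$b, rep(b_hand, 4))
  expect_equal(r$score, (b_hand - 1) / b_hand, tolerance = 1e-12)
  expect_equal(r$score, sil_brute(Z, lab), tolerance = 1e-12)
  # relabeling invariance
  expect_equal(silhouette_score(Z, c(7, 7, 3, 3))$score, r$score)
  # 100 random small instances vs oracle
  set.seed(21)
  for (i in 1:100) {
    n <- sample(4:50, 1); d <- sample(1:5, 1); k <- sample(2:4, 1)
    Zi <- matrix(rnorm(n * d), n)
    li <- sample(k, n, replace = TRUE)
    if (length(unique(li)) < 2) li[1] <- setdiff(1:k, li[1])[1]
    expect_equal(silhouette_score(Zi, li)$score, sil_brute(Zi, li),
                 tolerance = 1e-12)
  }
})

test_that("silhouette edge cases: tight far clusters, singletons, one cluster", {
  Z <- rbind(matrix(rnorm(40, sd = 1e-3), ncol = 2),
             matrix(rnorm(40, sd = 1e-3), ncol = 2) + 1e6)
  expect_gt(silhouette_score(Z, rep(1:2, each = 20))$score, 0.999)
  r <- silhouette_score(rbind(c(0, 0), c(5, 5), c(5, 6)), c(1, 2, 2))
  expect_identical(r$per_sample$s[1], 0)            # singleton convention
  expect_error(silhouette_score(matrix(0, 3, 2), c(1, 1, 1)),
               "one cluster")
})

test_that("procrustes distance: invariances, symmetry, grid-search oracle", {
  set.seed(13)
  A <- matrix(rnorm(10), 5)
  expect_lt(procrustes_distance(A, A), 1e-12)
  th <- 1.1
  R <- matrix(c(cos(th), sin(th), -sin(th), cos(th)), 2) %*% diag(c(1, -1))
  B <- 3 * (A %*% R) + matrix(rep(c(5, -2), each = 5), 5)
  expect_lt(procrustes_distance(A, B), 1e-10)
  for (i in 1:20) {
    A <- matrix(rnorm(16), 8); B <- matrix(rnorm(16), 8)
    expect_lt(abs(procrustes_distance(A, B) - procrustes_distance(B, A)),
              1e-12)
  }
  for (i in 1:5) {
    A <- matrix(rnorm(10), 5); B <- matrix(rnorm(10), 5)
    expect_equal(procrustes_distance(A, B), procrustes_grid(A, B),
                 tolerance = 1e-6)
  }
  expect_error(procrustes_distance(matrix(0, 3, 2), matrix(0, 4, 2)),
               "shape mismatch")
  expect_error(procrustes_distance(matrix(1, 5, 2), matrix(rnorm(10), 5)),
               "zero-variance")
})

test_that("encoding distance: self zero, similarity-invariant, positive for unrelated models", {
  ts <- tiny_hmm(200, seed = 1)
  m1 <- init_vae(vae_config(seed = 11, layer_dim = 16, predictive = FALSE), 31)
  m2 <- init_vae(vae_config(seed = 12, layer_dim = 16, predictive = FALSE), 31)
  expect_lt(encoding_distance(m1, m1, ts), 1e-12)
  th <- 0.7
  R <- matrix(c(cos(th), sin(th), -sin(th), cos(th)), 2)
  m3 <- m1
  m3$par$mW <- m1$par$mW %*% R
  m3$par$mb <- as.vector(m1$par$mb %*% R)
  expect_lt(encoding_distance(m1, m3, ts), 1e-8)
  expect_gt(encoding_distance(m1, m2, ts), 0.05)
  # TN-VAE vs VAE trajectories align on their shared time indices
  m4 <- init_vae(vae_config(seed = 11, layer_dim = 16, predictive = TRUE), 31)
  expect_lt(encoding_distance(m1, m4, ts), 1)       # runs, finite
})

test_that("cluster moments: symmetry, asymptotics, exponential skew, small clusters", {
  Z <- rbind(c(-1, 0), c(1, 0), c(-2, 1), c(2, 1))  # mirrored cluster
  r <- cluster_moments(Z, rep(1, 4))
  expect_equal(r$per_cluster$skewness, c(0, 0), tolerance = 1e-12)
  set.seed(17)
  g <- matrix(rnorm(4e4), ncol = 2)
  rg <- cluster_moments(g, rep(1, 2e4))
  se_skew <- sqrt(6 / 2e4); se_kurt <- sqrt(24 / 2e4)
  expect_true(all(abs(rg$per_cluster$skewness) < 3 * se_skew))
  expect_true(all(abs(rg$per_cluster$kurtosis) < 3 * se_kurt))
  ex <- matrix(rexp(4e4), ncol = 2)
  re <- cluster_moments(ex, rep(1, 2e4))
  expect_true(all(abs(re$per_cluster$skewness - 2) < 0.2))
  r2 <- cluster_moments(rbind(g[1:10, ], c(0, 0)), c(rep(1, 10), 2))
  expect_identical(r2$missing, "2")
  expect_true(all(r2$per_cluster$cluster == "1"))
})

test_that("encode_trajectory attributes TN-VAE latents to the next time bin", {
  ts <- tiny_hmm(50, seed = 4)
  P <- matrix(rnorm(62), 31, 2)
  m <- linear_encoder_model(P, predictive = TRUE)
  tr <- encode_trajectory(m, ts)
  expect_identical(tr$t, ts$t[-1])
  expect_equal(tr$Z, ts$X[-50, ] %*% P, ignore_attr = TRUE,
               tolerance = 1e-12)
  m0 <- linear_encoder_model(P, predictive = FALSE)
  tr0 <- encode_trajectory(m0, ts)
  expect_identical(tr0$t, ts$t)
  expect_equal(tr0$Z, ts$X %*% P, ignore_attr = TRUE, tolerance = 1e-12)
})
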
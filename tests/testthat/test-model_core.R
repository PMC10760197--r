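test_that("encode: zero-weight model, determinism, and a hand linear oracle", {
  m0 <- zero_params(init_vae(vae_config(n_layers = 2, layer_dim = 8),
                             input_dim = 5))
  q <- encode(m0, matrix(rnorm(20), 4))
  expect_true(all(q$mean == 0) && all(q$log_variance == 0))

  X <- matrix(c(0.5, 1.5, 2.0, 0.25), 2, 2)  # positive: ReLU is linear
  m <- zero_params(init_vae(vae_config(n_layers = 1, layer_dim = 2,
                                       latent_dim = 2), input_dim = 2))
  W1 <- rbind(c(1, 2), c(3, 4)); Wm <- rbind(c(1, 0), c(1, -1))
  m$par$eW1 <- W1; m$par$mW <- Wm
  q <- encode(m, X)
  expect_equal(q$mean, (X %*% W1) %*% Wm, tolerance = 1e-14)  # hand product
  expect_identical(encode(m, X), encode(m, X))
  expect_error(encode(m, matrix(0, 2, 3)), "expected 2 features, got 3")
})

test_that("reparameterize follows z = mean + exp(logvar/2) * noise", {
  q <- structure(list(mean = matrix(c(1, -2), 1),
                      log_variance = matrix(c(0, log(4)), 1)),
                 class = "posterior_params")
  expect_equal(reparameterize(q, matrix(0, 1, 2)), q$mean)
  n <- matrix(c(0.3, -0.7), 1)
  q0 <- q; q0$log_variance <- matrix(0, 1, 2)
  expect_equal(reparameterize(q0, n), q$mean + n)
  # Monte-Carlo vs closed form
  set.seed(1)
  draws <- t(sapply(1:1e5, function(i)
    reparameterize(q, matrix(rnorm(2), 1))))
  se <- sqrt(c(1, 4) / 1e5)
  expect_true(all(abs(colMeans(draws) - c(1, -2)) < 3 * se))
})

test_that("decode: zero weights give the bias, hand weights give the matrix product", {
  m <- zero_params(init_vae(vae_config(n_layers = 1, layer_dim = 2,
                                       latent_dim = 2), input_dim = 3))
  m$par$ob <- c(5, 6, 7)
  expect_equal(decode(m, matrix(0, 1, 2)), matrix(c(5, 6, 7), 1),
               tolerance = 1e-14)
  V1 <- rbind(c(2, 1), c(0, 3)); Vo <- rbind(c(1, 0, 2), c(0, 1, 1))
  m$par$dW1 <- V1; m$par$oW <- Vo; m$par$ob <- numeric(3)
  Z <- matrix(c(1, 2, 0.5, 0.25), 2, 2)       # positive path through ReLU
  expect_equal(decode(m, Z), (Z %*% V1) %*% Vo, tolerance = 1e-14)
  expect_identical(decode(m, Z), decode(m, Z))
  expect_error(decode(m, matrix(0, 1, 3)), "expected 2 latent dims")
})

test_that("loss components match the closed-form KL and combine exactly", {
  # posterior forced to mu = (1, -2), logvar = (0, log 4) via head biases
  m <- zero_params(init_vae(vae_config(n_layers = 1, layer_dim = 4,
                                       latent_dim = 2, beta = 3e-4),
                            input_dim = 3))
  m$par$mb <- c(1, -2); m$par$lb <- c(0, log(4))
  x <- matrix(rnorm(6), 2)
  lc <- vae_loss(m, x, x, noise = matrix(0, 2, 2))
  kl_hand <- 0.5 * (1 + 1 - 0 - 1) + 0.5 * (4 + 4 - log(4) - 1)
  expect_equal(lc$kl, kl_hand, tolerance = 1e-12)
  expect_identical(lc$total, lc$reconstruction + 3e-4 * lc$kl)
  # q identical to prior => kl exactly 0
  m2 <- zero_params(init_vae(vae_config(n_layers = 1, layer_dim = 4,
                                        latent_dim = 2), input_dim = 3))
  expect_identical(vae_loss(m2, x, x, noise = matrix(0, 2, 2))$kl, 0)
  # 1-D latent, mu = mu0, logvar = 0 => kl = mu0^2 / 2
  m3 <- zero_params(init_vae(vae_config(n_layers = 1, layer_dim = 2,
                                        latent_dim = 1), input_dim = 3))
  m3$par$mb <- 0.7
  expect_equal(vae_loss(m3, x, x, noise = matrix(0, 2, 1))$kl, 0.7^2 / 2,
               tolerance = 1e-14)
  expect_error(vae_loss(m, x, x[1, , drop = FALSE]), "align row-for-row")
})

test_that("analytic gradients agree with finite differences", {
  set.seed(42)
  cfg <- vae_config(n_layers = 2, layer_dim = 5, latent_dim = 2,
                    beta = 0.3, seed = 3)
  m <- init_vae(cfg, input_dim = 4)
  x_in <- matrix(rnorm(12), 3); x_tg <- matrix(rnorm(12), 3)
  eps <- matrix(rnorm(6), 3)
  out <- tnvae:::vae_loss_grad(m$par, 2, x_in, x_tg, 0.3, eps)
  h <- 1e-6
  for (nm in c("eW1", "eb2", "mW", "lW", "dW1", "oW", "ob")) {
    p <- m$par
    i <- sample(length(p[[nm]]), 1)
    p[[nm]][i] <- p[[nm]][i] + h
    up <- tnvae:::vae_loss_grad(p, 2, x_in, x_tg, 0.3, eps,
                                want_grad = FALSE)$total
    p[[nm]][i] <- p[[nm]][i] - 2 * h
    dn <- tnvae:::vae_loss_grad(p, 2, x_in, x_tg, 0.3, eps,
                                want_grad = FALSE)$total
    expect_equal(out$grads[[nm]][i], (up - dn) / (2 * h), tolerance = 1e-5)
  }
})

test_that("make_pairs counts transitions and respects gaps", {
  ts <- labeled_time_series(matrix(rnorm(25), 5))
  p <- make_pairs(ts, predictive = TRUE)
  expect_identical(nrow(p$x_in), 4L)
  expect_equal(p$x_target, ts$X[2:5, ], ignore_attr = TRUE)
  p0 <- make_pairs(ts, predictive = FALSE)
  expect_identical(p0$x_in, p0$x_target)
  gapped <- labeled_time_series(matrix(rnorm(36), 6), gaps = 2L)
  pg <- make_pairs(gapped, predictive = TRUE)
  expect_identical(nrow(pg$x_in), 4L)          # transition 2 -> 3 excluded
  expect_identical(pg$t_in, c(0L, 1L, 3L, 4L))
  expect_error(make_pairs(labeled_time_series(matrix(1, 1, 1)),
                          predictive = TRUE),
               "no transitions available")
})

test_that("loss is invariant to feature permutation with permuted weights", {
  set.seed(7)
  m <- init_vae(vae_config(n_layers = 2, layer_dim = 6, seed = 2),
                input_dim = 5)
  perm <- c(3, 1, 5, 2, 4)
  mp <- m
  mp$par$eW1 <- m$par$eW1[perm, ]
  mp$par$oW <- m$par$oW[, perm]
  mp$par$ob <- m$par$ob[perm]
  X <- matrix(rnorm(40), 8)
  noise <- matrix(rnorm(16), 8)
  a <- vae_loss(m, X, X, noise = noise)
  b <- vae_loss(mp, X[, perm], X[, perm], noise = noise)
  expect_equal(b$kl, a$kl, tolerance = 1e-12)
  expect_equal(b$total, a$total, tolerance = 1e-12)
})

test_that("with tiny beta the standard objective trains like an autoencoder", {
  set.seed(11)
  n <- 400
  shift <- matrix(rep(c(3, 3, 0, 0, 0), each = n / 2), ncol = 5)
  X <- rbind(matrix(rnorm(n / 2 * 5), ncol = 5) + shift,
             matrix(rnorm(n / 2 * 5), ncol = 5) - shift)
  toy <- labeled_time_series(X[sample(n), ])
  m <- train_vae(vae_config(n_layers = 2, layer_dim = 16, beta = 1e-4,
                            batch_size = 64, learning_rate = 1e-3,
                            predictive = FALSE, seed = 1),
                 toy, split_spec(seed = 1, val_fraction = 0.25),
                 epochs = 80)
  # reconstruction beats the variance of the (normalized) data
  data_var_loss <- 0.5 * 5
  expect_lt(tail(m$history$val_loss, 1), data_var_loss)
})
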
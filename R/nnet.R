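# Internal multilayer-perceptron machinery for the (TN-)VAE.
#
# Parameters live in a flat named list of matrices/vectors:
#   eW1, eb1, ... eW{L}, eb{L}   encoder hidden layers (ReLU)
#   mW, mb                       posterior-mean head (linear)
#   lW, lb                       posterior-log-variance head (linear)
#   dW1, db1, ... dW{L}, db{L}   decoder hidden layers (ReLU)
#   oW, ob                       decoder output head (linear)
# All gradients are derived by hand; the heavy lifting is BLAS matmul
# on (batch x width) matrices.

LOGVAR_CLAMP <- 15  # |log variance| clamp for numerical stability

add_bias <- function(A, b) A + rep(b, each = nrow(A))

glorot <- function(fan_in, fan_out) {
  s <- sqrt(6 / (fan_in + fan_out))
  matrix(stats::runif(fan_in * fan_out, -s, s), fan_in, fan_out)
}

# Initialize all parameters for given widths. Consumes the current RNG
# stream (callers seed it).
vae_init_params <- function(input_dim, n_layers, layer_dim, latent_dim) {
  par <- list()
  din <- input_dim
  for (l in seq_len(n_layers)) {
    par[[paste0("eW", l)]] <- glorot(din, layer_dim)
    par[[paste0("eb", l)]] <- numeric(layer_dim)
    din <- layer_dim
  }
  par$mW <- glorot(layer_dim, latent_dim); par$mb <- numeric(latent_dim)
  par$lW <- glorot(layer_dim, latent_dim); par$lb <- numeric(latent_dim)
  din <- latent_dim
  for (l in seq_len(n_layers)) {
    par[[paste0("dW", l)]] <- glorot(din, layer_dim)
    par[[paste0("db", l)]] <- numeric(layer_dim)
    din <- layer_dim
  }
  par$oW <- glorot(layer_dim, input_dim); par$ob <- numeric(input_dim)
  par
}

# Encoder forward pass. Returns posterior parameters and, if `cache`,
# the intermediates needed for backprop.
enc_forward <- function(par, n_layers, X, cache = FALSE) {
  hs <- if (cache) vector("list", n_layers + 1) else NULL
  masks <- if (cache) vector("list", n_layers) else NULL
  h <- X
  if (cache) hs[[1]] <- h
  for (l in seq_len(n_layers)) {
    a <- add_bias(h %*% par[[paste0("eW", l)]], par[[paste0("eb", l)]])
    m <- a > 0
    h <- a * m
    if (cache) { hs[[l + 1]] <- h; masks[[l]] <- m }
  }
  mu <- add_bias(h %*% par$mW, par$mb)
  lv_raw <- add_bias(h %*% par$lW, par$lb)
  lv_ok <- abs(lv_raw) < LOGVAR_CLAMP
  lv <- pmin(pmax(lv_raw, -LOGVAR_CLAMP), LOGVAR_CLAMP)
  list(mu = mu, lv = lv, lv_ok = lv_ok, hs = hs, masks = masks)
}

# Decoder forward pass.
dec_forward <- function(par, n_layers, Z, cache = FALSE) {
  gs <- if (cache) vector("list", n_layers + 1) else NULL
  masks <- if (cache) vector("list", n_layers) else NULL
  g <- Z
  if (cache) gs[[1]] <- g
  for (l in seq_len(n_layers)) {
    a <- add_bias(g %*% par[[paste0("dW", l)]], par[[paste0("db", l)]])
    m <- a > 0
    g <- a * m
    if (cache) { gs[[l + 1]] <- g; masks[[l]] <- m }
  }
  xhat <- add_bias(g %*% par$oW, par$ob)
  list(xhat = xhat, gs = gs, masks = masks)
}

# One full loss evaluation; optionally with gradients for every
# parameter. `eps` is the standard-normal reparameterization draw
# (same shape as the posterior mean). Loss convention:
#   reconstruction = 0.5 * ||x_target - xhat||^2 summed over features,
#                    averaged over the batch (unit-variance Gaussian
#                    likelihood up to an additive constant)
#   kl            = 0.5 * sum(mu^2 + sigma^2 - log sigma^2 - 1) summed
#                    over latent dims, averaged over the batch
#   total         = reconstruction + beta * kl
vae_loss_grad <- function(par, n_layers, x_in, x_target, beta, eps,
                          want_grad = TRUE) {
  n <- nrow(x_in)
  ef <- enc_forward(par, n_layers, x_in, cache = want_grad)
  mu <- ef$mu; lv <- ef$lv
  sd_ <- exp(lv / 2)
  z <- mu + sd_ * eps
  df <- dec_forward(par, n_layers, z, cache = want_grad)
  resid <- df$xhat - x_target
  recon <- 0.5 * sum(resid * resid) / n
  expo <- exp(lv)
  kl <- 0.5 * sum(mu * mu + expo - lv - 1) / n
  total <- recon + beta * kl
  out <- list(reconstruction = recon, kl = kl, total = total)
  if (!want_grad) return(out)

  g <- list()
  # decoder backward
  d <- resid / n                      # dL/dxhat
  g$oW <- crossprod(df$gs[[n_layers + 1]], d)
  g$ob <- colSums(d)
  dg <- tcrossprod(d, par$oW)
  for (l in rev(seq_len(n_layers))) {
    da <- dg * df$masks[[l]]
    g[[paste0("dW", l)]] <- crossprod(df$gs[[l]], da)
    g[[paste0("db", l)]] <- colSums(da)
    dg <- tcrossprod(da, par[[paste0("dW", l)]])
  }
  dz <- dg
  # heads backward (KL gradients join here)
  dmu <- dz + beta * mu / n
  dlv <- (dz * eps * (sd_ / 2) + beta * 0.5 * (expo - 1) / n) * ef$lv_ok
  hL <- ef$hs[[n_layers + 1]]
  g$mW <- crossprod(hL, dmu); g$mb <- colSums(dmu)
  g$lW <- crossprod(hL, dlv); g$lb <- colSums(dlv)
  dh <- tcrossprod(dmu, par$mW) + tcrossprod(dlv, par$lW)
  for (l in rev(seq_len(n_layers))) {
    da <- dh * ef$masks[[l]]
    g[[paste0("eW", l)]] <- crossprod(ef$hs[[l]], da)
    g[[paste0("eb", l)]] <- colSums(da)
    dh <- tcrossprod(da, par[[paste0("eW", l)]])
  }
  out$grads <- g
  out
}

adam_init <- function(par) {
  zero <- lapply(par, function(p) p * 0)
  list(m = zero, v = zero, t = 0L)
}

adam_step <- function(par, grads, state, lr, beta1 = 0.9, beta2 = 0.999,
                      eps = 1e-8) {
  state$t <- state$t + 1L
  c1 <- 1 - beta1^state$t
  c2 <- 1 - beta2^state$t
  for (nm in names(par)) {
    gg <- grads[[nm]]
    state$m[[nm]] <- beta1 * state$m[[nm]] + (1 - beta1) * gg
    state$v[[nm]] <- beta2 * state$v[[nm]] + (1 - beta2) * gg * gg
    par[[nm]] <- par[[nm]] -
      lr * (state$m[[nm]] / c1) / (sqrt(state$v[[nm]] / c2) + eps)
  }
  list(par = par, state = state)
}
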
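# Hand-constructable models for metric and selection tests.

# A model whose posterior mean is exactly X %*% P (log variance 0),
# built from one ReLU hidden layer via the (relu(x) - relu(-x)) = x
# identity. P is input_dim x latent_dim.
linear_encoder_model <- function(P, predictive = FALSE, seed = 1) {
  d <- nrow(P); k <- ncol(P)
  m <- init_vae(vae_config(n_layers = 1, layer_dim = 2 * k,
                           latent_dim = k, predictive = predictive,
                           seed = seed), input_dim = d)
  m$par$eW1 <- cbind(P, -P)
  m$par$eb1 <- numeric(2 * k)
  m$par$mW <- rbind(diag(k), -diag(k))
  m$par$mb <- numeric(k)
  m$par$lW <- matrix(0, 2 * k, k)
  m$par$lb <- numeric(k)
  m
}

# Zero out every parameter of a model (posterior mean/logvar heads
# return exactly the biases).
zero_params <- function(m) {
  m$par <- lapply(m$par, function(p) p * 0)
  m
}

# Attach a fabricated one-epoch history so selection functions can run.
with_history <- function(m, val_loss, val_nl) {
  m$history <- data.frame(epoch = 1L, train_loss = val_loss,
                          val_loss = val_loss, val_nl = val_nl)
  m$epochs_trained <- 1L
  m
}

# Small fast HMM series shared by several files.
tiny_hmm <- function(n = 600, seed = 1) {
  simulate_hmm(hmm_sleep_preset(), n, seed = seed)
}
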
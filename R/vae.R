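#' VAE / TN-VAE hyperparameter configuration
#'
#' One point of the hyperparameter grid. `predictive = FALSE` gives the
#' standard VAE (the decoder reconstructs the encoded point x_t);
#' `predictive = TRUE` gives the Time-Neighbor VAE, whose encoder of
#' x_t parameterizes the posterior over the *next* latent and whose
#' decoder predicts x_{t+1}. The architecture is otherwise identical:
#' `n_layers` ReLU hidden layers of width `layer_dim` in both encoder
#' and decoder, linear posterior mean / log-variance heads and a linear
#' decoder output, a standard-normal prior, and a KL weight `beta`
#' (beta-VAE convention, interpreted relative to a unit-variance
#' Gaussian likelihood averaged over the batch).
#'
#' @param n_layers hidden layers per coder (typical grid 2-4).
#' @param layer_dim units per hidden layer (typical grid 50-400).
#' @param latent_dim latent dimensionality (default 2).
#' @param beta KL weight (typical grid 1e-4 to 1e-3).
#' @param batch_size samples per gradient step.
#' @param learning_rate Adam step size (typical grid 1e-5 to 1e-3).
#' @param seed integer controlling parameter initialization (combined
#'   with the split seed during training).
#' @param predictive logical; FALSE = standard VAE, TRUE = TN-VAE.
#' @param n_mc Monte-Carlo samples per datum for the loss expectation.
#' @return Object of class `tnvae_config`.
#' @export
vae_config <- function(n_layers = 2, layer_dim = 100, latent_dim = 2,
                       beta = 1e-4, batch_size = 256,
                       learning_rate = 1e-3, seed = 1,
                       predictive = TRUE, n_mc = 1) {
  stopifnot(n_layers >= 1, layer_dim >= 1, latent_dim >= 1,
            batch_size >= 1, n_mc >= 1)
  if (beta <= 0) stop("`beta` must be > 0")
  if (learning_rate <= 0) stop("`learning_rate` must be > 0")
  structure(list(n_layers = as.integer(n_layers),
                 layer_dim = as.integer(layer_dim),
                 latent_dim = as.integer(latent_dim),
                 beta = beta, batch_size = as.integer(batch_size),
                 learning_rate = learning_rate, seed = as.integer(seed),
                 predictive = isTRUE(predictive), n_mc = as.integer(n_mc)),
            class = "tnvae_config")
}

#' @export
print.tnvae_config <- function(x, ...) {
  cat(sprintf(
    "<tnvae_config> %s | layers=%d dim=%d latent=%d beta=%g batch=%d lr=%g seed=%d\n",
    if (x$predictive) "TN-VAE" else "VAE", x$n_layers, x$layer_dim,
    x$latent_dim, x$beta, x$batch_size, x$learning_rate, x$seed))
  invisible(x)
}

#' Initialize an untrained model
#'
#' Glorot-uniform weights, zero biases; the draw is controlled by
#' `config$seed` so initialization is reproducible.
#'
#' @param config a [vae_config()].
#' @param input_dim number of observed features D.
#' @param normalizer optional list(mean, sd) applied to inputs before
#'   encoding (fitted on the training split by [train_vae()]).
#' @return Object of class `tnvae_model`.
#' @export
init_vae <- function(config, input_dim = 31, normalizer = NULL) {
  stopifnot(inherits(config, "tnvae_config"))
  set.seed(config$seed)
  par <- vae_init_params(input_dim, config$n_layers, config$layer_dim,
                         config$latent_dim)
  structure(list(config = config, par = par,
                 input_dim = as.integer(input_dim),
                 normalizer = normalizer,
                 history = empty_history(), epochs_trained = 0L),
            class = "tnvae_model")
}

empty_history <- function() {
  data.frame(epoch = integer(0), train_loss = numeric(0),
             val_loss = numeric(0), val_nl = numeric(0))
}

#' @export
print.tnvae_model <- function(x, ...) {
  print(x$config)
  cat(sprintf("  input dim %d, trained %d epoch(s)\n", x$input_dim,
              x$epochs_trained))
  if (nrow(x$history)) {
    h <- x$history[nrow(x$history), ]
    cat(sprintf("  final: train %.4f | val %.4f | val NL %.4f\n",
                h$train_loss, h$val_loss, h$val_nl))
  }
  invisible(x)
}

as_feature_matrix <- function(X) {
  if (inherits(X, "labeled_ts")) X <- X$X
  if (is.null(dim(X))) X <- matrix(X, nrow = 1)
  X
}

normalize_input <- function(model, X) {
  if (is.null(model$normalizer)) return(X)
  sweep(sweep(X, 2, model$normalizer$mean, "-"), 2,
        model$normalizer$sd, "/")
}

check_input_dim <- function(model, X, what = "X") {
  if (ncol(X) != model$input_dim)
    stop(sprintf("dimension mismatch in `%s`: expected %d features, got %d",
                 what, model$input_dim, ncol(X)))
}

#' Encode observations into posterior parameters
#'
#' Deterministic map from observation rows to the diagonal-Gaussian
#' posterior parameters (mean, log variance). For a TN-VAE the
#' posterior parameterized by row x_t is over the *next* latent
#' z_{t+1}; the caller owns that attribution (see
#' [encode_trajectory()]).
#'
#' @param model a `tnvae_model`.
#' @param X matrix of observation rows (or a `labeled_ts`). Inputs are
#'   passed through the model's normalizer if one is fitted.
#' @return list of class `posterior_params` with matrices `mean` and
#'   `log_variance`, one row per input row.
#' @export
encode <- function(model, X) {
  X <- as_feature_matrix(X)
  check_input_dim(model, X)
  X <- normalize_input(model, X)
  ef <- enc_forward(model$par, model$config$n_layers, X)
  structure(list(mean = ef$mu, log_variance = ef$lv),
            class = "posterior_params")
}

#' Reparameterized sampling from a diagonal-Gaussian posterior
#'
#' z = mean + exp(log_variance / 2) * noise.
#'
#' @param q a `posterior_params` object.
#' @param noise standard-normal draws, same shape as `q$mean`; drawn
#'   from the current RNG stream when omitted.
#' @return matrix of latent samples.
#' @export
reparameterize <- function(q, noise = NULL) {
  if (is.null(noise))
    noise <- matrix(stats::rnorm(length(q$mean)), nrow(q$mean))
  if (!all(dim(noise) == dim(q$mean)))
    stop("`noise` shape must match the posterior parameters")
  q$mean + exp(q$log_variance / 2) * noise
}

#' Decode latent points into reconstruction means
#'
#' Deterministic decoder mean in the model's (normalized) feature
#' space.
#'
#' @param model a `tnvae_model`.
#' @param Z matrix of latent rows.
#' @return matrix with `input_dim` columns.
#' @export
decode <- function(model, Z) {
  if (is.null(dim(Z))) Z <- matrix(Z, nrow = 1)
  if (ncol(Z) != model$config$latent_dim)
    stop(sprintf("dimension mismatch in `Z`: expected %d latent dims, got %d",
                 model$config$latent_dim, ncol(Z)))
  dec_forward(model$par, model$config$n_layers, Z)$xhat
}

#' Evaluate the training objective on a batch
#'
#' reconstruction = Gaussian negative log-likelihood of `x_target`
#' given the decoded sample, up to an additive constant (0.5 * squared
#' error summed over features, averaged over the batch); kl =
#' closed-form KL between the diagonal-Gaussian posterior and the
#' standard-normal prior, summed over latent dimensions and averaged
#' over the batch; total = reconstruction + beta * kl. A standard VAE
#' passes `x_target = x_in`; the TN-VAE passes the next-time rows.
#'
#' @param model a `tnvae_model`.
#' @param x_in,x_target row-aligned observation batches.
#' @param beta KL weight; defaults to the model's configured beta.
#' @param noise optional standard-normal draws for the reparameterized
#'   sample (batch x latent_dim); drawn from the RNG stream if omitted.
#' @return list of class `loss_components` with fields
#'   `reconstruction`, `kl`, `total`.
#' @export
vae_loss <- function(model, x_in, x_target, beta = model$config$beta,
                     noise = NULL) {
  x_in <- as_feature_matrix(x_in); x_target <- as_feature_matrix(x_target)
  if (nrow(x_in) != nrow(x_target))
    stop(sprintf("`x_in` and `x_target` must align row-for-row (%d vs %d)",
                 nrow(x_in), nrow(x_target)))
  check_input_dim(model, x_in, "x_in")
  check_input_dim(model, x_target, "x_target")
  x_in <- normalize_input(model, x_in)
  x_target <- normalize_input(model, x_target)
  if (is.null(noise))
    noise <- matrix(stats::rnorm(nrow(x_in) * model$config$latent_dim),
                    nrow(x_in))
  out <- vae_loss_grad(model$par, model$config$n_layers, x_in, x_target,
                       beta, noise, want_grad = FALSE)
  structure(out, class = "loss_components")
}

#' Build (input, target) training pairs from a time series
#'
#' For a predictive (TN-VAE) objective, one pair (x_t, x_{t+1}) per
#' observed transition: N - 1 pairs per contiguous segment, and pairs
#' never span a recorded gap. For the standard objective, each row is
#' its own target.
#'
#' @param ts a `labeled_ts`.
#' @param predictive logical; see [vae_config()].
#' @return list with matrices `x_in`, `x_target` and the 0-based
#'   transition origins `t_in` (predictive) or time indices (standard).
#' @export
make_pairs <- function(ts, predictive = TRUE) {
  if (predictive) {
    if (n_bins(ts) < 2) stop("no transitions available")
    tr <- transition_index(ts)
    if (!length(tr)) stop("no transitions available")
    i <- match(tr, ts$t)
    list(x_in = ts$X[i, , drop = FALSE],
         x_target = ts$X[i + 1L, , drop = FALSE], t_in = tr)
  } else {
    list(x_in = ts$X, x_target = ts$X, t_in = ts$t)
  }
}
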
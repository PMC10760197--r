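#' Train / validation / test split specification
#'
#' The test set is a contiguous terminal block of transitions,
#' identical across all seeds, so that encoding distances between
#' models trained under different seeds compare like with like. The
#' remaining transitions are partitioned into train and validation at
#' random by `seed`.
#'
#' @param seed integer controlling the train/validation partition (and,
#'   through [run_ensemble()], model initialization).
#' @param val_fraction fraction of the non-test transitions held out
#'   for validation, in (0, 1).
#' @param test_fraction fraction of all transitions held out as the
#'   terminal test block, in (0, 1).
#' @return Object of class `tnvae_split_spec`.
#' @export
split_spec <- function(seed = 1, val_fraction = 0.2, test_fraction = 0.2) {
  if (val_fraction <= 0 || val_fraction >= 1 ||
      test_fraction <= 0 || test_fraction >= 1 ||
      val_fraction + test_fraction >= 1)
    stop("fractions must lie in (0,1) and sum to less than 1")
  structure(list(seed = as.integer(seed), val_fraction = val_fraction,
                 test_fraction = test_fraction),
            class = "tnvae_split_spec")
}

#' Split a series into train / validation / test transitions
#'
#' @param ts a `labeled_ts`.
#' @param spec a [split_spec()].
#' @return list of class `tnvae_split` with integer vectors `train`,
#'   `val`, `test` of 0-based transition origins, and `test_rows`
#'   (1-based row positions of the test block, for encoding).
#' @export
split_series <- function(ts, spec) {
  stopifnot(inherits(spec, "tnvae_split_spec"))
  tr <- transition_index(ts)
  ntr <- length(tr)
  n_test <- round(spec$test_fraction * ntr)
  if (n_test < 1 || n_test >= ntr)
    stop(sprintf("cannot split %d transitions into test fraction %g",
                 ntr, spec$test_fraction))
  test <- tr[(ntr - n_test + 1L):ntr]
  rem <- tr[seq_len(ntr - n_test)]
  n_val <- round(spec$val_fraction * length(rem))
  if (n_val < 1 || n_val >= length(rem))
    stop(sprintf("empty split part: %d transitions, %d test, %d val",
                 ntr, n_test, n_val))
  set.seed(spec$seed)
  val <- sort(sample(rem, n_val))
  train <- setdiff(rem, val)
  first_test_row <- match(test[1], ts$t)
  structure(list(spec = spec, train = train, val = val, test = test,
                 n_transitions = ntr,
                 test_rows = first_test_row:(match(test[n_test], ts$t) + 1L)),
            class = "tnvae_split")
}

#' Extract the held-out test block as a series
#'
#' @param ts the full `labeled_ts`.
#' @param split a `tnvae_split` (or a [split_spec()], which is resolved
#'   first; the test block does not depend on the seed).
#' @return a `labeled_ts` covering the terminal test block.
#' @export
test_block <- function(ts, split) {
  if (inherits(split, "tnvae_split_spec")) split <- split_series(ts, split)
  subset_series(ts, split$test_rows)
}

# --- internal per-epoch validation plans -------------------------------

# Rows (1-based) feeding each validation-loss pair.
val_loss_plan <- function(ts, split, predictive) {
  r <- match(split$val, ts$t)
  list(in_rows = r, tgt_rows = if (predictive) r + 1L else r)
}

# Latent attribution for validation NL (metrics-module convention:
# a TN-VAE's encoder of x_t parameterizes z_{t+1}). For each usable
# validation transition t the step is z_t -> z_{t+1}; rows holds the
# unique rows to encode, ia/ib index the two endpoints of each step.
val_nl_plan <- function(ts, split, predictive) {
  t_ok <- if (predictive) split$val[split$val >= 1L] else split$val
  r <- match(t_ok, ts$t)
  ra <- if (predictive) r - 1L else r
  rb <- if (predictive) r else r + 1L
  rows <- sort(unique(c(ra, rb)))
  list(rows = rows, ia = match(ra, rows), ib = match(rb, rows))
}

#' Train a single VAE / TN-VAE
#'
#' Stochastic gradient optimization (Adam) of the beta-weighted ELBO
#' over the training transitions, with one reparameterization sample
#' per datum per step. A per-feature z-score normalizer is fitted on
#' the training rows only and stored with the model. After every epoch
#' the validation loss and validation Neighbor Loss are appended to the
#' history. Fully reproducible given (`config$seed`, `spec$seed`).
#'
#' @param config a [vae_config()].
#' @param ts a `labeled_ts`.
#' @param spec a [split_spec()].
#' @param epochs number of epochs (0 returns the initialized model
#'   with an empty history).
#' @return a `tnvae_model` with `history` and `split` attached.
#' @export
train_vae <- function(config, ts, spec, epochs = 100) {
  stopifnot(inherits(config, "tnvae_config"))
  split <- split_series(ts, spec)
  predictive <- config$predictive
  L <- config$n_layers

  train_in <- match(split$train, ts$t)
  train_tgt <- if (predictive) train_in + 1L else train_in
  mu_f <- colMeans(ts$X[train_in, , drop = FALSE])
  sd_f <- pmax(apply(ts$X[train_in, , drop = FALSE], 2, stats::sd), 1e-8)
  Xn <- sweep(sweep(ts$X, 2, mu_f, "-"), 2, sd_f, "/")

  set.seed((config$seed * 100003 + spec$seed * 7919) %% 2147483647L)
  par <- vae_init_params(ncol(Xn), L, config$layer_dim, config$latent_dim)

  model <- structure(
    list(config = config, par = par, input_dim = ncol(Xn),
         normalizer = list(mean = mu_f, sd = sd_f),
         history = empty_history(), epochs_trained = 0L, split = split),
    class = "tnvae_model")
  if (epochs == 0) return(model)

  vl <- val_loss_plan(ts, split, predictive)
  vn <- val_nl_plan(ts, split, predictive)
  Xval_in <- Xn[vl$in_rows, , drop = FALSE]
  Xval_tgt <- Xn[vl$tgt_rows, , drop = FALSE]
  Xnl <- Xn[vn$rows, , drop = FALSE]

  st <- adam_init(par)
  n_train <- length(train_in)
  bs <- min(config$batch_size, n_train)
  dz <- config$latent_dim
  hist <- matrix(NA_real_, epochs, 3)

  for (e in seq_len(epochs)) {
    ord <- sample.int(n_train)
    tl <- 0
    nb <- 0L
    for (start in seq(1L, n_train, by = bs)) {
      b <- ord[start:min(start + bs - 1L, n_train)]
      eps <- matrix(stats::rnorm(length(b) * dz), length(b))
      out <- vae_loss_grad(par, L, Xn[train_in[b], , drop = FALSE],
                           Xn[train_tgt[b], , drop = FALSE],
                           config$beta, eps)
      up <- adam_step(par, out$grads, st, config$learning_rate)
      par <- up$par; st <- up$state
      tl <- tl + out$total * length(b)
      nb <- nb + length(b)
    }
    train_loss <- tl / nb
    eps_v <- matrix(stats::rnorm(nrow(Xval_in) * dz), nrow(Xval_in))
    vloss <- vae_loss_grad(par, L, Xval_in, Xval_tgt, config$beta,
                           eps_v, want_grad = FALSE)$total
    MU <- enc_forward(par, L, Xnl)$mu
    zbar <- mean(row_norms(MU))
    vnl <- if (zbar > 0) {
      sum(row_norms(MU[vn$ib, , drop = FALSE] -
                    MU[vn$ia, , drop = FALSE])) / zbar
    } else NA_real_
    if (!is.finite(train_loss) || !is.finite(vloss))
      stop(sprintf(
        "non-finite loss at epoch %d (layers=%d dim=%d beta=%g lr=%g seed=%d)",
        e, L, config$layer_dim, config$beta, config$learning_rate,
        config$seed))
    hist[e, ] <- c(train_loss, vloss, vnl)
  }
  model$par <- par
  model$epochs_trained <- as.integer(epochs)
  model$history <- data.frame(epoch = seq_len(epochs),
                              train_loss = hist[, 1], val_loss = hist[, 2],
                              val_nl = hist[, 3])
  model
}

#' Expand named hyperparameter axes into a configuration grid
#'
#' Full Cartesian product in deterministic order (first axis varies
#' fastest). Axis names must be [vae_config()] argument names.
#'
#' @param axes named list of value vectors.
#' @param base a [vae_config()] supplying every field not on an axis.
#' @return named list of `tnvae_config`s (`cfg001`, `cfg002`, ...).
#' @export
expand_config_grid <- function(axes, base = vae_config()) {
  valid <- setdiff(names(formals(vae_config)), character(0))
  if (!length(axes) || is.null(names(axes)) || any(names(axes) == ""))
    stop("`axes` must be a named list")
  bad <- setdiff(names(axes), valid)
  if (length(bad))
    stop("unknown axis name(s) ", paste(bad, collapse = ", "),
         "; valid names: ", paste(valid, collapse = ", "))
  if (any(!lengths(axes)))
    stop("every axis must be nonempty")
  g <- expand.grid(axes, KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  configs <- lapply(seq_len(nrow(g)), function(i) {
    args <- as.list(base)
    args[names(g)] <- as.list(g[i, , drop = FALSE])
    do.call(vae_config, args)
  })
  names(configs) <- sprintf("cfg%03d", seq_along(configs))
  configs
}

#' Train an ensemble over a configuration grid
#'
#' One model per (configuration, seed) cell; the seed determines both
#' the train/validation partition and parameter initialization. When
#' `out_dir` is given, each cell is checkpointed as an RDS file and a
#' JSON manifest is updated incrementally, so an interrupted run can be
#' resumed (`resume = TRUE` completes only missing cells). A failing
#' cell is recorded in the manifest and the run continues.
#'
#' @param grid named list of [vae_config()]s (see
#'   [expand_config_grid()]).
#' @param ts a `labeled_ts`.
#' @param seeds integer vector of split/init seeds.
#' @param epochs epochs per model.
#' @param val_fraction,test_fraction split fractions (see
#'   [split_spec()]).
#' @param out_dir optional checkpoint directory.
#' @param resume logical; reuse completed checkpoints in `out_dir`.
#' @param verbose print one line per cell.
#' @return list of class `tnvae_ensemble`: `models` (named list) and
#'   `manifest` (data.frame with one row per cell).
#' @export
run_ensemble <- function(grid, ts, seeds, epochs = 100,
                         val_fraction = 0.2, test_fraction = 0.2,
                         out_dir = NULL, resume = FALSE,
                         verbose = FALSE) {
  if (!length(grid)) stop("empty configuration grid")
  if (is.null(names(grid)))
    names(grid) <- sprintf("cfg%03d", seq_along(grid))
  if (!is.null(out_dir) && !dir.exists(out_dir))
    dir.create(out_dir, recursive = TRUE)
  cells <- expand.grid(config_id = names(grid), seed = seeds,
                       KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  cells$cell <- sprintf("%s_s%d", cells$config_id, cells$seed)
  manifest <- data.frame(cell = cells$cell, config_id = cells$config_id,
                         seed = cells$seed, status = "pending",
                         error = NA_character_, file = NA_character_,
                         stringsAsFactors = FALSE)
  models <- list()
  for (i in seq_len(nrow(cells))) {
    id <- cells$cell[i]
    file <- if (!is.null(out_dir)) file.path(out_dir, paste0(id, ".rds"))
    if (resume && !is.null(out_dir) && file.exists(file)) {
      models[[id]] <- readRDS(file)
      manifest$status[i] <- "cached"
      manifest$file[i] <- file
    } else {
      cfg <- grid[[cells$config_id[i]]]
      cfg$seed <- as.integer(cells$seed[i])
      res <- tryCatch(
        train_vae(cfg, ts,
                  split_spec(seed = cells$seed[i],
                             val_fraction = val_fraction,
                             test_fraction = test_fraction),
                  epochs = epochs),
        error = function(e) e)
      if (inherits(res, "error")) {
        manifest$status[i] <- "failed"
        manifest$error[i] <- conditionMessage(res)
      } else {
        res$config_id <- cells$config_id[i]
        res$cell_id <- id
        models[[id]] <- res
        manifest$status[i] <- "done"
        if (!is.null(out_dir)) {
          saveRDS(res, file)
          manifest$file[i] <- file
        }
      }
    }
    if (!is.null(out_dir))
      jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                           dataframe = "rows", na = "null")
    if (verbose)
      message(sprintf("[%d/%d] %s: %s", i, nrow(cells), id,
                      manifest$status[i]))
  }
  structure(list(models = models, manifest = manifest),
            class = "tnvae_ensemble")
}
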
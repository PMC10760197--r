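# Model selection and ensemble-level analyses: which selection
# criterion (validation loss vs Neighbor Loss) picks models whose
# latent spaces match the generative structure and reproduce across
# seeds.

as_model_list <- function(models) {
  if (inherits(models, "tnvae_ensemble")) models <- models$models
  if (inherits(models, "tnvae_model")) models <- list(models)
  if (!length(models)) stop("empty ensemble")
  if (is.null(names(models)))
    names(models) <- vapply(seq_along(models), function(i) {
      m <- models[[i]]
      if (!is.null(m$cell_id)) m$cell_id else sprintf("model%03d", i)
    }, "")
  models
}

final_criteria <- function(models) {
  models <- as_model_list(models)
  rows <- lapply(names(models), function(id) {
    m <- models[[id]]
    if (!nrow(m$history))
      stop("model `", id, "` has no training history")
    h <- m$history[nrow(m$history), ]
    data.frame(id = id,
               config_id = if (!is.null(m$config_id)) m$config_id
                           else NA_character_,
               seed = m$config$seed, val_loss = h$val_loss,
               val_nl = h$val_nl, stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

criterion_column <- function(criterion) {
  switch(match.arg(criterion, c("neighbor_loss", "val_loss")),
         neighbor_loss = "val_nl", val_loss = "val_loss")
}

#' Select the best model from an ensemble
#'
#' Argmin of the final-epoch criterion (`val_loss` = validation loss,
#' `neighbor_loss` = validation Neighbor Loss). Exact ties are broken
#' by the other criterion, then by ensemble order, so selection is
#' deterministic and invariant to reordering up to the documented tie
#' rule.
#'
#' @param models a `tnvae_ensemble` or (named) list of `tnvae_model`s.
#' @param criterion `"neighbor_loss"` or `"val_loss"`.
#' @return the id (name) of the selected model.
#' @export
select_model <- function(models, criterion = c("neighbor_loss",
                                               "val_loss")) {
  fin <- final_criteria(models)
  col <- criterion_column(criterion)
  other <- setdiff(c("val_nl", "val_loss"), col)
  if (any(!is.finite(fin[[col]])))
    stop("criterion `", col, "` is not finite for model(s): ",
         paste(fin$id[!is.finite(fin[[col]])], collapse = ", "))
  fin$id[order(fin[[col]], fin[[other]])[1]]
}

spearman_or_undefined <- function(x, y, method = "spearman") {
  ok <- is.finite(x) & is.finite(y)
  x <- x[ok]; y <- y[ok]
  if (length(x) < 3 || length(unique(x)) < 2 || length(unique(y)) < 2)
    return(list(rho = NA_real_, n = length(x),
                note = "undefined (constant or too few values)"))
  list(rho = stats::cor(x, y, method = method), n = length(x), note = "")
}

model_pairs <- function(fin, pairing, max_pairs, pair_seed) {
  idx <- if (pairing == "within_config") {
    groups <- split(seq_len(nrow(fin)), fin$config_id)
    do.call(rbind, lapply(groups, function(g)
      if (length(g) >= 2) t(utils::combn(g, 2))))
  } else t(utils::combn(seq_len(nrow(fin)), 2))
  if (is.null(idx) || !nrow(idx)) return(NULL)
  if (nrow(idx) > max_pairs) {
    set.seed(pair_seed)
    idx <- idx[sample.int(nrow(idx), max_pairs), , drop = FALSE]
  }
  idx
}

#' Ensemble-level analysis of metrics, structure and robustness
#'
#' For every model: final validation loss, final validation Neighbor
#' Loss, silhouette score of its test-set encodings against
#' ground-truth labels, and per-cluster moment (skew/kurtosis)
#' summaries. For every model pair under the declared pairing policy:
#' the Procrustes encoding distance on the shared test block. Rank
#' correlations relate each selection criterion to structure recovery
#' (silhouette) and robustness (encoding distance); a constant
#' criterion is reported as undefined, never as 0.
#'
#' @param models a `tnvae_ensemble` or list of `tnvae_model`s sharing
#'   the input dimensionality.
#' @param test the held-out test block (`labeled_ts`), shared by all
#'   models.
#' @param truth_labels integer labels aligned with `test` rows;
#'   defaults to `test$labels` (use [block_labels()] for the spiral).
#' @param pairing `"within_config"` (pairs of seeds within one
#'   hyperparameter configuration, the default) or `"all"`.
#' @param method correlation type, `"spearman"` (default) or
#'   `"pearson"`.
#' @param max_pairs cap on the number of pairs; excess pairs are
#'   subsampled deterministically with `pair_seed`.
#' @param pair_seed seed for pair subsampling.
#' @return list of class `ensemble_report`: `rows`, `pairs`,
#'   `correlations`, `exclusions`, `pairing`.
#' @export
ensemble_analysis <- function(models, test, truth_labels = NULL,
                              pairing = c("within_config", "all"),
                              method = c("spearman", "pearson"),
                              max_pairs = 500, pair_seed = 1) {
  pairing <- match.arg(pairing)
  method <- match.arg(method)
  models <- as_model_list(models)
  if (is.null(truth_labels)) truth_labels <- test$labels
  if (is.null(truth_labels))
    stop("no ground-truth labels: pass `truth_labels` or a labeled test set")

  exclusions <- character(0)
  trajs <- list()
  rows <- list()
  for (id in names(models)) {
    m <- models[[id]]
    res <- tryCatch({
      traj <- encode_trajectory(m, test)
      lab <- truth_labels[match(traj$t, test$t)]
      sil <- silhouette_score(traj$Z, lab)$score
      mom <- cluster_moments(traj$Z, lab)
      h <- m$history[nrow(m$history), ]
      list(traj = traj,
           row = data.frame(
             id = id,
             config_id = if (!is.null(m$config_id)) m$config_id
                         else NA_character_,
             seed = m$config$seed, val_loss = h$val_loss,
             val_nl = h$val_nl, silhouette = sil,
             skew_abs_mean = mom$skew_abs_mean,
             kurt_abs_mean = mom$kurt_abs_mean,
             stringsAsFactors = FALSE))
    }, error = function(e) e)
    if (inherits(res, "error")) {
      exclusions <- c(exclusions,
                      sprintf("%s: %s", id, conditionMessage(res)))
    } else {
      trajs[[id]] <- res$traj
      rows[[id]] <- res$row
    }
  }
  if (!length(rows)) stop("every model failed to encode the test set")
  rows <- do.call(rbind, c(rows, make.row.names = FALSE))

  idx <- model_pairs(rows, pairing, max_pairs, pair_seed)
  pairs <- NULL
  if (!is.null(idx)) {
    pairs <- do.call(rbind, lapply(seq_len(nrow(idx)), function(j) {
      a <- idx[j, 1]; b <- idx[j, 2]
      ta <- trajs[[rows$id[a]]]; tb <- trajs[[rows$id[b]]]
      common <- intersect(ta$t, tb$t)
      d <- procrustes_distance(ta$Z[match(common, ta$t), , drop = FALSE],
                               tb$Z[match(common, tb$t), , drop = FALSE])
      data.frame(id_a = rows$id[a], id_b = rows$id[b],
                 config_id = if (identical(rows$config_id[a],
                                           rows$config_id[b]))
                   rows$config_id[a] else "mixed",
                 encoding_distance = d,
                 mean_val_loss = mean(c(rows$val_loss[a], rows$val_loss[b])),
                 mean_val_nl = mean(c(rows$val_nl[a], rows$val_nl[b])),
                 stringsAsFactors = FALSE)
    }))
  }

  corr <- function(criterion, outcome, x, y) {
    r <- spearman_or_undefined(x, y, method)
    data.frame(criterion = criterion, outcome = outcome, rho = r$rho,
               n = r$n, note = r$note, stringsAsFactors = FALSE)
  }
  correlations <- rbind(
    corr("val_nl", "silhouette", rows$val_nl, rows$silhouette),
    corr("val_loss", "silhouette", rows$val_loss, rows$silhouette),
    if (!is.null(pairs))
      corr("val_nl", "encoding_distance", pairs$mean_val_nl,
           pairs$encoding_distance),
    if (!is.null(pairs))
      corr("val_loss", "encoding_distance", pairs$mean_val_loss,
           pairs$encoding_distance))

  structure(list(rows = rows, pairs = pairs, correlations = correlations,
                 exclusions = exclusions, pairing = pairing,
                 method = method),
            class = "ensemble_report")
}

#' @export
print.ensemble_report <- function(x, ...) {
  cat(sprintf("<ensemble_report> %d models, %d pairs (%s pairing)\n",
              nrow(x$rows), if (is.null(x$pairs)) 0L else nrow(x$pairs),
              x$pairing))
  print(x$correlations, row.names = FALSE)
  if (length(x$exclusions))
    cat("excluded:", paste(x$exclusions, collapse = "; "), "\n")
  invisible(x)
}

#' Three-arm model-selection comparison
#'
#' Compares (standard VAE, validation-loss selection), (TN-VAE,
#' validation-loss selection) and (TN-VAE, Neighbor-Loss selection) on
#' the same dataset and splits. Each arm reports the selected model's
#' test silhouette and the spread (mean pairwise encoding distance) of
#' the top-k models under that arm's criterion; the spread is missing
#' when fewer than two models are available.
#'
#' @param vae_models ensemble of standard VAEs.
#' @param tnvae_models ensemble of TN-VAEs trained on the same data and
#'   splits.
#' @param test shared held-out test block.
#' @param truth_labels labels aligned with `test` rows (defaults to
#'   `test$labels`).
#' @param k top-k depth for the spread statistic.
#' @return data.frame with one row per arm.
#' @export
selection_comparison <- function(vae_models, tnvae_models, test,
                                 truth_labels = NULL, k = 5) {
  vae_models <- as_model_list(vae_models)
  tnvae_models <- as_model_list(tnvae_models)
  if (is.null(truth_labels)) truth_labels <- test$labels
  tests <- lapply(c(vae_models, tnvae_models), function(m)
    if (!is.null(m$split)) m$split$test else NULL)
  tests <- tests[!vapply(tests, is.null, TRUE)]
  if (length(tests) > 1 &&
      !all(vapply(tests, identical, TRUE, y = tests[[1]])))
    stop("mismatched datasets: ensembles carry different test blocks")

  arm <- function(models, criterion, label) {
    fin <- final_criteria(models)
    col <- criterion_column(criterion)
    sel <- select_model(models, criterion)
    traj <- encode_trajectory(models[[sel]], test)
    lab <- truth_labels[match(traj$t, test$t)]
    sil <- silhouette_score(traj$Z, lab)$score
    top <- fin$id[order(fin[[col]])][seq_len(min(k, nrow(fin)))]
    spread <- NA_real_
    if (length(top) >= 2) {
      cmb <- utils::combn(top, 2)
      spread <- mean(vapply(seq_len(ncol(cmb)), function(j)
        encoding_distance(models[[cmb[1, j]]], models[[cmb[2, j]]], test),
        0))
    }
    data.frame(arm = label, criterion = criterion, selected = sel,
               silhouette = sil, spread_topk = spread,
               k_used = length(top), stringsAsFactors = FALSE)
  }
  rbind(arm(vae_models, "val_loss", "VAE + val-loss"),
        arm(tnvae_models, "val_loss", "TN-VAE + val-loss"),
        arm(tnvae_models, "neighbor_loss", "TN-VAE + NL"))
}
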
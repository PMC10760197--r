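#' Latent trajectory container
#'
#' Time-ordered posterior-mean encodings of a dataset under one model.
#' `gaps` lists the time indices whose outgoing transition must be
#' excluded from neighbor statistics.
#'
#' @param Z numeric matrix, N points by latent_dim.
#' @param t integer time index per row (defaults to 0..N-1).
#' @param gaps integer vector of excluded transition origins.
#' @param labels optional aligned integer labels.
#' @return Object of class `latent_trajectory`.
#' @export
latent_trajectory <- function(Z, t = NULL, gaps = integer(0),
                              labels = NULL) {
  Z <- as.matrix(Z)
  if (!all(is.finite(Z))) stop("`Z` must be finite")
  n <- nrow(Z)
  if (n < 1) stop("empty trajectory")
  if (is.null(t)) t <- seq_len(n) - 1L
  if (length(t) != n) stop("`t` must align with rows of `Z`")
  structure(list(Z = Z, t = as.integer(t), gaps = as.integer(gaps),
                 labels = labels),
            class = "latent_trajectory")
}

as_trajectory <- function(x) {
  if (inherits(x, "latent_trajectory")) x else latent_trajectory(x)
}

row_norms <- function(Z) sqrt(rowSums(Z * Z))

# Indices i such that the step Z[i] -> Z[i+1] is an included transition.
included_steps <- function(traj) {
  n <- nrow(traj$Z)
  if (n < 2) return(integer(0))
  i <- seq_len(n - 1)
  i[diff(traj$t) == 1L & !(traj$t[-n] %in% traj$gaps)]
}

#' Neighbor Loss: temporal smoothness of a latent trajectory
#'
#' Sum of Euclidean distances between temporally adjacent latent
#' points, normalized by the mean distance of the latent points from
#' the origin:
#' \deqn{NL = \sum_t \|z_{t+1} - z_t\| / \bar z, \quad
#'       \bar z = \sum_t \|z_t\| / N.}
#' Scale-invariant by construction; low values mean the trajectory
#' moves little relative to the overall size of the latent manifold.
#' `neighbor_loss_normalized()` additionally divides by the number of
#' included transitions so values are comparable across datasets of
#' different length.
#'
#' @param traj a [latent_trajectory()] (or a plain matrix, taken as a
#'   contiguous trajectory).
#' @return nonnegative scalar.
#' @export
neighbor_loss <- function(traj) {
  traj <- as_trajectory(traj)
  steps <- included_steps(traj)
  if (nrow(traj$Z) < 2 || !length(steps))
    stop("neighbor loss needs at least one included transition")
  zbar <- mean(row_norms(traj$Z))
  if (zbar <= 0)
    stop("neighbor loss undefined: all-zero latent trajectory (zbar = 0)")
  d <- traj$Z[steps + 1L, , drop = FALSE] - traj$Z[steps, , drop = FALSE]
  sum(row_norms(d)) / zbar
}

#' @rdname neighbor_loss
#' @export
neighbor_loss_normalized <- function(traj) {
  traj <- as_trajectory(traj)
  neighbor_loss(traj) / length(included_steps(traj))
}

#' Silhouette score against ground-truth clusters
#'
#' Per-sample silhouette s(i) = (b(i) - a(i)) / max(a(i), b(i)), where
#' a(i) is the mean distance from point i to the other members of its
#' own cluster and b(i) the mean distance to the members of the
#' nearest other cluster; the dataset score is the mean of s over all
#' samples. Points in singleton clusters score 0 by convention.
#'
#' @param Z numeric matrix of points.
#' @param labels integer cluster labels (>= 2 distinct values).
#' @return list of class `silhouette_eval`: `score` (dataset mean) and
#'   `per_sample` data.frame with columns a, b, s.
#' @export
silhouette_score <- function(Z, labels) {
  Z <- as.matrix(Z)
  labels <- as.vector(labels)
  n <- nrow(Z)
  if (length(labels) != n) stop("`labels` must align with rows of `Z`")
  f <- factor(labels)
  if (nlevels(f) < 2) stop("silhouette undefined for one cluster")
  k <- as.integer(f)
  K <- nlevels(f)
  counts <- tabulate(k, K)
  D <- as.matrix(stats::dist(Z))
  G <- matrix(0, n, K); G[cbind(seq_len(n), k)] <- 1
  S <- D %*% G                        # summed distance to each cluster
  own <- counts[k]
  a <- ifelse(own > 1, S[cbind(seq_len(n), k)] / (own - 1), NA_real_)
  M <- sweep(S, 2, counts, "/")       # mean distance to each cluster
  M[cbind(seq_len(n), k)] <- Inf
  b <- do.call(pmin, as.data.frame(M))
  s <- ifelse(own > 1, (b - a) / pmax(a, b), 0)
  structure(list(score = mean(s),
                 per_sample = data.frame(a = a, b = b, s = s)),
            class = "silhouette_eval")
}

#' @export
print.silhouette_eval <- function(x, ...) {
  cat(sprintf("<silhouette_eval> score %.4f over %d samples\n",
              x$score, nrow(x$per_sample)))
  invisible(x)
}

#' Generalized Procrustes distance between two point sets
#'
#' Minimum residual Euclidean distance between row-matched point sets
#' after optimal translation, rotation, reflection and scaling. Both
#' matrices are centered and scaled to unit Frobenius norm, so the
#' value is a pure shape discrepancy: 0 iff B is a similarity
#' transform of A, and symmetric in its arguments. Computed in closed
#' form via the SVD of the cross-covariance.
#'
#' @param A,B numeric matrices of identical shape (n points x d dims,
#'   n >= d).
#' @return nonnegative scalar, equal to `sqrt(max(0, 1 - tr^2))` with
#'   `tr` the sum of singular values of the cross-covariance, but
#'   computed as the explicit aligned residual for numerical accuracy
#'   near zero.
#' @export
procrustes_distance <- function(A, B) {
  A <- as.matrix(A); B <- as.matrix(B)
  if (!all(dim(A) == dim(B)))
    stop(sprintf("shape mismatch: A is %dx%d, B is %dx%d",
                 nrow(A), ncol(A), nrow(B), ncol(B)))
  if (nrow(A) < ncol(A))
    stop("need at least as many points as dimensions")
  Ac <- sweep(A, 2, colMeans(A)); Bc <- sweep(B, 2, colMeans(B))
  na <- sqrt(sum(Ac * Ac)); nb <- sqrt(sum(Bc * Bc))
  if (na < 1e-12 || nb < 1e-12)
    stop("procrustes distance undefined for zero-variance input")
  Ac <- Ac / na; Bc <- Bc / nb
  s <- svd(crossprod(Ac, Bc))
  # optimal orthogonal map (rotation or reflection) and scale, applied
  # explicitly: avoids the cancellation in sqrt(1 - tr^2) when the
  # shapes (nearly) coincide
  resid <- Ac - sum(s$d) * (Bc %*% s$v %*% t(s$u))
  sqrt(sum(resid * resid))
}

#' Posterior-mean latent trajectory of a time series under a model
#'
#' For a standard VAE the latent attributed to time t is
#' `encode(x_t)$mean`. For a TN-VAE the encoder of x_t parameterizes
#' the posterior over the next latent, so the latent attributed to
#' time t+1 is `encode(x_t)$mean` and the trajectory starts at the
#' second time bin. Labels, when present, are realigned accordingly.
#'
#' @param model a `tnvae_model`.
#' @param ts a `labeled_ts`.
#' @return a [latent_trajectory()].
#' @export
encode_trajectory <- function(model, ts) {
  n <- n_bins(ts)
  if (model$config$predictive) {
    if (n < 2) stop("predictive trajectory needs at least 2 time bins")
    Z <- encode(model, ts$X[-n, , drop = FALSE])$mean
    tt <- ts$t[-1]
    # a gap u -> u+1 invalidates the latent derived from x_u as well as
    # the step leaving it
    gp <- sort(unique(c(ts$gaps, ts$gaps + 1L)))
    labels <- if (!is.null(ts$labels)) ts$labels[-1]
  } else {
    Z <- encode(model, ts$X)$mean
    tt <- ts$t
    gp <- ts$gaps
    labels <- ts$labels
  }
  latent_trajectory(Z, t = tt, gaps = gp, labels = labels)
}

#' Encoding distance between two models on shared test data
#'
#' Procrustes distance between the two models' posterior-mean
#' trajectories of the same test series, after restricting both to
#' the time indices they share (a TN-VAE trajectory starts one bin
#' later than a standard VAE's).
#'
#' @param model_a,model_b `tnvae_model`s accepting the test
#'   dimensionality.
#' @param test a `labeled_ts`.
#' @return nonnegative scalar.
#' @export
encoding_distance <- function(model_a, model_b, test) {
  ta <- encode_trajectory(model_a, test)
  tb <- encode_trajectory(model_b, test)
  common <- intersect(ta$t, tb$t)
  procrustes_distance(ta$Z[match(common, ta$t), , drop = FALSE],
                      tb$Z[match(common, tb$t), , drop = FALSE])
}

#' Per-cluster skewness and kurtosis of latent encodings
#'
#' Bias-corrected sample skewness (G1) and excess kurtosis (G2) per
#' cluster and latent dimension, plus scalar summaries (mean absolute
#' value across clusters and dimensions) used as a spurious-feature
#' diagnostic: encodings of Gaussian clusters that feather into
#' streaks show inflated |skew| and |kurtosis|.
#'
#' @param Z numeric matrix of points.
#' @param labels integer cluster labels.
#' @return list with `per_cluster` (data.frame: cluster, dim, n,
#'   skewness, kurtosis), `skew_abs_mean`, `kurt_abs_mean`, and
#'   `missing` (clusters with fewer than 3 points, reported rather
#'   than fatal).
#' @export
cluster_moments <- function(Z, labels) {
  Z <- as.matrix(Z)
  f <- factor(labels)
  res <- list()
  missing <- character(0)
  for (lev in levels(f)) {
    idx <- which(f == lev)
    nk <- length(idx)
    if (nk < 3) { missing <- c(missing, lev); next }
    Zi <- Z[idx, , drop = FALSE]
    ctr <- sweep(Zi, 2, colMeans(Zi))
    m2 <- colMeans(ctr^2); m3 <- colMeans(ctr^3); m4 <- colMeans(ctr^4)
    g1 <- m3 / m2^1.5
    G1 <- g1 * sqrt(nk * (nk - 1)) / (nk - 2)
    g2 <- m4 / m2^2 - 3
    G2 <- if (nk > 3) ((nk + 1) * g2 + 6) * (nk - 1) / ((nk - 2) * (nk - 3))
          else rep(NA_real_, length(g2))
    res[[lev]] <- data.frame(cluster = lev, dim = seq_along(g1), n = nk,
                             skewness = G1, kurtosis = G2)
  }
  per <- if (length(res)) do.call(rbind, c(res, make.row.names = FALSE))
         else data.frame(cluster = character(0), dim = integer(0),
                         n = integer(0), skewness = numeric(0),
                         kurtosis = numeric(0))
  list(per_cluster = per,
       skew_abs_mean = if (nrow(per)) mean(abs(per$skewness)) else NA_real_,
       kurt_abs_mean = if (nrow(per)) mean(abs(per$kurtosis), na.rm = TRUE)
                       else NA_real_,
       missing = missing)
}
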
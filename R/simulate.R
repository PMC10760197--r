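#' Hidden-Markov-model simulation parameters
#'
#' Parameters of a K-state hidden Markov chain with diagonal-Gaussian
#' emissions in D dimensions, used to mimic wake / REM / SWS brain-state
#' dynamics in spectral feature space (30 LFP band powers plus total EMG
#' power, D = 31, by default).
#'
#' @param transition K x K row-stochastic transition matrix.
#' @param means K x D matrix of per-state emission means.
#' @param scales K x D matrix of strictly positive per-state,
#'   per-dimension emission standard deviations.
#' @param state_names optional character vector of length K.
#' @return An object of class `hmm_params`.
#' @export
hmm_params <- function(transition, means, scales, state_names = NULL) {
  transition <- as.matrix(transition)
  means <- as.matrix(means)
  scales <- as.matrix(scales)
  k <- nrow(transition)
  if (ncol(transition) != k)
    stop("`transition` must be square")
  if (any(transition < 0))
    stop("`transition` entries must be nonnegative")
  rs <- rowSums(transition)
  if (any(abs(rs - 1) > 1e-12))
    stop("`transition` rows must sum to 1 (within 1e-12); row sums: ",
         paste(format(rs, digits = 15), collapse = ", "))
  if (nrow(means) != k || nrow(scales) != k)
    stop("`means` and `scales` must have one row per state")
  if (!identical(dim(means), dim(scales)))
    stop("`means` and `scales` must have identical dimensions")
  if (any(scales <= 0))
    stop("`scales` must be strictly positive")
  structure(list(n_states = k, transition = transition, means = means,
                 scales = scales, state_names = state_names),
            class = "hmm_params")
}

#' Stationary distribution of a Markov transition matrix
#'
#' Left eigenvector of the transition matrix for eigenvalue 1,
#' normalized to sum to one. Errors if the unit eigenvalue is not
#' unique (reducible or periodic-degenerate chain).
#'
#' @param transition row-stochastic matrix.
#' @return numeric vector of stationary probabilities.
#' @export
stationary_distribution <- function(transition) {
  transition <- as.matrix(transition)
  e <- eigen(t(transition))
  ones <- which(abs(e$values - 1) < 1e-9)
  if (length(ones) != 1)
    stop("transition matrix has no unique stationary distribution ",
         "(reducible chain?): ",
         paste(apply(format(transition, digits = 4), 1, paste,
                     collapse = " "), collapse = " | "))
  v <- Re(e$vectors[, ones])
  v / sum(v)
}

#' Simulate a hidden Markov chain with Gaussian emissions
#'
#' The initial state is drawn from the stationary distribution of the
#' transition matrix; emissions are diagonal Gaussians. Labels hold the
#' sampled hidden-state sequence (1-based state ids).
#'
#' @param params an [hmm_params()] object.
#' @param n_points number of time bins to simulate.
#' @param seed integer seed; identical seeds give identical output.
#' @param init optional initial-state distribution. The default draws
#'   the initial state from the stationary distribution, which
#'   requires an irreducible chain; supply `init` explicitly to
#'   simulate absorbing or reducible chains.
#' @return A [labeled_time_series()] with `labels` set.
#' @export
simulate_hmm <- function(params, n_points, seed = 1, init = NULL) {
  stopifnot(inherits(params, "hmm_params"), n_points >= 1)
  pi0 <- if (is.null(init)) stationary_distribution(params$transition)
         else {
           if (length(init) != params$n_states || any(init < 0) ||
               abs(sum(init) - 1) > 1e-12)
             stop("`init` must be a probability vector over the states")
           init
         }
  k <- params$n_states
  d <- ncol(params$means)
  cum <- t(apply(params$transition, 1, cumsum))
  set.seed(seed)
  s <- integer(n_points)
  s[1] <- findInterval(stats::runif(1), cumsum(pi0)) + 1L
  if (n_points > 1) {
    u <- stats::runif(n_points - 1)
    for (i in 2:n_points)
      s[i] <- findInterval(u[i - 1], cum[s[i - 1], ],
                           left.open = TRUE) + 1L
  }
  noise <- matrix(stats::rnorm(n_points * d), n_points, d)
  X <- params$means[s, , drop = FALSE] +
    noise * params$scales[s, , drop = FALSE]
  labeled_time_series(X, labels = s)
}

#' Spiral simulation parameters
#'
#' An Archimedean spiral r = a + b*theta traversed over `turns`
#' revolutions, sampled uniformly in arc length starting from the
#' innermost point, then lifted through a fixed random smooth nonlinear
#' map into `embed_dim` dimensions with additive Gaussian white noise.
#' The embedding map is fully determined by `embed_seed` and is a
#' reproducible part of the dataset definition.
#'
#' @param n_points number of points sampled along the curve.
#' @param turns number of revolutions (> 0).
#' @param noise_sd standard deviation of the additive noise in the
#'   embedded space (the noiseless embedding has coordinates in
#'   \[-1, 1\], so 0.1 is ~10 percent of the signal range).
#' @param embed_dim target dimensionality (>= 2, default 31).
#' @param embed_seed seed fixing the random embedding map.
#' @param inner_radius radius at the innermost point.
#' @return An object of class `spiral_params`.
#' @export
spiral_params <- function(n_points = 2000, turns = 3, noise_sd = 0.1,
                          embed_dim = 31, embed_seed = 1,
                          inner_radius = 0.2) {
  if (n_points < 2) stop("`n_points` must be >= 2")
  if (turns <= 0) stop("`turns` must be > 0")
  if (noise_sd < 0) stop("`noise_sd` must be >= 0")
  if (embed_dim < 2) stop("`embed_dim` must be >= 2")
  structure(list(n_points = as.integer(n_points), turns = turns,
                 noise_sd = noise_sd, embed_dim = as.integer(embed_dim),
                 embed_seed = as.integer(embed_seed),
                 inner_radius = inner_radius),
            class = "spiral_params")
}

# 2-D Archimedean spiral sampled uniformly in arc length.
# Returns list(points = n x 2, arc_length = n), arc length measured
# from the innermost point. Inversion of the arc-length integral is
# numerical (dense trapezoid grid + linear interpolation).
spiral_curve <- function(n_points, turns, inner_radius = 0.2,
                         grid_mult = 50L) {
  theta_max <- 2 * pi * turns
  a <- inner_radius
  b <- (1 - a) / theta_max           # outer radius 1
  ngrid <- max(10000L, grid_mult * n_points)
  th <- seq(0, theta_max, length.out = ngrid)
  ds <- sqrt((a + b * th)^2 + b^2)   # |d(position)/d(theta)|
  s <- c(0, cumsum((ds[-1] + ds[-ngrid]) / 2 * diff(th)))
  targets <- seq(0, s[ngrid], length.out = n_points)
  th_u <- stats::approx(s, th, xout = targets, ties = "ordered")$y
  r <- a + b * th_u
  list(points = cbind(r * cos(th_u), r * sin(th_u)), arc_length = targets)
}

# Fixed random smooth injective lift R^2 -> R^D: y_j = tanh(a_j . p + c_j).
# Injective because tanh is strictly monotone and the a_j span R^2.
spiral_embedding <- function(embed_dim, embed_seed) {
  set.seed(embed_seed)
  A <- matrix(stats::rnorm(2 * embed_dim, sd = 1.5), 2, embed_dim)
  offs <- stats::runif(embed_dim, -0.5, 0.5)
  function(P) tanh(sweep(P %*% A, 2, offs, "+"))
}

#' Simulate a noisy spiral embedded in high dimensions
#'
#' @param params a [spiral_params()] object.
#' @param seed seed for the additive observation noise (independent of
#'   `embed_seed`, which fixes the embedding map).
#' @return A [labeled_time_series()] with `latent_truth` holding the
#'   arc-length position along the curve (strictly increasing in time).
#' @export
simulate_spiral <- function(params, seed = 1) {
  stopifnot(inherits(params, "spiral_params"))
  curve <- spiral_curve(params$n_points, params$turns,
                        params$inner_radius)
  embed <- spiral_embedding(params$embed_dim, params$embed_seed)
  Y <- embed(curve$points)
  if (params$noise_sd > 0) {
    set.seed(seed)
    Y <- Y + matrix(stats::rnorm(length(Y), sd = params$noise_sd),
                    nrow(Y), ncol(Y))
  }
  labeled_time_series(Y, latent_truth = curve$arc_length)
}

#' Destroy temporal structure by shuffling rows
#'
#' Permutes rows uniformly at random (labels and latent truth permuted
#' in lockstep) and resets the time index to 0..N-1, so the result is
#' treated as independent samples with no meaningful transitions.
#'
#' @param ts a `labeled_ts`.
#' @param seed permutation seed.
#' @return A `labeled_ts` with the same rows in shuffled order.
#' @export
shuffle_time <- function(ts, seed = 1) {
  n <- n_bins(ts)
  set.seed(seed)
  p <- sample.int(n)
  labeled_time_series(
    ts$X[p, , drop = FALSE],
    labels = if (!is.null(ts$labels)) ts$labels[p],
    latent_truth = if (!is.null(ts$latent_truth)) ts$latent_truth[p]
  )
}

#' Block labels for continuous trajectories
#'
#' Assigns label `floor(i / block)` to row i (0-based), grouping each
#' `block` consecutive data points into one pseudo-cluster. Used as the
#' silhouette ground truth for the spiral dataset.
#'
#' @param ts a `labeled_ts`.
#' @param block block length (>= 1).
#' @return integer label vector of length N.
#' @export
block_labels <- function(ts, block = 100) {
  if (block < 1) stop("`block` must be >= 1")
  as.integer((seq_len(n_bins(ts)) - 1L) %/% as.integer(block))
}

#' Built-in simulation presets
#'
#' `hmm_sleep_preset()` loads the package's sleep-like three-state HMM
#' (long dwell times, no direct wake-to-REM transition, cluster means
#' separated by >= 3 pooled SDs in a handful of spectral dimensions and
#' overlapping elsewhere). `spiral_preset()` loads the default noisy
#' spiral. Both are stored as JSON under `inst/extdata`.
#'
#' @param path optional path to a JSON preset file, overriding the
#'   built-in one.
#' @return An [hmm_params()] or [spiral_params()] object.
#' @export
hmm_sleep_preset <- function(path = NULL) {
  if (is.null(path))
    path <- system.file("extdata", "hmm_sleep.json", package = "tnvae",
                        mustWork = TRUE)
  p <- jsonlite::fromJSON(path)
  hmm_params(p$transition, p$means, p$scales, state_names = p$state_names)
}

#' @rdname hmm_sleep_preset
#' @export
spiral_preset <- function(path = NULL) {
  if (is.null(path))
    path <- system.file("extdata", "spiral_default.json",
                        package = "tnvae", mustWork = TRUE)
  p <- jsonlite::fromJSON(path)
  spiral_params(n_points = p$n_points, turns = p$turns,
                noise_sd = p$noise_sd, embed_dim = p$embed_dim,
                embed_seed = p$embed_seed,
                inner_radius = p$inner_radius)
}
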
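# Independent oracles. These deliberately use the dumbest correct
# algorithm (double loops, matrix powering, grid search) and stay
# independent of the implementation paths they check.

# Silhouette by explicit double loop over points.
sil_brute <- function(Z, labels) {
  n <- nrow(Z)
  s <- numeric(n)
  for (i in seq_len(n)) {
    din <- c(); dby <- list()
    for (j in seq_len(n)) {
      if (j == i) next
      dij <- sqrt(sum((Z[i, ] - Z[j, ])^2))
      if (labels[j] == labels[i]) din <- c(din, dij)
      else {
        key <- as.character(labels[j])
        dby[[key]] <- c(dby[[key]], dij)
      }
    }
    if (!length(din)) { s[i] <- 0; next }
    a <- mean(din)
    b <- min(vapply(dby, mean, 0))
    s[i] <- (b - a) / max(a, b)
  }
  mean(s)
}

# Procrustes distance by refined grid search over rotation angle x
# reflection x scale, on matrices pre-normalized exactly as the
# definition prescribes (centered, unit Frobenius norm).
procrustes_grid <- function(A, B) {
  ctr <- function(M) sweep(M, 2, colMeans(M))
  A <- ctr(A); A <- A / sqrt(sum(A^2))
  B <- ctr(B); B <- B / sqrt(sum(B^2))
  eval_d2 <- function(theta, c, refl) {
    R <- matrix(c(cos(theta), sin(theta), -sin(theta), cos(theta)), 2)
    if (refl) R <- R %*% diag(c(1, -1))
    sum((A - c * (B %*% R))^2)
  }
  best <- c(theta = 0, c = 1)
  best_refl <- FALSE
  best_d2 <- Inf
  th_w <- pi; c_w <- 1
  th0 <- pi; c0 <- 1
  for (stage in 1:4) {
    ths <- seq(th0 - th_w, th0 + th_w, length.out = 41)
    cs <- seq(max(0, c0 - c_w), c0 + c_w, length.out = 41)
    for (refl in c(FALSE, TRUE)) for (th in ths) for (cc in cs) {
      d2 <- eval_d2(th, cc, refl)
      if (d2 < best_d2) {
        best_d2 <- d2; best <- c(theta = th, c = cc); best_refl <- refl
      }
    }
    th0 <- best[["theta"]]; c0 <- best[["c"]]
    th_w <- th_w / 10; c_w <- c_w / 10
  }
  sqrt(best_d2)
}

# Stationary distribution by brute-force matrix powering (repeated
# squaring: P^(2^30), plenty even for slow-mixing sleep dynamics).
stationary_power <- function(P, squarings = 30) {
  M <- P
  for (i in seq_len(squarings)) M <- M %*% M
  as.numeric(rep(1 / nrow(P), nrow(P)) %*% M)
}

# Standard deviation of the occupancy estimator (fraction of time in
# state k over n steps, stationary start) via brute-force summation of
# autocovariances from matrix powers.
occupancy_sd <- function(P, k, n, max_lag = 5000) {
  pi_ <- stationary_power(P)
  v <- pi_[k] * (1 - pi_[k])
  acc <- v
  Ph <- P
  for (h in seq_len(max_lag)) {
    cov_h <- pi_[k] * Ph[k, k] - pi_[k]^2
    acc <- acc + 2 * (1 - h / n) * cov_h
    if (abs(cov_h) < 1e-12 * v) break
    Ph <- Ph %*% P
  }
  sqrt(acc / n)
}

rand_orth <- function(d) {
  qr.Q(qr(matrix(rnorm(d * d), d)))
}
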
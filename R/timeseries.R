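#' Labeled time series container
#'
#' The container every stage of the package consumes: a time-ordered
#' observation matrix `X` (rows are time bins, columns are features),
#' an integer time index `t`, optional integer ground-truth `labels`
#' (e.g. hidden brain states), and an optional real-valued
#' `latent_truth` (the generative latent coordinate, e.g. arc-length
#' position along a spiral). `gaps` records time indices `u` whose
#' transition `u -> u + 1` is not observed (created by split
#' operations); pair construction never crosses a recorded gap.
#'
#' @param X numeric matrix, N time bins by D features.
#' @param t integer time index per row, strictly increasing. Defaults
#'   to `0:(N-1)`.
#' @param labels optional integer vector of length N.
#' @param latent_truth optional numeric vector of length N.
#' @param gaps integer vector of time indices whose outgoing
#'   transition is excluded.
#' @return An object of class `labeled_ts`.
#' @export
labeled_time_series <- function(X, t = NULL, labels = NULL,
                                latent_truth = NULL, gaps = integer(0)) {
  X <- as.matrix(X)
  storage.mode(X) <- "double"
  n <- nrow(X)
  if (is.null(t)) t <- seq_len(n) - 1L
  t <- as.integer(t)
  if (length(t) != n)
    stop("`t` must have one entry per row of `X` (got ", length(t),
         ", expected ", n, ")")
  if (n > 1 && any(diff(t) <= 0))
    stop("`t` must be strictly increasing")
  if (!is.null(labels)) {
    labels <- as.integer(labels)
    if (length(labels) != n)
      stop("`labels` must have length ", n)
  }
  if (!is.null(latent_truth)) {
    latent_truth <- as.numeric(latent_truth)
    if (length(latent_truth) != n)
      stop("`latent_truth` must have length ", n)
  }
  structure(
    list(X = X, t = t, labels = labels, latent_truth = latent_truth,
         gaps = as.integer(gaps)),
    class = "labeled_ts"
  )
}

#' @export
print.labeled_ts <- function(x, ...) {
  cat(sprintf("<labeled_ts> %d time bins x %d features\n",
              nrow(x$X), ncol(x$X)))
  if (!is.null(x$labels))
    cat("  labels:", paste(names(table(x$labels)), table(x$labels),
                           sep = ":", collapse = " "), "\n")
  if (!is.null(x$latent_truth))
    cat(sprintf("  latent truth in [%.3g, %.3g]\n",
                min(x$latent_truth), max(x$latent_truth)))
  if (length(x$gaps))
    cat("  gaps after t =", paste(x$gaps, collapse = ", "), "\n")
  invisible(x)
}

#' Number of time bins
#' @param ts a `labeled_ts`.
#' @export
n_bins <- function(ts) nrow(ts$X)

#' Time indices eligible as transitions
#'
#' A transition `u -> u + 1` exists when both bins are present, the time
#' step is one, and `u` is not a recorded gap. Returned as the 0-based
#' time index `u` of the transition's origin.
#'
#' @param ts a `labeled_ts`.
#' @return integer vector of transition origins (0-based time indices).
#' @export
transition_index <- function(ts) {
  n <- n_bins(ts)
  if (n < 2) return(integer(0))
  u <- ts$t[-n]
  ok <- diff(ts$t) == 1L & !(u %in% ts$gaps)
  u[ok]
}

#' Write / read a labeled time series as CSV
#'
#' Columns are `t`, `label`, `latent_truth`, `f0` .. `f{D-1}`; `label`
#' and `latent_truth` may be empty. UTF-8, header row required.
#'
#' @param ts a `labeled_ts`.
#' @param path file path.
#' @export
write_series_csv <- function(ts, path) {
  d <- ncol(ts$X)
  df <- data.frame(t = ts$t)
  df$label <- if (is.null(ts$labels)) NA_integer_ else ts$labels
  df$latent_truth <- if (is.null(ts$latent_truth)) NA_real_ else ts$latent_truth
  feat <- as.data.frame(ts$X)
  names(feat) <- paste0("f", seq_len(d) - 1L)
  df <- cbind(df, feat)
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_series_csv
#' @export
read_series_csv <- function(path) {
  df <- utils::read.csv(path, header = TRUE)
  if (!"t" %in% names(df))
    stop("dataset CSV must have a `t` column")
  fcols <- grep("^f[0-9]+$", names(df), value = TRUE)
  fcols <- fcols[order(as.integer(sub("^f", "", fcols)))]
  if (!length(fcols))
    stop("dataset CSV must have feature columns f0..f{D-1}")
  labels <- if ("label" %in% names(df) && !all(is.na(df$label)))
    df$label else NULL
  truth <- if ("latent_truth" %in% names(df) && !all(is.na(df$latent_truth)))
    df$latent_truth else NULL
  labeled_time_series(as.matrix(df[fcols]), t = df$t,
                      labels = labels, latent_truth = truth)
}

# Subset rows of a series, keeping alignment; `rows` are 1-based row
# positions, assumed contiguous in time or carrying their own gaps.
subset_series <- function(ts, rows, gaps = NULL) {
  if (is.null(gaps)) {
    tt <- ts$t[rows]
    gaps <- intersect(ts$gaps, tt)
  }
  labeled_time_series(
    ts$X[rows, , drop = FALSE], t = ts$t[rows],
    labels = if (!is.null(ts$labels)) ts$labels[rows],
    latent_truth = if (!is.null(ts$latent_truth)) ts$latent_truth[rows],
    gaps = gaps
  )
}
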
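#' Enumerate the unique edges of an N-node graph
#'
#' Edges are unordered node pairs (i, j) with i < j, listed in row-major
#' upper-triangle order: (1,2), (1,3), ..., (1,N), (2,3), ... This
#' ordering is shared by every edge-indexed object in the package.
#'
#' @param n_nodes number of nodes N (>= 2).
#' @return An integer matrix with `choose(N, 2)` rows and columns
#'   `i`, `j` (1-based node indices, i < j).
#' @export
#' @examples
#' nrow(edge_index(264))  # 34716 unique edges
edge_index <- function(n_nodes) {
  n <- as.integer(n_nodes)
  if (is.na(n) || n < 2L) stop("'n_nodes' must be >= 2")
  i <- rep.int(seq_len(n - 1L), times = (n - 1L):1L)
  j <- sequence((n - 1L):1L) + i
  cbind(i = i, j = j)
}

#' Number of sliding-window positions
#'
#' With stride 1 sample, a window of w samples fits `T - w + 1` times in
#' a series of T samples.
#'
#' @param n_timepoints series length T.
#' @param window_length window length w in samples.
#' @return Integer count of windows.
#' @export
#' @examples
#' n_sliding_windows(240, 45)  # 196
n_sliding_windows <- function(n_timepoints, window_length) {
  T <- as.integer(n_timepoints); w <- as.integer(window_length)
  if (w > T) stop(sprintf("window length (%d samples) exceeds series length (%d)", w, T))
  if (w < 2L) stop("'window_length' must be >= 2 samples")
  T - w + 1L
}

#' Convert a duration in seconds to a sample count
#'
#' Refuses to round: the duration must be an integer multiple of the
#' sampling interval.
#'
#' @param duration duration in seconds (> 0).
#' @param tr sampling interval in seconds (> 0).
#' @return Integer number of samples.
#' @export
#' @examples
#' seconds_to_samples(90, 2)  # 45
seconds_to_samples <- function(duration, tr) {
  if (duration <= 0 || tr <= 0) stop("'duration' and 'tr' must be > 0")
  r <- duration / tr
  if (abs(r - round(r)) > 1e-8)
    stop(sprintf("duration %g s is not an integer multiple of tr %g s", duration, tr))
  as.integer(round(r))
}

#' Sliding-window edge correlation time-series
#'
#' Slides a window of `window_length` samples over the node time-series
#' in steps of one sample and, at each position, computes the
#' correlation between every pair of nodes over the samples
#' `[t, t + w - 1]`. The rank-based (Spearman) coefficient is the
#' default; the product-moment (Pearson) coefficient is available via
#' `method`. Results are stored edge-major: an E x W matrix whose rows
#' follow [edge_index()] order, which keeps each edge's trajectory
#' contiguous.
#'
#' A window in which a node's segment is constant has no defined
#' correlation; such entries are stored as `NA`, counted in
#' `$n_missing`, and excluded from downstream summaries.
#'
#' @param ts a [roi_ts()].
#' @param window_length window length in samples (2 <= w <= T); see
#'   [seconds_to_samples()] to convert from seconds.
#' @param method `"spearman"` (rank-based, default) or `"pearson"`
#'   (product-moment).
#' @param verbose if `TRUE`, reports the missing-value count.
#' @return An object of class `edge_series`: a list with `values`
#'   (E x W matrix of correlations in `[-1, 1]`), `edge_index`,
#'   `window_length`, `method`, `node_ids`, `tr` and `n_missing`.
#' @export
sliding_window_correlation <- function(ts, window_length,
                                       method = c("spearman", "pearson"),
                                       verbose = FALSE) {
  stopifnot(inherits(ts, "roi_ts"))
  method <- match.arg(method)
  T <- ncol(ts$values)
  w <- as.integer(window_length)
  if (w > T)
    stop(sprintf("window length (%d samples) exceeds series length (%d samples)", w, T))
  if (w < 2L) stop("'window_length' must be >= 2 samples")
  W <- T - w + 1L
  idx <- edge_index(nrow(ts$values))
  x <- t(ts$values)  # T x N: cor() works column-wise
  vals <- matrix(NA_real_, nrow(idx), W)
  for (t in seq_len(W)) {
    C <- suppressWarnings(stats::cor(x[t:(t + w - 1L), , drop = FALSE],
                                     method = method))
    vals[, t] <- C[idx]
  }
  n_missing <- sum(is.na(vals))
  if (verbose && n_missing > 0)
    message(sprintf("%d of %d windowed correlations undefined (constant segment); stored as NA",
                    n_missing, length(vals)))
  structure(list(values = vals, edge_index = idx, window_length = w,
                 method = method, node_ids = ts$node_ids, tr = ts$tr,
                 n_missing = n_missing),
            class = "edge_series")
}

#' @export
print.edge_series <- function(x, ...) {
  cat(sprintf("<edge_series> %d edges x %d windows (w = %d samples, %s), %d missing\n",
              nrow(x$values), ncol(x$values), x$window_length, x$method,
              x$n_missing))
  invisible(x)
}

#' Reassemble one window's full connectivity matrix
#'
#' Expands the edge-major storage back to the symmetric N x N view of a
#' single window, with unit diagonal.
#'
#' @param es an `edge_series`.
#' @param window window position (1-based).
#' @return Symmetric N x N numeric matrix with 1 on the diagonal.
#' @export
as_connectivity_matrix <- function(es, window) {
  stopifnot(inherits(es, "edge_series"))
  W <- ncol(es$values)
  if (window < 1 || window > W) stop("'window' out of range 1..", W)
  n <- length(es$node_ids)
  C <- diag(1, n)
  C[es$edge_index] <- es$values[, window]
  C[es$edge_index[, c(2, 1)]] <- es$values[, window]
  dimnames(C) <- list(es$node_ids, es$node_ids)
  C
}
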
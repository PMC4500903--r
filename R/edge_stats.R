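#' Per-edge temporal mean and variance
#'
#' Reduces an edge correlation time-series to one temporal mean and one
#' temporal variance per edge, over that edge's non-missing windows.
#' The variance is the unbiased sample variance (n - 1 denominator).
#'
#' Because correlations are confined to `[-1, 1]`, every summary obeys a
#' Bhatia-Davis-type bound: `var_e <= (1 - mean_e)(1 + mean_e) * n/(n-1)`
#' with n the number of windows used. The bound is a structural property
#' of bounded variables, not an assumption; it is asserted throughout
#' the test-suite.
#'
#' @param es an `edge_series` from [sliding_window_correlation()], or a
#'   plain edges x windows numeric matrix.
#' @return An object of class `edge_summary`: list with numeric vectors
#'   `mean`, `variance`, `n_windows` (per edge) and the `edge_index`.
#' @export
summarize_edges <- function(es) {
  v <- as_edge_matrix(es)
  n_ok <- rowSums(!is.na(v))
  if (any(n_ok < 2L)) {
    bad <- which(n_ok < 2L)[1L]
    stop(sprintf("edge %d has %d usable window(s); need >= 2", bad, n_ok[bad]))
  }
  m <- rowMeans(v, na.rm = TRUE)
  ss <- rowSums((v - m)^2, na.rm = TRUE)
  structure(list(mean = m, variance = ss / (n_ok - 1L), n_windows = n_ok,
                 edge_index = attr(v, "edge_index")),
            class = "edge_summary")
}

# accept edge_series, binary-free matrix, or vector (single edge)
as_edge_matrix <- function(es) {
  if (inherits(es, "edge_series")) {
    v <- es$values
    attr(v, "edge_index") <- es$edge_index
    return(v)
  }
  if (is.numeric(es) && is.null(dim(es))) es <- matrix(es, nrow = 1L)
  if (!is.matrix(es) || !is.numeric(es))
    stop("expected an 'edge_series' or a numeric edges x windows matrix")
  v <- es
  attr(v, "edge_index") <- NULL
  v
}

#' @export
print.edge_summary <- function(x, ...) {
  cat(sprintf("<edge_summary> %d edges; mean in [%.3f, %.3f], variance in [%.4g, %.4g]\n",
              length(x$mean), min(x$mean), max(x$mean),
              min(x$variance), max(x$variance)))
  invisible(x)
}

#' Average edge summaries across subjects
#'
#' Element-wise arithmetic mean of the per-edge means and variances over
#' a list of subjects sharing the same edge set. This is the group-level
#' summary on which the mean-variance scaling relation is tested: each
#' subject is summarised first, then summaries are averaged, then the
#' rank correlation is computed once.
#'
#' @param summaries list of `edge_summary` objects with identical edge
#'   indices.
#' @return A single `edge_summary` (with `n_windows` the per-edge mean
#'   of the subjects' usable-window counts).
#' @export
group_average <- function(summaries) {
  if (inherits(summaries, "edge_summary")) summaries <- list(summaries)
  stopifnot(length(summaries) >= 1L,
            all(vapply(summaries, inherits, logical(1), "edge_summary")))
  ref <- summaries[[1L]]
  for (s in summaries[-1L]) {
    same <- length(s$mean) == length(ref$mean) &&
      (is.null(ref$edge_index) || is.null(s$edge_index) ||
         identical(s$edge_index, ref$edge_index))
    if (!same) stop("summaries do not share the same edge set")
  }
  E <- length(ref$mean)
  stack <- function(field)
    matrix(vapply(summaries, function(s) as.numeric(s[[field]]), numeric(E)),
           nrow = E)
  structure(list(
    mean = rowMeans(stack("mean")),
    variance = rowMeans(stack("variance")),
    n_windows = rowMeans(stack("n_windows")),
    edge_index = ref$edge_index), class = "edge_summary")
}

#' Rank-correlation test of mean-variance scaling (Taylor's law)
#'
#' Tests whether the per-edge temporal variance scales with the per-edge
#' temporal mean by computing the Spearman rank correlation between the
#' two across edges. Under Taylor's law the correlation would be
#' positive; for windowed connectivity time-series it is expected to be
#' negative (edges with a high mean correlation have little room left to
#' fluctuate, and empirically fluctuate less than the bound requires).
#'
#' The two-sided p-value uses the t approximation with `n_edges - 2`
#' degrees of freedom, `t = rho * sqrt((n - 2) / (1 - rho^2))`. For tiny
#' edge sets (`n_edges <= 9`) an exact permutation p-value is available.
#'
#' @param summary an `edge_summary`.
#' @param exact if `TRUE` and `n_edges <= 9`, compute the exact
#'   permutation two-sided p-value instead of the t approximation.
#' @return An object of class `scaling_result`: list with `rho`,
#'   `p_value`, `n_edges`, `method`.
#' @export
mean_variance_scaling <- function(summary, exact = FALSE) {
  stopifnot(inherits(summary, "edge_summary"))
  m <- summary$mean; v <- summary$variance
  n <- length(m)
  if (n < 3L) stop("need at least 3 edges for a defined p-value")
  if (stats::sd(m) == 0 || stats::sd(v) == 0)
    stop("zero spread in means or variances: rank correlation undefined")
  rho <- stats::cor(m, v, method = "spearman")
  if (exact) {
    if (n > 9L) stop("exact permutation p-value limited to n_edges <= 9")
    p <- spearman_perm_pvalue(m, v)
    method <- "spearman (exact permutation)"
  } else {
    tt <- rho * sqrt((n - 2) / max(1 - rho^2, .Machine$double.eps))
    p <- 2 * stats::pt(-abs(tt), df = n - 2)
    method <- "spearman (t approximation)"
  }
  structure(list(rho = rho, p_value = p, n_edges = n, method = method),
            class = "scaling_result")
}

#' @export
print.scaling_result <- function(x, ...) {
  cat(sprintf("<scaling_result> rho = %.4f, p = %.3g (%s, %d edges)\n",
              x$rho, x$p_value, x$method, x$n_edges))
  invisible(x)
}

# exhaustive two-sided permutation p-value for the Spearman statistic
spearman_perm_pvalue <- function(x, y) {
  obs <- abs(stats::cor(x, y, method = "spearman"))
  perms <- all_permutations(length(y))
  stat <- apply(perms, 1L, function(p) abs(stats::cor(x, y[p], method = "spearman")))
  mean(stat >= obs - 1e-12)
}

all_permutations <- function(n) {
  if (n == 1L) return(matrix(1L, 1L, 1L))
  sub <- all_permutations(n - 1L)
  out <- matrix(0L, n * nrow(sub), n)
  row <- 1L
  for (k in seq_len(n)) {
    for (r in seq_len(nrow(sub))) {
      rest <- seq_len(n)[-k]
      out[row, ] <- c(k, rest[sub[r, ]])
      row <- row + 1L
    }
  }
  out
}
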
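# Independent brute-force oracles used across the suite. These are kept
# deliberately naive (explicit loops, explicit ranking) so that they share no
# code path with the package implementation.

# Spearman rank correlation: explicit average-rank ranking, then the
# product-moment formula applied to the ranks.
oracle_spearman <- function(x, y) {
  avg_rank <- function(v) {
    r <- numeric(length(v))
    for (i in seq_along(v)) {
      less <- sum(v < v[i])
      ties <- sum(v == v[i])
      r[i] <- less + (ties + 1) / 2
    }
    r
  }
  rx <- avg_rank(x); ry <- avg_rank(y)
  dx <- rx - mean(rx); dy <- ry - mean(ry)
  sum(dx * dy) / sqrt(sum(dx^2) * sum(dy^2))
}

# Pearson correlation from first principles.
oracle_pearson <- function(x, y) {
  dx <- x - mean(x); dy <- y - mean(y)
  sum(dx * dy) / sqrt(sum(dx^2) * sum(dy^2))
}

# Naive per-window recomputation of the full edge x window matrix.
oracle_sliding <- function(values, w, method = "spearman") {
  n <- nrow(values); T <- ncol(values)
  f <- if (method == "spearman") oracle_spearman else oracle_pearson
  pairs <- list()
  for (i in 1:(n - 1)) for (j in (i + 1):n) pairs[[length(pairs) + 1]] <- c(i, j)
  out <- matrix(NA_real_, length(pairs), T - w + 1)
  for (t in 1:(T - w + 1)) {
    for (e in seq_along(pairs)) {
      a <- values[pairs[[e]][1], t:(t + w - 1)]
      b <- values[pairs[[e]][2], t:(t + w - 1)]
      out[e, t] <- f(a, b)
    }
  }
  out
}

# Small cohort used by several files; mild size keeps the suite quick.
tiny_cohort <- function(n_subjects = 3, n_nodes = 12, n_blocks = 3,
                        n_timepoints = 120, seed = 11, ...) {
  generate_cohort(block_cohort_spec(n_subjects = n_subjects, n_nodes = n_nodes,
                                    n_blocks = n_blocks,
                                    n_timepoints = n_timepoints, seed = seed,
                                    ...))
}

# Bhatia-Davis-type bound for sample variances of [-1, 1]-valued series.
expect_bounded_variance <- function(summary) {
  bound <- (1 - summary$mean) * (1 + summary$mean) *
    summary$n_windows / (summary$n_windows - 1)
  expect_true(all(summary$variance <= bound + 1e-12))
}
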
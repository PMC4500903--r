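#' Classify edges as within- or between-network
#'
#' An edge (i, j) is "within" iff both endpoint nodes carry the same
#' network label in the partition; otherwise "between". The within and
#' between classes always partition the full edge set.
#'
#' @param x an `edge_series`, `edge_summary`, or an [edge_index()]
#'   matrix.
#' @param partition a [node_partition()] covering every node appearing
#'   in the edge index.
#' @return Factor of length E with levels `within`, `between`.
#' @export
classify_edges <- function(x, partition) {
  stopifnot(inherits(partition, "node_partition"))
  idx <- if (is.matrix(x)) x else x$edge_index
  if (is.null(idx)) stop("no edge index available on 'x'")
  n_needed <- max(idx)
  if (n_needed > length(partition$labels))
    stop("node ", n_needed, " has no label in the partition")
  lab <- partition$labels
  factor(ifelse(lab[idx[, 1L]] == lab[idx[, 2L]], "within", "between"),
         levels = c("within", "between"))
}

#' Within- versus between-network variance contrast
#'
#' For each subject, averages the per-edge temporal variances separately
#' over within-network and between-network edges, then compares the two
#' per-subject means with a two-tailed t-test across subjects (paired by
#' default, since both class means come from the same subject). The
#' t statistic is computed on the per-subject differences
#' `within - between`, so a negative t indicates lower variance for
#' within-network edges.
#'
#' When the paired differences are numerically constant the t statistic
#' is undefined: an all-zero difference vector yields `t = 0, p = 1`,
#' and a constant non-zero one is flagged `degenerate` (t and p `NA`)
#' rather than reported as infinite.
#'
#' @param summaries list of `edge_summary` objects, one per subject,
#'   sharing one edge index.
#' @param partition a [node_partition()].
#' @param paired use the paired t-test (default) or Welch's two-sample
#'   test.
#' @return An object of class `contrast_result`: per-subject
#'   `within_mean_variance` and `between_mean_variance`, `t_statistic`,
#'   `p_value`, `df`, `n_subjects`, `paired`, `degenerate`.
#' @export
variance_contrast <- function(summaries, partition, paired = TRUE) {
  if (inherits(summaries, "edge_summary"))
    stop("need summaries from >= 2 subjects")
  stopifnot(all(vapply(summaries, inherits, logical(1), "edge_summary")))
  if (length(summaries) < 2L) stop("need summaries from >= 2 subjects")
  cls <- classify_edges(summaries[[1L]], partition)
  if (!all(c("within", "between") %in% cls))
    stop("both edge classes must be non-empty; partition has ",
         nlevels(droplevels(cls)), " represented class(es)")
  within_mv <- vapply(summaries, function(s) mean(s$variance[cls == "within"]),
                      numeric(1))
  between_mv <- vapply(summaries, function(s) mean(s$variance[cls == "between"]),
                       numeric(1))
  degenerate <- FALSE
  if (paired) {
    d <- within_mv - between_mv
    n <- length(d)
    sd_d <- stats::sd(d)
    if (sd_d == 0) {
      if (all(d == 0)) { tt <- 0; p <- 1 } else {
        degenerate <- TRUE; tt <- NA_real_; p <- NA_real_
      }
    } else {
      tt <- mean(d) / (sd_d / sqrt(n))
      p <- 2 * stats::pt(-abs(tt), df = n - 1)
    }
    df <- n - 1
  } else {
    ht <- stats::t.test(within_mv, between_mv, paired = FALSE)
    tt <- unname(ht$statistic); p <- ht$p.value; df <- unname(ht$parameter)
  }
  structure(list(within_mean_variance = within_mv,
                 between_mean_variance = between_mv,
                 t_statistic = tt, p_value = p, df = df,
                 n_subjects = length(summaries), paired = paired,
                 degenerate = degenerate),
            class = "contrast_result")
}

#' @export
print.contrast_result <- function(x, ...) {
  cat(sprintf("<contrast_result> %d subjects; mean variance within %.4g vs between %.4g\n",
              x$n_subjects, mean(x$within_mean_variance),
              mean(x$between_mean_variance)))
  if (x$degenerate) {
    cat("  degenerate: constant non-zero paired differences; t undefined\n")
  } else {
    cat(sprintf("  %s t = %.3f, df = %g, p = %.3g (within - between)\n",
                if (x$paired) "paired" else "Welch", x$t_statistic, x$df,
                x$p_value))
  }
  invisible(x)
}

#' Node-by-node matrix of edge temporal variances
#'
#' Lays the per-edge variances out as a symmetric N x N matrix with
#' nodes grouped by network label (networks in order of first appearance
#' in the partition, nodes in original order inside each network) and
#' `NA` on the diagonal. Within-network variances form the diagonal
#' blocks of this view.
#'
#' @param summary an `edge_summary` covering all `choose(N, 2)` edges.
#' @param partition a [node_partition()].
#' @return Symmetric N x N matrix with node ids as dimnames and the
#'   reordered label vector attached as attribute `"network"`.
#' @export
variance_matrix <- function(summary, partition) {
  stopifnot(inherits(summary, "edge_summary"),
            inherits(partition, "node_partition"))
  lab <- partition$labels
  n <- length(lab)
  idx <- summary$edge_index
  if (is.null(idx)) idx <- edge_index(n)
  if (nrow(idx) != n * (n - 1) / 2 || max(idx) > n)
    stop("summary does not cover all edges of the partition's nodes")
  M <- matrix(NA_real_, n, n)
  M[idx] <- summary$variance
  M[idx[, c(2, 1)]] <- summary$variance
  dimnames(M) <- list(partition$node_ids, partition$node_ids)
  ord <- order(match(lab, unique(lab)))  # stable: keeps node order in-network
  M <- M[ord, ord]
  attr(M, "network") <- unname(lab[ord])
  M
}
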
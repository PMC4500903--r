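#' Ground-truth recovery error of the sliding-window estimator
#'
#' Measures how well sliding-window correlations recover the known
#' instantaneous correlation trajectories of a synthetic cohort. For
#' each edge class with a common ground truth (the within-block edges of
#' each block, and all between-block edges), the windowed correlations
#' are averaged over every edge of the class and every subject, giving
#' one estimated trajectory per class; this is compared, window by
#' window, against the window-averaged ground-truth trajectory (a
#' w-sample window estimates the mean instantaneous correlation over the
#' samples it covers). The error is the mean absolute difference across
#' windows.
#'
#' Recovery is only expected to be accurate when the coupling dynamics
#' are slow relative to the window (trajectory period of at least about
#' four window lengths); faster dynamics are smoothed out by the window
#' itself.
#'
#' @param cohort a `block_cohort` from [generate_cohort()].
#' @param window_length window length in samples.
#' @param method correlation method passed to
#'   [sliding_window_correlation()]; the product-moment coefficient is
#'   the default here because the ground truth is a Pearson correlation.
#' @return A list with `per_class` (data.frame: class, n_edges, mae) and
#'   `overall` (edge-count-weighted mean of the class MAEs).
#' @export
recovery_error <- function(cohort, window_length, method = "pearson") {
  stopifnot(inherits(cohort, "block_cohort"))
  spec <- cohort$spec
  w <- as.integer(window_length)
  idx <- edge_index(spec$n_nodes)
  blk <- match(spec$block_labels, spec$blocks)
  same <- blk[idx[, 1L]] == blk[idx[, 2L]]
  class_of <- ifelse(same, spec$blocks[blk[idx[, 1L]]], "between")

  est <- NULL
  for (s in cohort$subjects) {
    es <- sliding_window_correlation(s, w, method = method)
    est <- if (is.null(est)) es$values else est + es$values
  }
  est <- est / length(cohort$subjects)

  classes <- c(spec$blocks[spec$blocks %in% class_of], "between")
  classes <- classes[classes %in% class_of]
  per <- lapply(classes, function(cl) {
    truth <- if (cl == "between") cohort$ground_truth$between_corr
             else cohort$ground_truth$within_corr[cl, ]
    truth_w <- window_average(truth, w)
    traj <- colMeans(est[class_of == cl, , drop = FALSE])
    data.frame(class = cl, n_edges = sum(class_of == cl),
               mae = mean(abs(traj - truth_w)))
  })
  per <- do.call(rbind, per)
  list(per_class = per,
       overall = sum(per$mae * per$n_edges) / sum(per$n_edges))
}
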
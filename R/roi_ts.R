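#' ROI signal time-series
#'
#' Container for one subject's region-of-interest (node) signals: an
#' N x T numeric matrix (one row per node, one column per sample) plus
#' the sampling interval (TR, seconds).
#'
#' @param values N x T numeric matrix, no missing values.
#' @param node_ids character vector of N unique node identifiers;
#'   defaults to the matrix rownames or `"n1" ... "nN"`.
#' @param tr sampling interval in seconds (> 0).
#' @return An object of class `roi_ts`.
#' @export
roi_ts <- function(values, node_ids = NULL, tr = 2) {
  values <- as.matrix(values)
  if (!is.numeric(values)) stop("'values' must be a numeric matrix")
  if (nrow(values) < 2L) stop("need at least 2 nodes")
  if (ncol(values) < 2L) stop("need at least 2 time-points")
  if (anyNA(values)) stop("'values' must not contain missing values")
  if (!is.numeric(tr) || length(tr) != 1L || tr <= 0)
    stop("'tr' must be a single positive number (seconds)")
  if (is.null(node_ids)) node_ids <- rownames(values)
  if (is.null(node_ids)) node_ids <- paste0("n", seq_len(nrow(values)))
  node_ids <- as.character(node_ids)
  if (length(node_ids) != nrow(values)) stop("length(node_ids) != nrow(values)")
  if (anyDuplicated(node_ids)) stop("duplicate node ids: ",
                                    paste(unique(node_ids[duplicated(node_ids)]),
                                          collapse = ", "))
  attributes(values) <- list(dim = dim(values))  # drop stray attrs (e.g. from scale())
  rownames(values) <- node_ids
  structure(list(values = values, node_ids = node_ids, tr = tr),
            class = "roi_ts")
}

#' @export
print.roi_ts <- function(x, ...) {
  cat(sprintf("<roi_ts> %d nodes x %d time-points, TR = %g s\n",
              nrow(x$values), ncol(x$values), x$tr))
  invisible(x)
}

#' Node-to-network partition
#'
#' Assigns each node to a network label (e.g. a resting-state network).
#' The partition induces the within/between classification of edges:
#' an edge is "within" iff both endpoints carry the same label.
#'
#' @param labels character vector of network labels, one per node.
#' @param node_ids node identifiers; defaults to `names(labels)` or
#'   `"n1" ... "nN"`.
#' @return An object of class `node_partition`.
#' @export
node_partition <- function(labels, node_ids = NULL) {
  if (is.null(node_ids)) node_ids <- names(labels)
  labels <- as.character(labels)
  if (is.null(node_ids)) node_ids <- paste0("n", seq_along(labels))
  node_ids <- as.character(node_ids)
  if (length(node_ids) != length(labels)) stop("one label per node required")
  if (anyDuplicated(node_ids)) stop("duplicate node ids in partition")
  if (anyNA(labels) || any(!nzchar(labels)))
    stop("every node must carry a non-empty label")
  names(labels) <- node_ids
  structure(list(labels = labels, node_ids = node_ids),
            class = "node_partition")
}

#' @export
print.node_partition <- function(x, ...) {
  tab <- table(x$labels)
  cat(sprintf("<node_partition> %d nodes, %d networks\n",
              length(x$labels), length(tab)))
  print(tab)
  invisible(x)
}
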
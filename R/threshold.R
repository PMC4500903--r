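#' Magnitude-based edge binarization
#'
#' Declares an edge "present" at a window whenever its correlation
#' strictly exceeds a single global cutoff. This is the thresholding
#' strategy of static connectivity analysis carried over to the dynamic
#' case: sensitivity follows the magnitude of correlation, so edges with
#' a high temporal mean (typically within-network edges) dominate.
#'
#' @param es an `edge_series`, a numeric edges x windows matrix, or a
#'   single trajectory vector.
#' @param cutoff global correlation cutoff in (-1, 1).
#' @param absolute if `TRUE`, threshold `|r|` instead of signed r.
#' @return An object of class `binary_edge_series`: `present` (logical
#'   E x W matrix), `strategy`, `parameter`, `n_missing_masked` (count of
#'   missing source values mapped to absent).
#' @export
magnitude_threshold <- function(es, cutoff, absolute = FALSE) {
  if (!is.numeric(cutoff) || length(cutoff) != 1L || cutoff <= -1 || cutoff >= 1)
    stop("'cutoff' must be a single correlation value in (-1, 1)")
  v <- as_edge_matrix(es)
  if (absolute) v <- abs(v)
  present <- v > cutoff
  n_na <- sum(is.na(present))
  present[is.na(present)] <- FALSE
  new_binary_edge_series(present, "magnitude", cutoff, n_na,
                         attr(v, "edge_index"))
}

#' Variance-based edge binarization
#'
#' Declares an edge "present" at a window whenever its correlation
#' strictly exceeds that edge's own temporal mean plus `k` sample
#' standard deviations. Each edge is judged against its own history, so
#' sensitivity follows the size of fluctuations rather than the level:
#' an edge oscillating around zero can be "present" at its peaks while a
#' flat edge with a high mean never is. Adding a constant to a
#' trajectory leaves its variance-based raster unchanged — the
#' operational difference from [magnitude_threshold()].
#'
#' A constant (zero-variance) edge has no window exceeding mean + k*0
#' strictly, so it is entirely absent.
#'
#' @param es an `edge_series`, numeric matrix, or trajectory vector.
#' @param k standard-deviation multiplier (> 0); default 1.
#' @return A `binary_edge_series` (see [magnitude_threshold()]).
#' @export
variance_threshold <- function(es, k = 1) {
  if (!is.numeric(k) || length(k) != 1L || k <= 0)
    stop("'k' must be a single positive SD multiplier")
  v <- as_edge_matrix(es)
  n_ok <- rowSums(!is.na(v))
  if (any(n_ok < 2L))
    stop("every edge needs >= 2 usable windows for a variance threshold")
  m <- rowMeans(v, na.rm = TRUE)
  s <- sqrt(rowSums((v - m)^2, na.rm = TRUE) / (n_ok - 1L))
  present <- v > (m + k * s)
  n_na <- sum(is.na(present))
  present[is.na(present)] <- FALSE
  new_binary_edge_series(present, "variance", k, n_na, attr(v, "edge_index"))
}

new_binary_edge_series <- function(present, strategy, parameter, n_missing,
                                   edge_index = NULL) {
  structure(list(present = present, strategy = strategy, parameter = parameter,
                 n_missing_masked = n_missing, edge_index = edge_index),
            class = "binary_edge_series")
}

#' @export
print.binary_edge_series <- function(x, ...) {
  cat(sprintf("<binary_edge_series> %d edges x %d windows, %s (%s = %g), density %.3f\n",
              nrow(x$present), ncol(x$present), x$strategy,
              if (x$strategy == "magnitude") "cutoff" else "k",
              x$parameter, mean(x$present)))
  invisible(x)
}

#' Agreement between two edge-presence rasters
#'
#' Quantifies how differently two binarization strategies select
#' time-points: per edge, the Jaccard index of the two present sets
#' (intersection over union; two empty sets count as identical, Jaccard
#' 1), plus the global presence density of each raster.
#'
#' @param a,b `binary_edge_series` objects of identical shape.
#' @return A list of class `presence_overlap` with `jaccard` (per-edge
#'   numeric vector), `density_a`, `density_b`.
#' @export
presence_overlap <- function(a, b) {
  stopifnot(inherits(a, "binary_edge_series"), inherits(b, "binary_edge_series"))
  if (!identical(dim(a$present), dim(b$present)))
    stop("rasters have different shapes: ",
         paste(dim(a$present), collapse = "x"), " vs ",
         paste(dim(b$present), collapse = "x"))
  inter <- rowSums(a$present & b$present)
  union <- rowSums(a$present | b$present)
  jac <- ifelse(union == 0L, 1, inter / union)
  structure(list(jaccard = jac, density_a = mean(a$present),
                 density_b = mean(b$present)),
            class = "presence_overlap")
}

#' @export
print.presence_overlap <- function(x, ...) {
  cat(sprintf("<presence_overlap> %d edges; mean Jaccard %.3f; densities %.3f vs %.3f\n",
              length(x$jaccard), mean(x$jaccard), x$density_a, x$density_b))
  invisible(x)
}
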
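#' Plot an edge-presence raster
#'
#' Draws a binary raster (windows on x, edges on y) in the style of the
#' worked thresholding example: dark where an edge is absent, light
#' where present.
#'
#' @param bes a `binary_edge_series`.
#' @param ... passed to [graphics::image()].
#' @export
plot_presence_raster <- function(bes, ...) {
  stopifnot(inherits(bes, "binary_edge_series"))
  z <- t(bes$present) * 1
  graphics::image(x = seq_len(nrow(z)), y = seq_len(ncol(z)), z = z,
                  col = c("black", "white"), xlab = "window",
                  ylab = "edge", useRaster = TRUE, ...)
  invisible(NULL)
}

#' Heatmap of the network-ordered variance matrix
#'
#' Displays a [variance_matrix()] with nodes grouped by network and
#' separator lines between networks, so that within-network edges appear
#' as diagonal blocks.
#'
#' @param vm matrix from [variance_matrix()].
#' @param ... passed to [graphics::image()].
#' @export
plot_variance_matrix <- function(vm, ...) {
  n <- nrow(vm)
  pal <- grDevices::hcl.colors(64, "YlOrRd", rev = TRUE)
  graphics::image(x = seq_len(n), y = seq_len(n), z = t(vm[n:1, ]),
                  col = pal, xlab = "node", ylab = "node",
                  useRaster = TRUE, ...)
  net <- attr(vm, "network")
  if (!is.null(net)) {
    cuts <- which(diff(as.integer(factor(net, levels = unique(net)))) != 0) + 0.5
    graphics::abline(v = cuts, h = n - cuts + 1, col = "grey30", lwd = 0.8)
  }
  invisible(NULL)
}
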
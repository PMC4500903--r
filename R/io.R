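#' Read and write ROI time-series tables
#'
#' The on-disk layout is one row per node: a header row of time indices
#' (`t0, t1, ...`), a first column `node` of node identifiers, and one
#' numeric column per sample. Tab-separated by default; files ending in
#' `.csv` are read/written comma-separated. Reading validates the table
#' strictly: ragged rows, non-numeric or missing cells and duplicate
#' node ids are parse errors that name the offending row/column.
#'
#' @param ts a [roi_ts()].
#' @param path file path (`.tsv` or `.csv`).
#' @param tr sampling interval in seconds to attach on read (the table
#'   itself carries no time units).
#' @return `read_roi_table()` returns a [roi_ts()];
#'   `write_roi_table()` returns `path` invisibly.
#' @export
write_roi_table <- function(ts, path) {
  stopifnot(inherits(ts, "roi_ts"))
  sep <- table_sep(path)
  # 17 significant digits => bit-exact write/read round trip for doubles
  chr <- matrix(fmt_num(ts$values), nrow = nrow(ts$values))
  df <- data.frame(node = ts$node_ids, chr, check.names = FALSE)
  colnames(df) <- c("node", paste0("t", seq_len(ncol(ts$values)) - 1L))
  utils::write.table(df, path, sep = sep, quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_roi_table
#' @export
read_roi_table <- function(path, tr = 2) {
  sep <- table_sep(path)
  nf <- utils::count.fields(path, sep = sep, quote = "")
  if (length(unique(nf)) > 1L)
    stop(sprintf("ragged table '%s': line %d has %d fields, expected %d",
                 path, which(nf != nf[1L])[1L], nf[nf != nf[1L]][1L], nf[1L]))
  df <- utils::read.table(path, header = TRUE, sep = sep, quote = "",
                          check.names = FALSE, colClasses = "character")
  if (ncol(df) < 3L) stop("need a node column plus at least 2 time-points")
  ids <- df[[1L]]
  if (anyDuplicated(ids))
    stop("duplicate node ids: ", paste(unique(ids[duplicated(ids)]), collapse = ", "))
  vals <- matrix(NA_real_, nrow(df), ncol(df) - 1L)
  for (j in 2:ncol(df)) {
    v <- suppressWarnings(as.numeric(df[[j]]))
    bad <- which(is.na(v) | !nzchar(trimws(df[[j]])))
    if (length(bad))
      stop(sprintf("non-numeric or missing cell at row %d (node '%s'), column '%s'",
                   bad[1L], ids[bad[1L]], colnames(df)[j]))
    vals[, j - 1L] <- v
  }
  roi_ts(vals, node_ids = ids, tr = tr)
}

table_sep <- function(path) {
  if (grepl("\\.csv$", path, ignore.case = TRUE)) "," else "\t"
}

fmt_num <- function(x) formatC(x, digits = 17, format = "g")

#' Read and write node-partition tables
#'
#' Two tab-separated columns with a header: `node` and `label`.
#'
#' @param partition a [node_partition()].
#' @param path file path.
#' @return `read_partition()` returns a [node_partition()].
#' @export
write_partition <- function(partition, path) {
  stopifnot(inherits(partition, "node_partition"))
  utils::write.table(data.frame(node = partition$node_ids,
                                label = partition$labels),
                     path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_partition
#' @export
read_partition <- function(path) {
  df <- utils::read.table(path, header = TRUE, sep = "\t", quote = "",
                          colClasses = "character")
  if (ncol(df) < 2L) stop("partition file needs columns node and label")
  node_partition(df[[2L]], node_ids = df[[1L]])
}

#' Write per-edge summary statistics as TSV
#'
#' Columns: `edge_i`, `edge_j` (1-based node indices), `mean`,
#' `variance`, `n_windows`.
#'
#' @param summary an `edge_summary`.
#' @param path file path.
#' @export
write_edge_summary <- function(summary, path) {
  stopifnot(inherits(summary, "edge_summary"))
  idx <- summary$edge_index
  if (is.null(idx)) idx <- cbind(i = NA_integer_, j = NA_integer_)[rep(1, length(summary$mean)), ]
  utils::write.table(data.frame(edge_i = idx[, 1L], edge_j = idx[, 2L],
                                mean = fmt_num(summary$mean),
                                variance = fmt_num(summary$variance),
                                n_windows = summary$n_windows),
                     path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Write an edge correlation series in long format
#'
#' One row per (edge, window): `edge_i`, `edge_j`, `window` (1-based),
#' `value`. Missing correlations are written as `NA`.
#'
#' @param es an `edge_series`.
#' @param path file path.
#' @export
write_edge_series <- function(es, path) {
  stopifnot(inherits(es, "edge_series"))
  E <- nrow(es$values); W <- ncol(es$values)
  utils::write.table(data.frame(edge_i = rep(es$edge_index[, 1L], W),
                                edge_j = rep(es$edge_index[, 2L], W),
                                window = rep(seq_len(W), each = E),
                                value = as.vector(es$values)),
                     path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Write a synthetic cohort to a directory
#'
#' One TSV per subject (`subject_01.tsv`, ...), the node partition
#' (`partition.tsv`) and a JSON sidecar (`cohort.json`) recording the
#' full generating spec including the seed.
#'
#' @param cohort a `block_cohort`.
#' @param dir output directory (created if needed).
#' @return The directory path, invisibly.
#' @export
write_cohort <- function(cohort, dir) {
  stopifnot(inherits(cohort, "block_cohort"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  for (s in seq_along(cohort$subjects))
    write_roi_table(cohort$subjects[[s]],
                    file.path(dir, sprintf("subject_%02d.tsv", s)))
  write_partition(cohort$partition, file.path(dir, "partition.tsv"))
  spec <- cohort$spec
  side <- list(n_subjects = spec$n_subjects, n_nodes = spec$n_nodes,
               block_labels = spec$block_labels,
               n_timepoints = spec$n_timepoints, tr = spec$tr,
               within_coupling = lapply(spec$within_coupling, unclass),
               global_coupling = unclass(spec$global_coupling),
               latent_bandpass = spec$latent_bandpass, seed = spec$seed)
  jsonlite::write_json(side, file.path(dir, "cohort.json"),
                       auto_unbox = TRUE, digits = NA, null = "null")
  invisible(dir)
}
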
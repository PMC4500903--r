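#' Pipeline run configuration
#'
#' Collects everything a full analysis run needs: the window length in
#' seconds, the sampling interval, the correlation method, the
#' binarization parameters, the seed, and either a synthetic cohort spec
#' or paths to input data. The window must be an integer number of
#' samples (`window_seconds / tr` integral); this is validated up front.
#'
#' @param window_seconds sliding-window length in seconds.
#' @param tr sampling interval in seconds.
#' @param method `"spearman"` or `"pearson"`.
#' @param cutoffs magnitude cutoffs applied in the thresholding stage.
#' @param k SD multiplier for the variance threshold.
#' @param seed integer seed; overrides the cohort spec's seed so one
#'   number controls the whole run.
#' @param cohort a [block_cohort_spec()] to simulate inputs, or `NULL`
#'   when reading files.
#' @param input_dir directory of subject TSV tables (used when `cohort`
#'   is `NULL`); every `*.tsv`/`*.csv` except `partition.tsv` is read as
#'   one subject.
#' @param partition_file path to the node-partition TSV (defaults to
#'   `partition.tsv` inside `input_dir`).
#' @param out_dir where to write stage outputs and the manifest, or
#'   `NULL` to keep results in memory only.
#' @param store_edges also write the (large) per-subject long-format
#'   edge series.
#' @return An object of class `run_config`.
#' @export
run_config <- function(window_seconds = 90, tr = 2,
                       method = c("spearman", "pearson"),
                       cutoffs = c(0.3, 0.2, 0.15), k = 1, seed = 1,
                       cohort = block_cohort_spec(tr = tr),
                       input_dir = NULL, partition_file = NULL,
                       out_dir = NULL, store_edges = FALSE) {
  method <- match.arg(method)
  w <- seconds_to_samples(window_seconds, tr)  # validates integrality
  if (is.null(cohort) && is.null(input_dir))
    stop("either a cohort spec or an input directory is required")
  if (!is.null(input_dir) && !dir.exists(input_dir))
    stop("input directory not found: ", input_dir)
  if (!is.null(partition_file) && !file.exists(partition_file))
    stop("partition file not found: ", partition_file)
  structure(list(window_seconds = window_seconds, tr = tr, method = method,
                 cutoffs = cutoffs, k = k, seed = as.integer(seed),
                 cohort = cohort, input_dir = input_dir,
                 partition_file = partition_file, out_dir = out_dir,
                 store_edges = isTRUE(store_edges), window_samples = w),
            class = "run_config")
}

#' Read a run configuration from YAML
#'
#' Recognised top-level keys mirror the [run_config()] arguments;
#' `cohort` is a nested map with [block_cohort_spec()] fields, whose
#' `within_coupling`/`global_coupling` entries are maps with
#' [coupling_trajectory()] fields (`type`, then `value` or
#' `mean`/`amplitude`/`period`/`phase`).
#'
#' @param path YAML file.
#' @param ... overrides applied on top of the file's values.
#' @return A `run_config`.
#' @export
read_run_config <- function(path, ...) {
  y <- yaml::read_yaml(path)
  if (!is.null(y$cohort)) {
    cs <- y$cohort
    for (f in c("within_coupling", "global_coupling"))
      if (!is.null(cs[[f]])) cs[[f]] <- do.call(coupling_trajectory, cs[[f]])
    if (!is.null(cs$latent_bandpass)) cs$latent_bandpass <- unlist(cs$latent_bandpass)
    y$cohort <- do.call(block_cohort_spec, cs)
  }
  if (!is.null(y$cutoffs)) y$cutoffs <- unlist(y$cutoffs)
  over <- list(...)
  y[names(over)] <- over
  do.call(run_config, y)
}

#' Run the full dynamic-connectivity pipeline
#'
#' Executes simulate (or read) -> sliding-window connectivity ->
#' edge summaries and the mean-variance scaling test -> both
#' binarization strategies -> the within/between-network variance
#' contrast, and assembles a manifest with the configuration, its hash,
#' per-stage timings, missing-value counts and (when writing to disk)
#' the MD5 of every output file. The run is deterministic: the same
#' configuration and seed reproduce identical outputs and hashes.
#'
#' @param config a [run_config()].
#' @return A list of class `pipeline_run` with `manifest` and `results`
#'   (subjects, partition, edge summaries, group summary, scaling,
#'   thresholds, contrast, variance matrix).
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "run_config"))
  w <- config$window_samples
  timings <- c(); tic <- function() proc.time()[["elapsed"]]
  out <- config$out_dir
  if (!is.null(out)) dir.create(out, recursive = TRUE, showWarnings = FALSE)

  # stage: simulate | ingest
  t0 <- tic()
  if (!is.null(config$cohort)) {
    spec <- config$cohort; spec$seed <- config$seed
    cohort <- generate_cohort(spec)
    subjects <- cohort$subjects; partition <- cohort$partition
  } else {
    files <- sort(list.files(config$input_dir, pattern = "\\.(tsv|csv)$",
                             full.names = TRUE))
    files <- files[basename(files) != "partition.tsv"]
    if (!length(files)) stop("stage ingest: no subject tables in ", config$input_dir)
    subjects <- lapply(files, read_roi_table, tr = config$tr)
    pf <- config$partition_file
    if (is.null(pf)) pf <- file.path(config$input_dir, "partition.tsv")
    if (!file.exists(pf)) stop("stage ingest: partition file not found: ", pf)
    partition <- read_partition(pf)
    cohort <- NULL
  }
  timings["inputs"] <- tic() - t0

  # stage: connect
  t0 <- tic()
  series <- lapply(subjects, sliding_window_correlation, window_length = w,
                   method = config$method)
  n_missing <- sum(vapply(series, `[[`, numeric(1), "n_missing"))
  timings["connect"] <- tic() - t0

  # stage: stats
  t0 <- tic()
  summaries <- lapply(series, summarize_edges)
  group <- group_average(summaries)
  scaling <- mean_variance_scaling(group)
  timings["stats"] <- tic() - t0

  # stage: threshold (first subject's series as the demo target)
  t0 <- tic()
  magnitude <- lapply(config$cutoffs, function(cc)
    magnitude_threshold(series[[1L]], cc))
  names(magnitude) <- paste0("cutoff_", config$cutoffs)
  variance <- variance_threshold(series[[1L]], k = config$k)
  timings["threshold"] <- tic() - t0

  # stage: rsn
  t0 <- tic()
  contrast <- variance_contrast(summaries, partition)
  vmat <- variance_matrix(group, partition)
  timings["rsn"] <- tic() - t0

  manifest <- list(
    config = config_to_list(config),
    seed = config$seed,
    n_subjects = length(subjects),
    n_nodes = length(subjects[[1L]]$node_ids),
    n_edges = nrow(series[[1L]]$values),
    n_windows = ncol(series[[1L]]$values),
    window_samples = w,
    n_missing_correlations = n_missing,
    scaling = list(rho = scaling$rho, p_value = scaling$p_value),
    contrast = list(t = contrast$t_statistic, p_value = contrast$p_value,
                    mean_within = mean(contrast$within_mean_variance),
                    mean_between = mean(contrast$between_mean_variance)),
    raster_density = c(vapply(magnitude, function(b) mean(b$present), numeric(1)),
                       variance_k = mean(variance$present)),
    timings_seconds = as.list(round(timings, 3)))
  manifest$config_hash <- hash_object(manifest$config)

  if (!is.null(out)) {
    write_partition(partition, file.path(out, "partition.tsv"))
    write_edge_summary(group, file.path(out, "group_summary.tsv"))
    jsonlite::write_json(list(rho = scaling$rho, p_value = scaling$p_value,
                              n_edges = scaling$n_edges),
                         file.path(out, "scaling.json"),
                         auto_unbox = TRUE, digits = NA)
    jsonlite::write_json(list(t_statistic = contrast$t_statistic,
                              p_value = contrast$p_value,
                              within_mean_variance = contrast$within_mean_variance,
                              between_mean_variance = contrast$between_mean_variance,
                              n_subjects = contrast$n_subjects),
                         file.path(out, "contrast.json"),
                         auto_unbox = TRUE, digits = NA)
    vm <- vmat; vm[is.na(vm)] <- ""
    utils::write.table(vm, file.path(out, "variance_matrix.tsv"), sep = "\t",
                       quote = FALSE, col.names = NA)
    if (config$store_edges)
      for (s in seq_along(series))
        write_edge_series(series[[s]],
                          file.path(out, sprintf("edges_subject_%02d.tsv", s)))
    files <- sort(list.files(out, full.names = TRUE))
    files <- files[basename(files) != "manifest.json"]
    manifest$output_md5 <- as.list(stats::setNames(unname(tools::md5sum(files)),
                                                   basename(files)))
    jsonlite::write_json(manifest, file.path(out, "manifest.json"),
                         auto_unbox = TRUE, digits = NA, null = "null")
  }

  structure(list(manifest = manifest,
                 results = list(subjects = subjects, partition = partition,
                                series = series, summaries = summaries,
                                group_summary = group, scaling = scaling,
                                magnitude_rasters = magnitude,
                                variance_raster = variance,
                                contrast = contrast, variance_matrix = vmat,
                                cohort = cohort)),
            class = "pipeline_run")
}

#' @export
print.pipeline_run <- function(x, ...) {
  m <- x$manifest
  cat(sprintf("<pipeline_run> %d subjects, %d edges x %d windows (w = %d, %s)\n",
              m$n_subjects, m$n_edges, m$n_windows, m$window_samples,
              m$config$method))
  cat(sprintf("  scaling rho = %.4f (p = %.3g); contrast t = %.3f (p = %.3g)\n",
              m$scaling$rho, m$scaling$p_value, m$contrast$t, m$contrast$p_value))
  invisible(x)
}

#' Robustness sweep over window lengths and correlation methods
#'
#' Re-runs connectivity, summaries and the mean-variance scaling test on
#' one set of subjects for every combination of window length and
#' correlation method, mirroring the replication design that checks the
#' scaling relation is not an artifact of one window choice (e.g. 50 s
#' and 130 s windows, and the Pearson coefficient, alongside the 90 s
#' Spearman default).
#'
#' @param subjects list of [roi_ts()] (or a `block_cohort`).
#' @param window_seconds window lengths in seconds.
#' @param methods correlation methods.
#' @param tr sampling interval in seconds.
#' @return data.frame with one row per combination: `window_seconds`,
#'   `method`, `window_samples`, `rho`, `p_value`.
#' @export
sweep_scaling <- function(subjects, window_seconds = c(50, 90, 130),
                          methods = c("spearman", "pearson"), tr = 2) {
  if (inherits(subjects, "block_cohort")) subjects <- subjects$subjects
  grid <- expand.grid(window_seconds = window_seconds, method = methods,
                      stringsAsFactors = FALSE)
  res <- lapply(seq_len(nrow(grid)), function(r) {
    w <- seconds_to_samples(grid$window_seconds[r], tr)
    summaries <- lapply(subjects, function(s)
      summarize_edges(sliding_window_correlation(s, w, method = grid$method[r])))
    sc <- mean_variance_scaling(group_average(summaries))
    data.frame(window_seconds = grid$window_seconds[r],
               method = grid$method[r], window_samples = w,
               rho = sc$rho, p_value = sc$p_value)
  })
  do.call(rbind, res)
}

config_to_list <- function(config) {
  list(window_seconds = config$window_seconds, tr = config$tr,
       method = config$method, cutoffs = config$cutoffs, k = config$k,
       seed = config$seed,
       cohort = if (is.null(config$cohort)) NULL else {
         sp <- config$cohort
         list(n_subjects = sp$n_subjects, n_nodes = sp$n_nodes,
              block_labels = sp$block_labels, n_timepoints = sp$n_timepoints,
              tr = sp$tr,
              within_coupling = lapply(sp$within_coupling, unclass),
              global_coupling = unclass(sp$global_coupling),
              latent_bandpass = sp$latent_bandpass, seed = sp$seed)
       },
       input_dir = config$input_dir, partition_file = config$partition_file,
       store_edges = config$store_edges)
}

# md5 of the canonical JSON serialization (written to a temp file)
hash_object <- function(x) {
  f <- tempfile(fileext = ".json")
  on.exit(unlink(f))
  jsonlite::write_json(x, f, auto_unbox = TRUE, digits = NA, null = "null")
  unname(tools::md5sum(f))
}
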
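#' Specification of a synthetic block-structured cohort
#'
#' Describes a multi-subject cohort of BOLD-like node time-series with a
#' prescribed, analytically known time-varying correlation structure.
#' Nodes are organised into K blocks (emulating resting-state networks).
#' Node i in block k is generated by the mixing model
#'
#'   x_i(t) = a_k(t) g_k(t) + b(t) h(t) + sqrt(1 - a_k(t)^2 - b(t)^2) e_i(t)
#'
#' where g_k (one per block), h (shared by all nodes) and e_i (one per
#' node) are independent zero-mean unit-variance latent series. The
#' model-implied instantaneous correlation is a_k(t)^2 + b(t)^2 for a
#' pair of nodes in the same block k, and b(t)^2 for nodes in different
#' blocks; these closed forms are returned as ground truth alongside the
#' simulated data.
#'
#' The defaults give a cohort with constant, high within-block coupling
#' and a slowly fluctuating, low shared coupling: within-block edges
#' then have a high temporal mean and low temporal variance of windowed
#' correlation while between-block edges show the opposite, the designed
#' effect the downstream contrast statistics are validated against.
#'
#' @param n_subjects number of subjects.
#' @param n_nodes total number of nodes N.
#' @param n_blocks number of equally sized blocks K (used when
#'   `block_labels` is not given; N must then be divisible by K).
#' @param block_labels optional explicit length-N vector of block labels.
#' @param n_timepoints number of samples T per subject.
#' @param tr sampling interval in seconds.
#' @param within_coupling a [coupling_trajectory()] for a_k(t), or a list
#'   of one trajectory per block.
#' @param global_coupling a [coupling_trajectory()] for b(t).
#' @param latent_bandpass length-2 numeric, the frequency band in Hz
#'   applied to the latent series (Butterworth, applied forwards and
#'   backwards, then re-standardized), or `NULL` for white latents. The
#'   default 0.008-0.1 Hz matches the band conventionally used for
#'   resting-state BOLD.
#' @param seed integer RNG seed; the cohort is a deterministic function
#'   of the spec.
#' @return An object of class `block_cohort_spec`.
#' @seealso [generate_cohort()]
#' @export
block_cohort_spec <- function(n_subjects = 20, n_nodes = 40, n_blocks = 4,
                              block_labels = NULL, n_timepoints = 240, tr = 2,
                              within_coupling = coupling_trajectory("constant", value = 0.8),
                              global_coupling = coupling_trajectory("sinusoid",
                                mean = 0.3, amplitude = 0.2, period = 200),
                              latent_bandpass = c(0.008, 0.1), seed = 42) {
  if (n_subjects < 1) stop("'n_subjects' must be >= 1")
  if (n_nodes < 2) stop("'n_nodes' must be >= 2")
  if (n_timepoints < 2) stop("'n_timepoints' must be >= 2")
  if (tr <= 0) stop("'tr' must be > 0 (seconds)")
  if (is.null(block_labels)) {
    if (n_nodes %% n_blocks != 0)
      stop("'n_nodes' must be divisible by 'n_blocks' when 'block_labels' is not given")
    block_labels <- rep(paste0("B", seq_len(n_blocks)), each = n_nodes / n_blocks)
  }
  block_labels <- as.character(block_labels)
  if (length(block_labels) != n_nodes)
    stop("'block_labels' must have one entry per node")
  blocks <- unique(block_labels)
  sizes <- table(block_labels)
  if (any(sizes < 2)) stop("every block needs at least 2 nodes")
  if (inherits(within_coupling, "coupling_trajectory"))
    within_coupling <- stats::setNames(rep(list(within_coupling), length(blocks)), blocks)
  if (length(within_coupling) != length(blocks))
    stop("'within_coupling' must be one trajectory, or one per block")
  if (is.null(names(within_coupling))) names(within_coupling) <- blocks
  if (!is.null(latent_bandpass)) {
    latent_bandpass <- as.numeric(latent_bandpass)
    if (length(latent_bandpass) != 2L || any(latent_bandpass <= 0) ||
        diff(latent_bandpass) <= 0)
      stop("'latent_bandpass' must be c(low, high) in Hz with 0 < low < high")
    if (latent_bandpass[2] >= 1 / (2 * tr))
      stop("upper band edge must be below the Nyquist frequency 1/(2*tr)")
  }
  seed <- as.integer(seed)
  spec <- structure(list(n_subjects = as.integer(n_subjects),
                         n_nodes = as.integer(n_nodes),
                         block_labels = block_labels,
                         blocks = blocks,
                         n_timepoints = as.integer(n_timepoints), tr = tr,
                         within_coupling = within_coupling,
                         global_coupling = global_coupling,
                         latent_bandpass = latent_bandpass, seed = seed),
                    class = "block_cohort_spec")
  # feasibility: noise variance 1 - a^2 - b^2 must be non-negative everywhere
  a <- cohort_within_trajectories(spec)
  b <- eval_trajectory(global_coupling, n_timepoints)
  if (any(a < 0) || any(a > 1) || any(b < 0) || any(b > 1))
    stop("coupling trajectories must stay in [0, 1]")
  if (any(sweep(a^2, 2, b^2, `+`) > 1 + 1e-12))
    stop("a_k(t)^2 + b(t)^2 exceeds 1 at some t: noise variance would be negative")
  spec
}

# K x T matrix of within-coupling trajectories, rows ordered like spec$blocks
cohort_within_trajectories <- function(spec) {
  a <- t(vapply(spec$blocks,
                function(k) eval_trajectory(spec$within_coupling[[k]], spec$n_timepoints),
                numeric(spec$n_timepoints)))
  rownames(a) <- spec$blocks
  a
}

# zero-phase Butterworth bandpass of each column, then re-standardization
bandpass_standardize <- function(x, band, tr) {
  if (!is.null(band)) {
    ny <- 1 / (2 * tr)
    bf <- signal::butter(2, band / ny, type = "pass")
    x <- apply(x, 2, function(col) signal::filtfilt(bf, col))
  }
  scale(x)[, , drop = FALSE]
}

#' Generate a synthetic cohort with known correlation structure
#'
#' Simulates every subject of a [block_cohort_spec()] and returns the
#' subjects together with the closed-form ground-truth correlation
#' trajectories of the mixing model. Each node series is standardized to
#' zero mean and unit sample variance, which leaves all windowed
#' correlations unchanged. The cohort is bit-reproducible: the same spec
#' (including seed) always yields the same data, and subject s is
#' generated from its own deterministic substream so that it does not
#' change when `n_subjects` grows.
#'
#' @param spec a [block_cohort_spec()].
#' @return A list of class `block_cohort` with elements
#'   \describe{
#'     \item{subjects}{list of [roi_ts()] objects, one per subject}
#'     \item{partition}{[node_partition()] mapping nodes to blocks}
#'     \item{ground_truth}{list with `within_corr` (K x T matrix, one row
#'       per block, r_k(t) = a_k(t)^2 + b(t)^2) and `between_corr`
#'       (length-T vector, b(t)^2)}
#'     \item{spec}{the input spec}
#'   }
#' @export
generate_cohort <- function(spec) {
  stopifnot(inherits(spec, "block_cohort_spec"))
  N <- spec$n_nodes; T <- spec$n_timepoints; K <- length(spec$blocks)
  a <- cohort_within_trajectories(spec)                  # K x T
  b <- eval_trajectory(spec$global_coupling, T)          # T
  noise_w <- sqrt(pmax(1 - sweep(a^2, 2, b^2, `+`), 0))  # K x T
  block_of <- match(spec$block_labels, spec$blocks)      # node -> block row

  set.seed(spec$seed)
  subject_seeds <- sample.int(.Machine$integer.max - 1L, spec$n_subjects)

  subjects <- vector("list", spec$n_subjects)
  for (s in seq_len(spec$n_subjects)) {
    set.seed(subject_seeds[s])
    g <- bandpass_standardize(matrix(stats::rnorm(T * K), T, K),
                              spec$latent_bandpass, spec$tr)
    h <- bandpass_standardize(matrix(stats::rnorm(T), T, 1),
                              spec$latent_bandpass, spec$tr)[, 1]
    e <- bandpass_standardize(matrix(stats::rnorm(T * N), T, N),
                              spec$latent_bandpass, spec$tr)
    x <- matrix(0, N, T)
    for (i in seq_len(N)) {
      k <- block_of[i]
      x[i, ] <- a[k, ] * g[, k] + b * h + noise_w[k, ] * e[, i]
    }
    x <- t(scale(t(x)))  # unit sample variance contract; correlations unchanged
    subjects[[s]] <- roi_ts(x, node_ids = paste0("n", seq_len(N)), tr = spec$tr)
  }

  within_corr <- a^2 + matrix(b^2, K, T, byrow = TRUE)
  rownames(within_corr) <- spec$blocks
  structure(list(subjects = subjects,
                 partition = node_partition(spec$block_labels,
                                            paste0("n", seq_len(N))),
                 ground_truth = list(within_corr = within_corr,
                                     between_corr = b^2),
                 spec = spec),
            class = "block_cohort")
}

#' @export
print.block_cohort <- function(x, ...) {
  cat(sprintf("<block_cohort> %d subjects, %d nodes in %d blocks, T = %d, TR = %g s\n",
              length(x$subjects), x$spec$n_nodes, length(x$spec$blocks),
              x$spec$n_timepoints, x$spec$tr))
  invisible(x)
}
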
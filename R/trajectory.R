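#' Coupling trajectory specification
#'
#' A small declarative description of how a (dimensionless) coupling
#' coefficient evolves over discrete time. Two shapes are supported:
#' a constant level and a sinusoid. Trajectories are evaluated on the
#' integer sample grid `t = 0, 1, ..., T - 1` (one sample per TR).
#'
#' @param type `"constant"` or `"sinusoid"`.
#' @param value level of a constant trajectory.
#' @param mean offset of a sinusoid trajectory.
#' @param amplitude sinusoid amplitude (>= 0).
#' @param period sinusoid period in samples (> 0).
#' @param phase sinusoid phase in radians.
#' @return An object of class `coupling_trajectory`.
#' @seealso [eval_trajectory()], [block_cohort_spec()]
#' @export
#' @examples
#' b <- coupling_trajectory("sinusoid", mean = 0.3, amplitude = 0.2, period = 200)
#' head(eval_trajectory(b, 10))
coupling_trajectory <- function(type = c("constant", "sinusoid"), value = NULL,
                                mean = NULL, amplitude = NULL, period = NULL,
                                phase = 0) {
  type <- match.arg(type)
  if (type == "constant") {
    if (is.null(value) || !is.numeric(value) || length(value) != 1L)
      stop("a constant trajectory needs a single numeric 'value'")
    traj <- list(type = type, value = as.numeric(value))
  } else {
    if (is.null(mean) || is.null(amplitude) || is.null(period))
      stop("a sinusoid trajectory needs 'mean', 'amplitude' and 'period'")
    if (amplitude < 0) stop("'amplitude' must be >= 0")
    if (period <= 0) stop("'period' must be > 0")
    traj <- list(type = type, mean = as.numeric(mean),
                 amplitude = as.numeric(amplitude),
                 period = as.numeric(period), phase = as.numeric(phase))
  }
  class(traj) <- "coupling_trajectory"
  traj
}

#' Evaluate a coupling trajectory on the sample grid
#'
#' @param traj a [coupling_trajectory()].
#' @param n_timepoints number of samples T; values are returned for
#'   `t = 0, ..., T - 1`.
#' @return Numeric vector of length `n_timepoints`.
#' @export
eval_trajectory <- function(traj, n_timepoints) {
  stopifnot(inherits(traj, "coupling_trajectory"), n_timepoints >= 1)
  t <- seq_len(n_timepoints) - 1
  if (traj$type == "constant") {
    rep(traj$value, n_timepoints)
  } else {
    traj$mean + traj$amplitude * sin(2 * pi * t / traj$period + traj$phase)
  }
}

#' Sliding-window average of a trajectory
#'
#' Averages a per-sample trajectory over each window `[t, t + w - 1]`,
#' giving the value a sliding-window estimator is expected to recover.
#'
#' @param x numeric vector (one value per sample).
#' @param window_length window length in samples.
#' @return Numeric vector of length `length(x) - window_length + 1`.
#' @export
window_average <- function(x, window_length) {
  w <- as.integer(window_length)
  if (w < 1L || w > length(x)) stop("'window_length' must be in [1, length(x)]")
  cs <- cumsum(c(0, x))
  (cs[(w + 1):(length(x) + 1)] - cs[1:(length(x) - w + 1)]) / w
}
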
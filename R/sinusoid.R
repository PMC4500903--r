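#' Specification of an idealized sinusoidal connectivity trajectory
#'
#' Describes a correlation-valued sinusoid
#' `v[t] = m + A * sin(2 * pi * t / P + phi)` used as an idealized edge
#' connectivity time-series. Because the values represent correlations,
#' the whole trajectory must stay inside `[-1, 1]`, which requires
#' `|m| + A <= 1`.
#'
#' @param mean dimensionless correlation offset m.
#' @param amplitude amplitude A (>= 0).
#' @param period period P in samples (> 0).
#' @param phase phase in radians.
#' @param n_samples number of samples T (>= 1).
#' @return An object of class `sinusoid_spec`.
#' @export
sinusoid_spec <- function(mean = 0, amplitude = 0.2, period = 80, phase = 0,
                          n_samples = 240) {
  if (!is.numeric(amplitude) || amplitude < 0)
    stop("'amplitude' must be >= 0")
  if (abs(mean) + amplitude > 1)
    stop("|mean| + amplitude must be <= 1 so that the trajectory stays in [-1, 1]")
  if (period <= 0) stop("'period' must be > 0")
  if (n_samples < 1) stop("'n_samples' must be >= 1")
  structure(list(mean = mean, amplitude = amplitude, period = period,
                 phase = phase, n_samples = as.integer(n_samples)),
            class = "sinusoid_spec")
}

#' Generate an idealized sinusoidal connectivity trajectory
#'
#' @param spec a [sinusoid_spec()].
#' @return Numeric vector of length `spec$n_samples`, all values in
#'   `[-1, 1]`.
#' @export
#' @examples
#' s2 <- generate_sinusoid(sinusoid_spec(mean = 0, amplitude = 0.2))
#' range(s2)  # spans -0.2 .. 0.2
generate_sinusoid <- function(spec) {
  stopifnot(inherits(spec, "sinusoid_spec"))
  t <- seq_len(spec$n_samples) - 1
  spec$mean + spec$amplitude * sin(2 * pi * t / spec$period + spec$phase)
}

#' The two idealized anti-phase connectivity trajectories
#'
#' A worked example of the two thresholding strategies uses two
#' sinusoidal edge trajectories: S1 with a high mean and small
#' fluctuations (mean 0.26, amplitude 0.05) and S2 centred on zero with
#' larger fluctuations (mean 0, amplitude 0.2), in anti-phase with each
#' other. Under magnitude cutoffs of 0.3, 0.2 and 0.15, S1 moves from
#' peaks-only presence to continuous presence while S2 is mostly
#' invisible; a variance-based threshold (mean + 1 SD) isolates the
#' peaks of both.
#'
#' @param n_samples trajectory length (default 240 samples).
#' @param period common period in samples (default 80, i.e. three full
#'   cycles over the default length).
#' @return A list with numeric trajectories `S1` and `S2` and the two
#'   `sinusoid_spec` objects used to build them.
#' @export
figure1_sinusoids <- function(n_samples = 240, period = 80) {
  s1_spec <- sinusoid_spec(mean = 0.26, amplitude = 0.05, period = period,
                           phase = 0, n_samples = n_samples)
  s2_spec <- sinusoid_spec(mean = 0, amplitude = 0.2, period = period,
                           phase = pi, n_samples = n_samples)
  list(S1 = generate_sinusoid(s1_spec), S2 = generate_sinusoid(s2_spec),
       S1_spec = s1_spec, S2_spec = s2_spec)
}
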
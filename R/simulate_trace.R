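#' Describe a single electrical stimulation event
#'
#' @param time_s Seconds from recording start (`>= 0`).
#' @param site Stimulation site, `"VTA"` (dopaminergic midbrain input) or
#'   `"V2L"` (lateral secondary visual cortex input).
#' @param frequency_hz Pulse frequency in Hz, in `(0, 50]`.
#' @param n_pulses Number of pulses in the train (`>= 1`).
#' @return A one-row `data.frame` with the event fields.
#' @examples
#' stimulus_event(30, "V2L", frequency_hz = 20, n_pulses = 5)
#' @export
stimulus_event <- function(time_s, site = c("VTA", "V2L"), frequency_hz = 50,
                           n_pulses = 10) {
  site <- match.arg(site)
  if (!is.numeric(time_s) || time_s < 0) stop("'time_s' must be >= 0")
  if (frequency_hz <= 0) stop("'frequency_hz' must be > 0")
  if (n_pulses < 1) stop("'n_pulses' must be >= 1")
  data.frame(time_s = time_s, site = site, frequency_hz = frequency_hz,
             n_pulses = n_pulses, stringsAsFactors = FALSE)
}

#' Simulate a raw fluorescence trace
#'
#' Generates a single-cell raw fluorescence time series as
#' `F(t) = F0 * (1 + drift(t) + sum_i a_i * k_i(t - t_i)) + noise`, where
#' `k_i` are unit-peak transient kernels, `a_i` the injected dF/F amplitudes,
#' drift is a slow sinusoid and noise is white Gaussian with standard
#' deviation `noise_sd * F0`. Because signal, drift and noise all scale with
#' the baseline, every downstream dF/F quantity is invariant to the choice
#' of `baseline_f0`.
#'
#' @param baseline_f0 Baseline fluorescence, arbitrary units (`> 0`).
#' @param events A `data.frame` of stimulation events (see
#'   [stimulus_event()]); may have zero rows.
#' @param kernels A single `"transient_kernel"` or a list with one kernel
#'   per event.
#' @param amplitudes Numeric vector of injected peak dF/F amplitudes, one
#'   per event.
#' @param duration_s Recording length, seconds.
#' @param fps Sampling rate, frames per second.
#' @param noise_sd White-noise standard deviation as a fraction of baseline.
#' @param drift_amplitude Peak drift as a fraction of baseline.
#' @param drift_period_s Period of the sinusoidal drift (default 300 s).
#' @param seed Optional integer seed; identical seeds give bit-identical
#'   traces.
#' @return Numeric vector of length `floor(duration_s * fps)`.
#' @examples
#' k <- make_transient_kernel("short", 0.5, 1.5, fps = 2.3)
#' ev <- stimulus_event(30, "V2L", 20, 5)
#' tr <- simulate_trace(1000, ev, k, amplitudes = 0.5, duration_s = 60,
#'                      fps = 2.3, noise_sd = 0, seed = 1)
#' max(tr / 1000 - 1)  # recovers the injected 0.5
#' @export
simulate_trace <- function(baseline_f0, events = NULL, kernels = NULL,
                           amplitudes = NULL, duration_s, fps = 2.3,
                           noise_sd = 0.02, drift_amplitude = 0,
                           drift_period_s = 300, seed = NULL) {
  if (!is.numeric(baseline_f0) || baseline_f0 <= 0)
    stop("'baseline_f0' must be positive")
  if (fps <= 0) stop("'fps' must be > 0")
  n <- floor(duration_s * fps + 1e-9)
  if (n < 1) stop("'duration_s' too short for one frame")
  t <- (seq_len(n) - 1L) / fps
  n_ev <- if (is.null(events)) 0L else nrow(events)
  if (n_ev > 0L) {
    if (inherits(kernels, "transient_kernel"))
      kernels <- rep(list(kernels), n_ev)
    if (length(kernels) != n_ev || length(amplitudes) != n_ev)
      stop("'kernels' and 'amplitudes' must align with 'events'")
    if (any(events$time_s < 0) || any(events$time_s >= duration_s))
      stop("events outside the recording")
  }
  if (!is.null(seed)) set.seed(seed)
  signal <- numeric(n)
  for (i in seq_len(n_ev)) {
    i0 <- round(events$time_s[i] * fps) + 1L
    kv <- kernels[[i]]$values
    idx <- i0:min(n, i0 + length(kv) - 1L)
    signal[idx] <- signal[idx] + amplitudes[i] * kv[seq_along(idx)]
  }
  drift <- if (drift_amplitude != 0)
    drift_amplitude * sin(2 * pi * t / drift_period_s) else 0
  noise <- if (noise_sd > 0) stats::rnorm(n, 0, noise_sd) else 0
  baseline_f0 * (1 + drift + signal + noise)
}

#' Assemble a trace matrix
#'
#' Bundles a cells-by-frames fluorescence matrix with its sampling rate,
#' stimulus annotations and cell identifiers; the main input container of
#' the analysis pipeline.
#'
#' @param traces Numeric matrix, one row per cell, one column per frame.
#' @param fps Frames per second.
#' @param events Optional `data.frame` of stimulation events.
#' @param cell_ids Optional character/integer cell identifiers (defaults to
#'   `1:nrow`).
#' @return An object of class `"trace_matrix"`.
#' @export
trace_matrix <- function(traces, fps, events = NULL, cell_ids = NULL) {
  traces <- as.matrix(traces)
  if (fps <= 0) stop("'fps' must be > 0")
  if (is.null(cell_ids)) cell_ids <- seq_len(nrow(traces))
  if (length(cell_ids) != nrow(traces))
    stop("'cell_ids' must have one entry per row")
  rownames(traces) <- as.character(cell_ids)
  structure(list(traces = traces, fps = fps, events = events,
                 cell_ids = cell_ids,
                 time_s = (seq_len(ncol(traces)) - 1L) / fps),
            class = "trace_matrix")
}

#' @export
print.trace_matrix <- function(x, ...) {
  cat(sprintf("<trace_matrix: %d cells x %d frames at %.2f fps, %d events>\n",
              nrow(x$traces), ncol(x$traces), x$fps,
              if (is.null(x$events)) 0L else nrow(x$events)))
  invisible(x)
}
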
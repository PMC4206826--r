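#' Fit the decay constant of a calcium transient
#'
#' Fits `dF/F(t) = dFFmax * exp(-t / tau)`, where `dFFmax` is pinned to the
#' observed dF/F at the peak sample and `t` is the time elapsed after the
#' peak. The default `"nls"` method minimises the residual sum of squares
#' over `tau` by one-dimensional optimisation (the model has a single free
#' parameter once the peak is pinned); `"loglinear"` regresses
#' `log(dF/F)` on `t` through the fixed intercept `log(dFFmax)`, using only
#' strictly positive samples, and is also the closed-form oracle used in
#' the package's tests.
#'
#' @param dff Numeric dF/F trace.
#' @param fps Frames per second.
#' @param peak_index 1-based index of the transient peak.
#' @param fit_end_index 1-based index of the last sample of the fit window.
#'   See [decay_fit_window()] for the default window rule.
#' @param method `"nls"` (default, needs >= 3 samples) or `"loglinear"`
#'   (needs >= 2 positive samples).
#' @return An object of class `"decay_fit"`: `dff_max`, `tau_s`,
#'   `fit_window` (start/end seconds), `rss`, `method`, `n`.
#' @examples
#' t <- seq(0, 25, by = 1 / 2.3)
#' fit <- fit_decay(0.5 * exp(-t / 10), fps = 2.3, peak_index = 1,
#'                  fit_end_index = length(t))
#' fit$tau_s  # ~10
#' @export
fit_decay <- function(dff, fps, peak_index, fit_end_index,
                      method = c("nls", "loglinear")) {
  method <- match.arg(method)
  if (fps <= 0) stop("'fps' must be > 0")
  if (peak_index < 1 || fit_end_index > length(dff) ||
      fit_end_index < peak_index)
    stop("invalid fit window")
  y <- dff[peak_index:fit_end_index]
  m <- length(y)
  min_n <- if (method == "nls") 3L else 2L
  if (m < min_n)
    stop("fit window must hold at least ", min_n, " samples")
  a <- y[1]
  if (a <= 0) stop("dF/F at the peak must be positive")
  if (all(y[-1] <= 0)) stop("decay segment is all non-positive; cannot fit")
  trel <- (seq_len(m) - 1L) / fps
  if (method == "loglinear") {
    pos <- y > 0
    if (sum(pos) < 2L) stop("need >= 2 positive samples for log-linear fit")
    tp <- trel[pos]; lp <- log(y[pos]) - log(a)
    if (sum(tp^2) == 0) stop("degenerate fit window")
    slope <- sum(tp * lp) / sum(tp^2)
    if (slope >= 0) stop("no decay detected (non-negative log-linear slope)")
    tau <- -1 / slope
    rss <- sum((y - a * exp(-trel / tau))^2)
  } else {
    rssf <- function(tau) sum((y - a * exp(-trel / tau))^2)
    opt <- stats::optimize(rssf, interval = c(0.5 / fps, 1e3), tol = 1e-9)
    tau <- opt$minimum
    rss <- opt$objective
  }
  structure(list(dff_max = a, tau_s = tau,
                 fit_window = c(start_s = (peak_index - 1) / fps,
                                end_s = (fit_end_index - 1) / fps),
                 rss = rss, method = method, n = m),
            class = "decay_fit")
}

#' @export
print.decay_fit <- function(x, ...) {
  cat(sprintf("<decay_fit: tau %.3f s, peak dF/F %.3f, %d samples, rss %.3g (%s)>\n",
              x$tau_s, x$dff_max, x$n, x$rss, x$method))
  invisible(x)
}

#' Default decay fit window
#'
#' From the peak sample to the first sample where dF/F drops below 5% of
#' the peak value, capped at 40 s after the peak.
#'
#' @param dff Numeric dF/F trace.
#' @param fps Frames per second.
#' @param peak_index 1-based peak index.
#' @param floor_frac Fraction of the peak at which the window ends.
#' @param max_s Cap on the window length, seconds after the peak.
#' @return 1-based index of the last sample of the fit window.
#' @export
decay_fit_window <- function(dff, fps, peak_index, floor_frac = 0.05,
                             max_s = 40) {
  n <- length(dff)
  last <- min(n, peak_index + floor(max_s * fps + 1e-9))
  seg <- dff[peak_index:last]
  below <- which(seg < floor_frac * dff[peak_index])
  if (length(below)) peak_index + below[1] - 1L else last
}

#' Summed dF/F over a time window
#'
#' Sum of the dF/F samples whose timestamps fall in the half-open window
#' `[start, end)` seconds (frame `k` has timestamp `k / fps`, 0-based).
#' Summing samples (rather than integrating) is the convention throughout;
#' set `integral = TRUE` for a trapezoidal time integral instead.
#'
#' @param dff Numeric dF/F trace.
#' @param fps Frames per second.
#' @param window_s Length-2 numeric `(start, end)` in seconds.
#' @param integral If `TRUE`, return the trapezoidal integral (dF/F x s).
#' @return A list with `summed_dff` and `n_samples`.
#' @export
summed_response <- function(dff, fps, window_s, integral = FALSE) {
  if (length(window_s) != 2 || window_s[2] <= window_s[1])
    stop("'window_s' must be (start, end) with end > start")
  t <- (seq_along(dff) - 1L) / fps
  idx <- which(t >= window_s[1] & t < window_s[2])
  if (!length(idx)) stop("window contains no samples")
  val <- if (integral && length(idx) > 1) {
    sum(diff(t[idx]) * (dff[idx[-length(idx)]] + dff[idx[-1]]) / 2)
  } else sum(dff[idx])
  list(summed_dff = val, n_samples = length(idx))
}

#' Ratio of a response measure to a reference condition
#'
#' @param value_post Measure under the condition of interest.
#' @param value_reference Measure under the reference condition (non-zero).
#' @return `value_post / value_reference`.
#' @export
changing_ratio <- function(value_post, value_reference) {
  if (any(value_reference == 0)) stop("reference value must be non-zero")
  value_post / value_reference
}

#' Peak dF/F within a search window
#'
#' @param dff Numeric dF/F trace.
#' @param fps Frames per second.
#' @param search_window_s Length-2 `(start, end)` seconds, half-open.
#' @return A list with `peak_dff` and `peak_time_s`; ties broken by the
#'   earliest time.
#' @export
peak_response <- function(dff, fps, search_window_s) {
  t <- (seq_along(dff) - 1L) / fps
  idx <- which(t >= search_window_s[1] & t < search_window_s[2])
  if (!length(idx)) stop("empty search window")
  i <- idx[which.max(dff[idx])]     # which.max returns the first maximum
  list(peak_dff = dff[i], peak_time_s = t[i])
}

#' Detect whether a transient occurred after a stimulus
#'
#' A response is deemed to have occurred when the maximum dF/F within the
#' post-stimulus response window exceeds `k_sd` standard deviations of the
#' dF/F over the 5 s immediately preceding the stimulus.
#'
#' @param dff Numeric dF/F trace.
#' @param fps Frames per second.
#' @param stim_time_s Stimulus onset, seconds.
#' @param response_window_s Length of the post-stimulus window, seconds.
#' @param k_sd Threshold in baseline standard deviations.
#' @return Logical.
#' @export
detect_occurrence <- function(dff, fps, stim_time_s, response_window_s = 5,
                              k_sd = 3) {
  if (stim_time_s < 5) stop("need >= 5 s of pre-stimulus baseline")
  t <- (seq_along(dff) - 1L) / fps
  base <- dff[t >= stim_time_s - 5 & t < stim_time_s]
  if (length(base) < 2) stop("insufficient pre-stimulus baseline samples")
  resp <- dff[t >= stim_time_s & t < stim_time_s + response_window_s]
  if (!length(resp)) stop("response window contains no samples")
  max(resp) > k_sd * stats::sd(base)
}

#' Per-cell population response vector for one stimulus repetition
#'
#' Element *i* summarises cell *i*'s dF/F response to the stimulus; the
#' default summary is the peak dF/F within 5 s of stimulus onset (matching
#' the fast kinetics of sensory-evoked transients), with the mean over the
#' window available as an alternative. Cell order follows the matrix row
#' order and must be held fixed across repetitions.
#'
#' @param dm A `"dff_matrix"` (see [compute_dff_matrix()]).
#' @param stim_time_s Stimulus onset, seconds.
#' @param summary `"peak"` or `"mean"`.
#' @param window_s Length of the post-stimulus summary window, seconds.
#' @return Named numeric vector of length `n_cells`.
#' @export
response_vector <- function(dm, stim_time_s, summary = c("peak", "mean"),
                            window_s = 5) {
  stopifnot(inherits(dm, "dff_matrix"))
  summary <- match.arg(summary)
  t <- dm$time_s
  idx <- which(t >= stim_time_s & t < stim_time_s + window_s)
  if (!length(idx)) stop("summary window outside the recording")
  fun <- if (summary == "peak") function(x) max(x) else function(x) mean(x)
  v <- apply(dm$dff[, idx, drop = FALSE], 1, fun)
  stats::setNames(as.numeric(v), as.character(dm$cell_ids))
}
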
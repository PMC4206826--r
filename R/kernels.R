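#' Build a unit-peak calcium transient kernel
#'
#' Constructs a sampled transient waveform used by the trace simulator.
#' Two stereotyped shapes are supported: `"short"` transients (fast rise,
#' decay complete within ~5 s, typical of direct sensory-cortex drive) and
#' `"long"` transients (slow rise peaking 6--7 s after the stimulus,
#' lasting 20--30 s, typical of phasic dopaminergic drive).
#'
#' The rise is a saturating exponential calibrated so the kernel reaches its
#' maximum of exactly 1 at the sample nearest `peak_time_s`; after the peak
#' the kernel follows `exp(-(t - t_peak)/tau_s)` exactly, so that downstream
#' decay-constant fitting has a known ground truth.
#'
#' @param kind `"short"` or `"long"`.
#' @param peak_time_s Time of the peak, seconds from event onset. Must be
#'   `<= 1.5` for short kernels and within `[6, 7]` for long kernels.
#' @param tau_s Decay time constant, seconds (`> 0`).
#' @param fps Sampling rate, frames per second (`> 0`).
#' @param duration_s Support length in seconds. Defaults to 5 (short) or
#'   25 (long); must be `<= 5` for short and within `[20, 30]` for long.
#' @param rise_tau_s Time constant of the saturating-exponential rise;
#'   defaults to `peak_time_s / 3` (or an instantaneous rise if
#'   `peak_time_s` falls on the first sample).
#'
#' @return An object of class `"transient_kernel"`: a list with `values`
#'   (unit-peak non-negative samples), `peak_index` (1-based), `peak_time_s`
#'   (snapped to the sample grid), `tau_s`, `fps`, `duration_s`, `kind`.
#' @examples
#' k <- make_transient_kernel("long", peak_time_s = 6.5, tau_s = 8, fps = 2.3)
#' which.max(k$values) == k$peak_index
#' @export
make_transient_kernel <- function(kind = c("short", "long"), peak_time_s,
                                  tau_s, fps, duration_s = NULL,
                                  rise_tau_s = NULL) {
  kind <- match.arg(kind)
  if (!is.numeric(tau_s) || length(tau_s) != 1L || tau_s <= 0)
    stop("'tau_s' must be a single positive number")
  if (!is.numeric(fps) || length(fps) != 1L || fps <= 0)
    stop("'fps' must be a single positive number")
  if (!is.numeric(peak_time_s) || length(peak_time_s) != 1L || peak_time_s < 0)
    stop("'peak_time_s' must be a single non-negative number")
  if (is.null(duration_s))
    duration_s <- if (kind == "short") 5 else 25
  if (kind == "short") {
    if (peak_time_s > 1.5) stop("short kernels require peak_time_s <= 1.5 s")
    if (duration_s > 5) stop("short kernels require duration_s <= 5 s")
  } else {
    if (peak_time_s < 6 || peak_time_s > 7)
      stop("long kernels require peak_time_s in [6, 7] s")
    if (duration_s < 20 || duration_s > 30)
      stop("long kernels require duration_s in [20, 30] s")
  }
  n <- floor(duration_s * fps + 1e-9) + 1L
  t <- (seq_len(n) - 1L) / fps
  ip <- round(peak_time_s * fps) + 1L
  ip <- min(max(ip, 1L), n)
  tp <- t[ip]
  if (is.null(rise_tau_s)) rise_tau_s <- if (tp > 0) tp / 3 else Inf
  v <- numeric(n)
  if (ip > 1L) {
    # saturating rise normalised to 1 at the peak sample
    v[seq_len(ip - 1L)] <- (1 - exp(-t[seq_len(ip - 1L)] / rise_tau_s)) /
      (1 - exp(-tp / rise_tau_s))
  }
  v[ip:n] <- exp(-(t[ip:n] - tp) / tau_s)
  structure(list(values = v, peak_index = ip, peak_time_s = tp,
                 tau_s = tau_s, fps = fps, duration_s = duration_s,
                 kind = kind, rise_tau_s = rise_tau_s),
            class = "transient_kernel")
}

#' Evaluate a transient kernel at arbitrary times
#'
#' Continuous-time evaluation of the kernel definition used by
#' [make_transient_kernel()] (same rise/decay parameters, peak pinned at the
#' kernel's snapped peak time).
#'
#' @param kernel A `"transient_kernel"` object.
#' @param t_s Times in seconds from event onset (vectorised).
#' @return Kernel values at `t_s`; zero outside `[0, duration_s]`.
#' @export
eval_transient_kernel <- function(kernel, t_s) {
  stopifnot(inherits(kernel, "transient_kernel"))
  tp <- kernel$peak_time_s
  out <- numeric(length(t_s))
  inside <- t_s >= 0 & t_s <= kernel$duration_s
  rising <- inside & t_s < tp
  if (any(rising))
    out[rising] <- (1 - exp(-t_s[rising] / kernel$rise_tau_s)) /
      (1 - exp(-tp / kernel$rise_tau_s))
  decaying <- inside & t_s >= tp
  out[decaying] <- exp(-(t_s[decaying] - tp) / kernel$tau_s)
  out
}

#' @export
print.transient_kernel <- function(x, ...) {
  cat(sprintf("<transient_kernel: %s, peak %.2f s, tau %.2f s, %.0f samples at %.2f fps>\n",
              x$kind, x$peak_time_s, x$tau_s, length(x$values), x$fps))
  invisible(x)
}
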
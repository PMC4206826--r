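#' Configuration for the synthetic two-channel movie generator
#'
#' @param width,height Image size in pixels (`>= 64`).
#' @param n_frames Number of frames.
#' @param fps Frames per second.
#' @param n_neurons,n_astrocytes Number of neuron / astrocyte somata.
#' @param radius_px Soma radius in pixels.
#' @param background Green-channel background intensity.
#' @param baseline_f0 Neuron baseline fluorescence above background.
#' @param snr Contrast-to-noise ratio: pixel noise SD is
#'   `baseline_f0 / snr` (use `Inf` for noise-free movies).
#' @param astro_green Astrocyte green-channel intensity above background
#'   (dim, but visible in the mean image so detection picks them up and the
#'   red channel is needed to exclude them).
#' @param astro_red Astrocyte red-channel intensity above the red
#'   background (the counterstain signal).
#' @param red_background Red-channel background intensity.
#' @param events,amplitude_range Stimulation events given to every neuron
#'   and the range response amplitudes are drawn from.
#' @param drift_px Integer `(dx, dy)` rigid drift applied to both channels.
#' @param drift_from_frame First frame (1-based) affected by the drift.
#' @param seed Integer seed.
#' @return A list of class `"movie_config"`.
#' @export
movie_config <- function(width = 96, height = 96, n_frames = 60, fps = 2.3,
                         n_neurons = 10, n_astrocytes = 3, radius_px = 4,
                         background = 100, baseline_f0 = 500, snr = 5,
                         astro_green = 400, astro_red = 500,
                         red_background = 50,
                         events = stimulus_event(10, "V2L", 20, 5),
                         amplitude_range = c(0.2, 0.5),
                         drift_px = c(0, 0), drift_from_frame = NA,
                         seed = 1L) {
  if (width < 64 || height < 64) stop("movie must be at least 64 x 64")
  structure(as.list(environment()), class = "movie_config")
}

place_disks <- function(n, width, height, r, min_gap = 2, max_tries = 2000) {
  centers <- matrix(numeric(0), 0, 2)
  tries <- 0
  while (nrow(centers) < n) {
    tries <- tries + 1
    if (tries > max_tries)
      stop("could not place ", n, " non-overlapping cells in a ",
           width, " x ", height, " field")
    cx <- stats::runif(1, r + 1, width - r - 2)
    cy <- stats::runif(1, r + 1, height - r - 2)
    if (nrow(centers) == 0 ||
        all(sqrt((centers[, 1] - cx)^2 + (centers[, 2] - cy)^2) >=
            2 * r + min_gap))
      centers <- rbind(centers, c(cx, cy))
  }
  centers
}

disk_pixels <- function(cx, cy, r, width, height) {
  # 0-based pixel coordinates; membership = centre distance <= r
  xr <- max(0, floor(cx - r)):min(width - 1, ceiling(cx + r))
  yr <- max(0, floor(cy - r)):min(height - 1, ceiling(cy + r))
  g <- expand.grid(x = xr, y = yr)
  g[(g$x - cx)^2 + (g$y - cy)^2 <= r^2, , drop = FALSE]
}

#' Simulate a two-channel calcium imaging movie with ground truth
#'
#' Renders a neuron (green) channel and an astrocyte-counterstain (red)
#' channel. Each neuron soma is a disk whose pixels follow a raw
#' fluorescence trace from [simulate_trace()]; astrocyte disks are static
#' in green and bright in red. Optionally a global integer rigid drift is
#' applied to both channels from a given frame, for exercising
#' registration. Pixel arrays are `height x width x frames`.
#'
#' @param config A [movie_config()].
#' @param seed Integer seed overriding `config$seed`.
#' @return A list of class `"ca_movie"`: `green`, `red` (arrays), `fps`,
#'   `rois` (ground-truth `data.frame`: id, cx, cy, r, label),
#'   `traces` (injected neuron traces, neurons x frames),
#'   `amplitudes`, `events`, `drift`.
#' @export
simulate_movie <- function(config = movie_config(), seed = NULL) {
  stopifnot(inherits(config, "movie_config"))
  if (is.null(seed)) seed <- config$seed
  set.seed(seed)
  W <- config$width; H <- config$height; Tn <- config$n_frames
  r <- config$radius_px
  n_cells <- config$n_neurons + config$n_astrocytes
  rois <- data.frame(id = integer(0), cx = numeric(0), cy = numeric(0),
                     r = numeric(0), label = character(0),
                     stringsAsFactors = FALSE)
  if (n_cells > 0) {
    centers <- place_disks(n_cells, W, H, r)
    rois <- data.frame(id = seq_len(n_cells), cx = centers[, 1],
                       cy = centers[, 2], r = r,
                       label = rep(c("neuron", "astrocyte"),
                                   c(config$n_neurons, config$n_astrocytes)),
                       stringsAsFactors = FALSE)
  }
  duration_s <- Tn / config$fps
  amps <- if (config$n_neurons > 0)
    stats::runif(config$n_neurons, config$amplitude_range[1],
                 config$amplitude_range[2]) else numeric(0)
  kern <- make_transient_kernel("short", 0.5, 1.5, config$fps)
  traces <- matrix(0, config$n_neurons, Tn)
  for (i in seq_len(config$n_neurons))
    traces[i, ] <- simulate_trace(config$baseline_f0, config$events, kern,
                                  amplitudes = rep(amps[i],
                                                   nrow(config$events)),
                                  duration_s = duration_s, fps = config$fps,
                                  noise_sd = 0)
  green <- array(config$background, dim = c(H, W, Tn))
  red <- array(config$red_background, dim = c(H, W, Tn))
  for (i in seq_len(nrow(rois))) {
    px <- disk_pixels(rois$cx[i], rois$cy[i], r, W, H)
    ri <- px$y + 1L; ci <- px$x + 1L
    for (f in seq_len(Tn)) {
      if (rois$label[i] == "neuron") {
        # disk pixels carry the raw trace value, so a mean-over-ROI readout
        # reproduces the injected trace exactly in the noise-free case
        green[cbind(ri, ci, f)] <- traces[rois$id[i], f]
      } else {
        green[cbind(ri, ci, f)] <- config$background + config$astro_green
        red[cbind(ri, ci, f)] <- config$red_background + config$astro_red
      }
    }
  }
  if (is.finite(config$snr) && config$snr > 0) {
    nsd <- config$baseline_f0 / config$snr
    green <- green + array(stats::rnorm(length(green), 0, nsd), dim(green))
    red <- red + array(stats::rnorm(length(red), 0, nsd / 2), dim(red))
    green[green < 0] <- 0
    red[red < 0] <- 0
  }
  drift <- matrix(0L, Tn, 2, dimnames = list(NULL, c("dx", "dy")))
  if (!is.na(config$drift_from_frame) && any(config$drift_px != 0)) {
    idx <- config$drift_from_frame:Tn
    drift[idx, 1] <- as.integer(config$drift_px[1])
    drift[idx, 2] <- as.integer(config$drift_px[2])
    for (f in idx) {
      green[, , f] <- shift_frame(green[, , f], drift[f, 1], drift[f, 2],
                                  fill = config$background)
      red[, , f] <- shift_frame(red[, , f], drift[f, 1], drift[f, 2],
                                fill = config$red_background)
    }
  }
  structure(list(green = green, red = red, fps = config$fps, rois = rois,
                 traces = traces, amplitudes = amps, events = config$events,
                 drift = drift, config = config),
            class = "ca_movie")
}

# integer translation: positive dx moves content right, dy moves it down
shift_frame <- function(frame, dx, dy, fill = stats::median(frame)) {
  H <- nrow(frame); W <- ncol(frame)
  out <- matrix(fill, H, W)
  src_r <- seq_len(H) - dy
  src_c <- seq_len(W) - dx
  ok_r <- src_r >= 1 & src_r <= H
  ok_c <- src_c >= 1 & src_c <= W
  out[ok_r, ok_c] <- frame[src_r[ok_r], src_c[ok_c]]
  out
}

#' @export
print.ca_movie <- function(x, ...) {
  cat(sprintf("<ca_movie: %d x %d x %d frames, %d neurons + %d astrocytes>\n",
              dim(x$green)[1], dim(x$green)[2], dim(x$green)[3],
              sum(x$rois$label == "neuron"), sum(x$rois$label == "astrocyte")))
  invisible(x)
}
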
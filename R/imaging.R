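#' Rigid (translation-only) frame registration
#'
#' Aligns every frame of a movie to a reference frame by the integer
#' translation that maximises the circular cross-correlation (computed via
#' FFT) between the frame and the reference. The same shift is applied to
#' every channel; border pixels exposed by the shift are filled with the
#' frame median. Sub-pixel motion, rotation and scaling are out of scope.
#'
#' @param movie A `"ca_movie"` (see [simulate_movie()]) or a list with at
#'   least a `green` `height x width x frames` array.
#' @param reference_frame_index 1-based index of the reference frame.
#' @return A list with `movie` (registered copy) and `shifts`
#'   (frames x 2 integer matrix of applied corrections `(dx, dy)`; a frame
#'   whose content had drifted by `+5` px in x is reported as `(-5, 0)`).
#' @export
register_frames <- function(movie, reference_frame_index = 1) {
  green <- movie$green
  if (is.null(green) || length(dim(green)) != 3 || dim(green)[3] < 1)
    stop("empty movie")
  Tn <- dim(green)[3]
  if (reference_frame_index < 1 || reference_frame_index > Tn)
    stop("invalid reference frame index")
  ref <- green[, , reference_frame_index]
  fr <- stats::fft(ref - mean(ref))
  shifts <- matrix(0L, Tn, 2, dimnames = list(NULL, c("dx", "dy")))
  channels <- intersect(c("green", "red"), names(movie))
  out <- movie
  for (f in seq_len(Tn)) {
    if (f == reference_frame_index) next
    frame <- green[, , f]
    cc <- Re(stats::fft(Conj(fr) * stats::fft(frame - mean(frame)),
                        inverse = TRUE))
    peak <- which(cc == max(cc), arr.ind = TRUE)[1, ]
    d <- as.integer(peak) - 1L                       # (row, col) displacement
    dims <- dim(ref)
    d <- ifelse(d > dims / 2, d - dims, d)
    dy <- d[1]; dx <- d[2]
    shifts[f, ] <- c(-dx, -dy)
    if (dx != 0 || dy != 0)
      for (ch in channels)
        out[[ch]][, , f] <- shift_frame(movie[[ch]][, , f], -dx, -dy)
  }
  list(movie = out, shifts = shifts)
}

#' Semi-automatic cell detection on a mean image
#'
#' Automatic path: Gaussian smoothing, local maxima above an intensity
#' percentile, greedy non-maximum suppression so the resulting fixed-radius
#' disk ROIs do not overlap. Semi-automatic path: when user seed points are
#' supplied, one disk ROI is returned per seed and no detection is run.
#' Coordinates are 0-based `(x = column, y = row)`.
#'
#' @param mean_image Numeric matrix (time-average of the green channel).
#' @param min_radius,max_radius Radius bounds in pixels; the ROI radius is
#'   their midpoint.
#' @param intensity_percentile Percentile (0--100) of the smoothed image
#'   below which maxima are discarded.
#' @param seeds Optional list/matrix of user-supplied `(x, y)` seed points.
#' @return A `data.frame` ROI set: `id`, `cx`, `cy`, `r`, `label`
#'   (`"unknown"`).
#' @export
detect_cells <- function(mean_image, min_radius = 3, max_radius = 5,
                         intensity_percentile = 95, seeds = NULL) {
  if (!all(is.finite(mean_image))) stop("mean image must be finite")
  if (max_radius < min_radius) stop("'max_radius' must be >= 'min_radius'")
  r <- (min_radius + max_radius) / 2
  if (!is.null(seeds)) {
    seeds <- matrix(unlist(seeds), ncol = 2, byrow = !is.matrix(seeds))
    return(data.frame(id = seq_len(nrow(seeds)), cx = seeds[, 1],
                      cy = seeds[, 2], r = r, label = "unknown",
                      stringsAsFactors = FALSE))
  }
  sm <- as.matrix(EBImage::gblur(mean_image, sigma = max(min_radius / 2, 1)))
  H <- nrow(sm); W <- ncol(sm)
  thr <- stats::quantile(sm, intensity_percentile / 100)
  is_max <- matrix(TRUE, H, W)
  is_max[c(1, H), ] <- FALSE
  is_max[, c(1, W)] <- FALSE
  core <- 2:(H - 1)
  corc <- 2:(W - 1)
  for (dr in -1:1) for (dc in -1:1) {
    if (dr == 0 && dc == 0) next
    is_max[core, corc] <- is_max[core, corc] &
      (sm[core, corc] > sm[core + dr, corc + dc])
  }
  cand <- which(is_max & sm > thr, arr.ind = TRUE)
  if (nrow(cand) == 0)
    return(data.frame(id = integer(0), cx = numeric(0), cy = numeric(0),
                      r = numeric(0), label = character(0),
                      stringsAsFactors = FALSE))
  ord <- order(sm[cand], decreasing = TRUE)
  cand <- cand[ord, , drop = FALSE]
  keep <- matrix(numeric(0), 0, 2)   # (x, y), 0-based
  for (i in seq_len(nrow(cand))) {
    x <- cand[i, 2] - 1; y <- cand[i, 1] - 1
    if (nrow(keep) == 0 ||
        all((keep[, 1] - x)^2 + (keep[, 2] - y)^2 >= (2 * r)^2))
      keep <- rbind(keep, c(x, y))
  }
  data.frame(id = seq_len(nrow(keep)), cx = keep[, 1], cy = keep[, 2],
             r = r, label = "unknown", stringsAsFactors = FALSE)
}

#' Label astrocytes by counterstain intensity
#'
#' An ROI is labelled `"astrocyte"` when its mean red-channel
#' (sulforhodamine-style counterstain) intensity exceeds the given
#' percentile of the ROI-wise red intensities; all other ROIs are labelled
#' `"neuron"`. With an all-zero red channel every ROI is a neuron.
#'
#' @param rois ROI `data.frame` (`id`, `cx`, `cy`, `r`, ...).
#' @param red_mean_image Red-channel mean image, same pixel space as the
#'   ROIs.
#' @param red_threshold_percentile Percentile (0--100) of ROI-wise red
#'   intensity above which an ROI is called an astrocyte.
#' @return The ROI `data.frame` with `label` filled in and a `red_mean`
#'   column appended.
#' @export
classify_astrocytes <- function(rois, red_mean_image,
                                red_threshold_percentile = 75) {
  if (nrow(rois) == 0) {
    rois$red_mean <- numeric(0)
    return(rois)
  }
  H <- nrow(red_mean_image); W <- ncol(red_mean_image)
  red <- vapply(seq_len(nrow(rois)), function(i) {
    px <- disk_pixels(rois$cx[i], rois$cy[i], rois$r[i], W, H)
    if (nrow(px) == 0) stop("ROI ", rois$id[i], " has no pixels")
    mean(red_mean_image[cbind(px$y + 1L, px$x + 1L)])
  }, 0)
  thr <- stats::quantile(red, red_threshold_percentile / 100)
  rois$label <- ifelse(red > thr, "astrocyte", "neuron")
  rois$red_mean <- red
  rois
}

#' Extract per-ROI fluorescence traces from a movie
#'
#' Each retained ROI yields one row: the mean green-channel intensity over
#' the ROI's disk pixels, per frame. Row order follows ROI id order.
#'
#' @param movie A `"ca_movie"` or list with a `green` array and `fps`.
#' @param rois ROI `data.frame`.
#' @param exclude_astrocytes Drop ROIs labelled `"astrocyte"`.
#' @return A [trace_matrix()] whose `cell_ids` are the retained ROI ids.
#' @export
extract_traces <- function(movie, rois, exclude_astrocytes = TRUE) {
  green <- movie$green
  H <- dim(green)[1]; W <- dim(green)[2]; Tn <- dim(green)[3]
  if (exclude_astrocytes && "label" %in% names(rois))
    rois <- rois[rois$label != "astrocyte", , drop = FALSE]
  rois <- rois[order(rois$id), , drop = FALSE]
  traces <- matrix(0, nrow(rois), Tn)
  for (i in seq_len(nrow(rois))) {
    if (rois$cx[i] < 0 || rois$cx[i] > W - 1 ||
        rois$cy[i] < 0 || rois$cy[i] > H - 1)
      stop("ROI ", rois$id[i], " outside image bounds")
    px <- disk_pixels(rois$cx[i], rois$cy[i], rois$r[i], W, H)
    if (nrow(px) == 0) stop("ROI ", rois$id[i], " has no pixels")
    flat <- (px$x) * H + px$y + 1L          # column-major index within a frame
    for (f in seq_len(Tn))
      traces[i, f] <- mean(green[flat + (f - 1L) * H * W])
  }
  trace_matrix(traces, fps = movie$fps, cell_ids = rois$id)
}
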
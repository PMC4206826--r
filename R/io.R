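#' Write / read a trace matrix as CSV
#'
#' Traces are written rows = cells, columns = frames, with a header row of
#' frame timestamps (seconds) and the cell id in the first column. Stimulus
#' events, when present, go to a sidecar file `<path base>_events.csv`
#' (they are part of the experiment design, carried with the data rather
#' than inferred from it).
#'
#' @param tm A [trace_matrix()].
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_traces_csv <- function(tm, path) {
  stopifnot(inherits(tm, "trace_matrix"))
  df <- data.frame(cell_id = tm$cell_ids, tm$traces, check.names = FALSE)
  colnames(df) <- c("cell_id", sprintf("%.6f", tm$time_s))
  utils::write.csv(df, path, row.names = FALSE)
  if (!is.null(tm$events) && nrow(tm$events))
    utils::write.csv(tm$events, events_path(path), row.names = FALSE)
  invisible(path)
}

events_path <- function(path) sub("\\.csv$", "_events.csv", path)

#' @rdname write_traces_csv
#' @param fps Sampling rate; if `NULL`, inferred from the timestamp header.
#' @export
read_traces_csv <- function(path, fps = NULL) {
  df <- utils::read.csv(path, check.names = FALSE)
  ts <- as.numeric(colnames(df)[-1])
  if (is.null(fps)) {
    if (length(ts) > 1 && !anyNA(ts)) fps <- 1 / mean(diff(ts))
    else stop("cannot infer fps from header; pass 'fps'")
  }
  events <- NULL
  ep <- events_path(path)
  if (file.exists(ep)) events <- utils::read.csv(ep, stringsAsFactors = FALSE)
  trace_matrix(as.matrix(df[, -1, drop = FALSE]), fps = fps,
               events = events, cell_ids = df$cell_id)
}

#' Write / read an ROI set (with optional ground truth) as JSON
#'
#' Schema: `{"cells": [{"id", "cx", "cy", "r", "label"}], "events": [...],
#' "effects": ...}`. Coordinates are 0-based `(x = column, y = row)`.
#'
#' @param rois ROI `data.frame` (`id`, `cx`, `cy`, `r`, `label`).
#' @param path Output JSON path.
#' @param events Optional events `data.frame`.
#' @param effects Optional list of applied effect parameters.
#' @return `path`, invisibly.
#' @export
write_rois_json <- function(rois, path, events = NULL, effects = NULL) {
  obj <- list(cells = rois)
  if (!is.null(events)) obj$events <- events
  if (!is.null(effects)) obj$effects <- effects
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_rois_json
#' @export
read_rois_json <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  rois <- as.data.frame(obj$cells, stringsAsFactors = FALSE)
  if (nrow(rois) && anyDuplicated(rois$id)) stop("ROI ids must be unique")
  attr(rois, "events") <- obj$events
  attr(rois, "effects") <- obj$effects
  rois
}

#' Write / read a movie as multi-page TIFF (one file per channel)
#'
#' 16-bit unsigned TIFF, frame index = time. Intensities are scaled by
#' `scale` into the 16-bit range on write and scaled back on read, so raw
#' values survive a round trip up to 16-bit quantisation.
#'
#' @param movie A `"ca_movie"`.
#' @param base_path Path prefix; `_green.tif` / `_red.tif` are appended.
#' @param scale Intensity corresponding to the top of the 16-bit range.
#' @return Named character vector of the written files, invisibly.
#' @export
write_movie_tiff <- function(movie, base_path, scale = 4096) {
  out <- c()
  for (ch in intersect(c("green", "red"), names(movie))) {
    arr <- movie[[ch]] / scale
    arr[arr > 1] <- 1
    arr[arr < 0] <- 0
    frames <- lapply(seq_len(dim(arr)[3]), function(f) arr[, , f])
    p <- paste0(base_path, "_", ch, ".tif")
    tiff::writeTIFF(frames, p, bits.per.sample = 16L)
    out[ch] <- p
  }
  invisible(out)
}

#' @rdname write_movie_tiff
#' @param fps Frame rate to attach to the movie object.
#' @export
read_movie_tiff <- function(base_path, fps, scale = 4096) {
  movie <- list(fps = fps)
  for (ch in c("green", "red")) {
    p <- paste0(base_path, "_", ch, ".tif")
    if (!file.exists(p)) next
    frames <- tiff::readTIFF(p, all = TRUE)
    movie[[ch]] <- array(unlist(frames),
                         dim = c(dim(frames[[1]]), length(frames))) * scale
  }
  if (is.null(movie$green)) stop("no green channel found at ", base_path)
  class(movie) <- "ca_movie"
  movie
}

#' Read / write a pipeline configuration as YAML
#'
#' The YAML mirrors the [sim_config()], [experiment_design()] and analysis
#' parameter names; see [run_pipeline()] for the analysis defaults.
#'
#' @param path YAML file path.
#' @return A nested list.
#' @export
read_config_yaml <- function(path) {
  if (!file.exists(path)) stop("config file not found: ", path)
  yaml::read_yaml(path)
}

#' @rdname read_config_yaml
#' @param config Configuration list to serialise.
#' @export
write_config_yaml <- function(config, path) {
  yaml::write_yaml(config, path)
  invisible(path)
}
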
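## File interfaces: multi-page TIFF movies with a plain-text calibration
## sidecar, and CSV track/ground-truth tables.

#' Write a movie as multi-page TIFF plus calibration sidecar
#'
#' Pixel values are stored as 32-bit float TIFF samples scaled to [0, 1];
#' the scale factor and the calibration (pixel size, frame interval) go into
#' a `key = value` sidecar at `<path>.meta`, so [read_movie()] restores the
#' movie exactly.
#'
#' @param movie an `nd_movie`.
#' @param path output TIFF path.
#' @return `path`, invisibly.
#' @export
write_movie <- function(movie, path) {
  if (!inherits(movie, "nd_movie")) stop_invalid("`movie` must be an nd_movie")
  scale <- max(movie$stack, 1e-12)
  pages <- lapply(seq_len(dim(movie$stack)[3]),
                  function(f) movie$stack[, , f] / scale)
  tiff::writeTIFF(pages, path, bits.per.sample = 32L, compression = "none",
                  reduce = FALSE)
  write_run_config(list(pixel_size_um = movie$pixel_size,
                        frame_interval_s = movie$frame_interval,
                        intensity_scale = scale,
                        channel_label = movie$channel_label),
                   paste0(path, ".meta"))
  invisible(path)
}

#' Read a movie written by [write_movie()]
#'
#' @param path TIFF path; calibration is read from `<path>.meta` unless
#'   `pixel_size`/`frame_interval` are supplied.  Missing calibration is an
#'   error — units are never silently assumed.
#' @param pixel_size,frame_interval optional explicit calibration.
#' @return an `nd_movie`.
#' @export
read_movie <- function(path, pixel_size = NULL, frame_interval = NULL) {
  if (!file.exists(path)) stop_invalid(paste("cannot read TIFF:", path))
  pages <- tryCatch(tiff::readTIFF(path, all = TRUE),
                    error = function(e)
                      stop_invalid(paste("corrupted TIFF:", path)))
  if (!is.list(pages)) pages <- list(pages)
  meta_path <- paste0(path, ".meta")
  scale <- 1; label <- "ch1"
  if (file.exists(meta_path)) {
    meta <- read_run_config(meta_path)
    pixel_size <- pixel_size %||% meta$pixel_size_um
    frame_interval <- frame_interval %||% meta$frame_interval_s
    scale <- meta$intensity_scale %||% 1
    label <- meta$channel_label %||% "ch1"
  }
  if (is.null(pixel_size) || is.null(frame_interval))
    stop_invalid("calibration metadata missing: supply pixel_size and frame_interval")
  stack <- array(0, c(dim(pages[[1]]), length(pages)))
  for (f in seq_along(pages)) stack[, , f] <- pages[[f]] * scale
  nd_movie(stack, pixel_size, frame_interval, channel_label = label)
}

#' Write ground-truth tracks as CSV
#'
#' Columns: `track_id`, `population_id`, `frame`, `x_um`, `y_um`,
#' `censored`.
#'
#' @param ground_truth an `nd_ground_truth`.
#' @param path output CSV path.
#' @return `path`, invisibly.
#' @export
write_ground_truth <- function(ground_truth, path) {
  tr <- ground_truth$tracks
  utils::write.csv(data.frame(track_id = tr$track_id,
                              population_id = tr$population_id,
                              frame = tr$frame, x_um = tr$x_um,
                              y_um = tr$y_um,
                              censored = tr$censored_start | tr$censored_end),
                   path, row.names = FALSE)
  invisible(path)
}

#' Write an FCS trace as CSV (`time_s`, `counts`)
#' @param trace an `nd_fcs_trace`.
#' @param path output CSV path.
#' @return `path`, invisibly.
#' @export
write_fcs_trace <- function(trace, path) {
  utils::write.csv(data.frame(
    time_s = (seq_along(trace$samples) - 1L) * trace$sampling_dt,
    counts = trace$samples), path, row.names = FALSE)
  invisible(path)
}

#' Read an FCS trace CSV (`time_s`, `counts`)
#' @param path CSV path.
#' @return list usable by [autocorrelate()].
#' @export
read_fcs_trace <- function(path) {
  df <- utils::read.csv(path)
  if (!all(c("time_s", "counts") %in% names(df)))
    stop_invalid("FCS trace CSV needs columns time_s, counts")
  dt <- stats::median(diff(df$time_s))
  structure(list(samples = df$counts, sampling_dt = dt,
                 duration = nrow(df) * dt),
            class = "nd_fcs_trace")
}
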
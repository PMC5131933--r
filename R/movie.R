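#' Construct a voltage movie
#'
#' The universal exchange object: a stack of 2D transmembrane-potential
#' frames with spatial and temporal metadata. Frames are stored as an
#' H x W x T array (frame t is `frames[, , t]`); pixel (r, c) of every frame
#' sits at x = (c - 1) * dx_mm, y = (r - 1) * dx_mm, origin top-left.
#'
#' @param frames Numeric H x W x T array of potentials in mV (T >= 2).
#' @param dx_mm Pixel spacing in mm.
#' @param frame_interval_ms Time between frames in ms.
#' @param t0_ms Time of the first frame (default 0).
#' @param meta Named list of provenance metadata (scenario, solver, seed...).
#' @return An object of class `voltage_movie`.
#' @export
voltage_movie <- function(frames, dx_mm, frame_interval_ms, t0_ms = 0,
                          meta = list()) {
  if (!is.array(frames) || length(dim(frames)) != 3L)
    stop("frames must be an H x W x T array")
  if (dim(frames)[3] < 2L) stop("a movie needs at least 2 frames")
  if (!is.finite(dx_mm) || dx_mm <= 0) stop("dx_mm must be positive")
  if (!is.finite(frame_interval_ms) || frame_interval_ms <= 0)
    stop("frame_interval_ms must be positive")
  structure(
    list(frames = frames, dx_mm = dx_mm,
         frame_interval_ms = frame_interval_ms, t0_ms = t0_ms, meta = meta),
    class = "voltage_movie")
}

#' @export
print.voltage_movie <- function(x, ...) {
  d <- dim(x$frames)
  cat(sprintf("<voltage_movie> %d x %d px (%.3g x %.3g mm), %d frames @ %g ms, t0 = %g ms\n",
              d[1], d[2], d[1] * x$dx_mm, d[2] * x$dx_mm, d[3],
              x$frame_interval_ms, x$t0_ms))
  if (length(x$meta))
    cat("  meta:", paste(names(x$meta), unlist(lapply(x$meta, format)),
                         sep = "=", collapse = ", "), "\n")
  invisible(x)
}

#' Movie frame times
#' @param movie A `voltage_movie` or `phase_movie`.
#' @return Numeric vector of frame times in ms.
#' @export
frame_times <- function(movie) {
  movie$t0_ms + (seq_len(dim(movie$frames)[3]) - 1) * movie$frame_interval_ms
}

#' Extract a time window of a movie
#'
#' @param movie A [voltage_movie()].
#' @param from_ms,to_ms Window bounds (inclusive, in movie time).
#' @return A [voltage_movie()] restricted to the window.
#' @export
subset_movie <- function(movie, from_ms, to_ms) {
  stopifnot(inherits(movie, "voltage_movie"))
  tt <- frame_times(movie)
  idx <- which(tt >= from_ms - 1e-9 & tt <= to_ms + 1e-9)
  if (length(idx) < 2L) stop("window contains fewer than 2 frames")
  if (length(idx) == length(tt)) return(movie)  # whole record: no copy
  voltage_movie(movie$frames[, , idx, drop = FALSE], movie$dx_mm,
                movie$frame_interval_ms, t0_ms = tt[idx[1]],
                meta = movie$meta)
}

#' Electrically active time window of a movie
#'
#' The interval over which fibrillatory activity is ongoing: frames must
#' carry a spatial voltage range above `min_range_mv`, and the window ends
#' at the last frame in which new depolarization occurred (the fraction of
#' excited pixels, V > -40 mV, still increased). After the last wavefront
#' dies the tissue only repolarizes; including that tail in the analysis
#' would bias the per-pixel mean voltage toward rest and distort the phase
#' origin.
#'
#' @param movie A [voltage_movie()].
#' @param min_range_mv Spatial V range threshold (default 25 mV).
#' @return `c(start_ms, end_ms)` of the active interval, or `NULL` if no
#'   frame is active.
#' @export
activity_window <- function(movie, min_range_mv = 25) {
  d <- dim(movie$frames)
  tt <- frame_times(movie)
  act <- logical(d[3])
  exc <- numeric(d[3])
  for (i in seq_len(d[3])) {
    fr <- movie$frames[, , i]
    act[i] <- (max(fr) - min(fr)) > min_range_mv
    exc[i] <- mean(fr > -40)
  }
  if (!any(act)) return(NULL)
  start_i <- which(act)[1]
  end_i <- max(which(act))
  rising <- which(diff(exc) > 0)
  if (length(rising)) end_i <- min(end_i, max(rising) + 1L)
  if (end_i < start_i) end_i <- max(which(act))
  c(tt[start_i], tt[end_i])
}

#' Decimate a movie in time and/or space
#'
#' Temporal decimation keeps every `time_factor`-th frame (the new frame
#' interval is `time_factor` times the old one). Spatial decimation keeps
#' every `space_factor`-th row and column starting at pixel (1, 1), e.g.
#' factor 2 maps a 0.25 mm compute grid onto the 0.5 mm display grid.
#'
#' @param movie A [voltage_movie()].
#' @param time_factor,space_factor Positive integer decimation factors.
#' @return A [voltage_movie()].
#' @export
decimate_movie <- function(movie, time_factor = 1L, space_factor = 1L) {
  stopifnot(inherits(movie, "voltage_movie"))
  tf <- as.integer(time_factor); sf <- as.integer(space_factor)
  if (tf < 1L || sf < 1L) stop("decimation factors must be >= 1")
  d <- dim(movie$frames)
  fr <- movie$frames[seq(1L, d[1], by = sf),
                     seq(1L, d[2], by = sf),
                     seq(1L, d[3], by = tf), drop = FALSE]
  voltage_movie(fr, dx_mm = movie$dx_mm * sf,
                frame_interval_ms = movie$frame_interval_ms * tf,
                t0_ms = movie$t0_ms,
                meta = c(movie$meta,
                         list(decimated = sprintf("time x%d, space x%d", tf, sf))))
}
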
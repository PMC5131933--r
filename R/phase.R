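#' Per-pixel mean voltage map
#'
#' The origin of the phase plane: `Vmean(x, y)` is the arithmetic mean of
#' the action potential at each pixel over an averaging window, by default
#' the whole provided record (intended to cover the fibrillation state).
#'
#' @param movie A [voltage_movie()].
#' @param window Optional `c(start_ms, end_ms)` restricting the average;
#'   `NULL` uses the whole movie.
#' @return An H x W matrix of class `mean_voltage_map` with attributes
#'   `window_ms` and `dx_mm`.
#' @export
compute_vmean <- function(movie, window = NULL) {
  stopifnot(inherits(movie, "voltage_movie"))
  tt <- frame_times(movie)
  if (is.null(window)) {
    idx <- seq_along(tt)
    window <- c(tt[1], tt[length(tt)])
  } else {
    stopifnot(length(window) == 2L, window[1] <= window[2])
    idx <- which(tt >= window[1] & tt <= window[2])
    if (!length(idx)) stop("empty averaging window")
  }
  d <- dim(movie$frames)
  # frame-wise accumulation: no full-movie copy for long records
  vm <- matrix(0, d[1], d[2])
  for (i in idx) vm <- vm + movie$frames[, , i]
  vm <- vm / length(idx)
  structure(vm, class = c("mean_voltage_map", "matrix"),
            window_ms = window, dx_mm = movie$dx_mm)
}

# phase of voltage frames p0..p1 (phase-frame indices) given vmean and the
# delay in frames; returns H x W x (p1-p0+1). delayed_first puts V(t+tau)
# on the ordinate (first atan2 argument).
phase_block <- function(frames, vmean, ntau, p0, p1, delayed_first = TRUE) {
  d <- dim(frames)
  n <- p1 - p0 + 1
  v0 <- frames[, , p0:p1, drop = FALSE] - as.vector(vmean)
  vd <- frames[, , (p0 + ntau):(p1 + ntau), drop = FALSE] - as.vector(vmean)
  th <- if (delayed_first) atan2(vd, v0) else atan2(v0, vd)
  # atan2 returns values in [-pi, pi]; fold -pi onto +pi for (-pi, pi]
  th[th == -pi] <- pi
  # declared convention: a pixel flat at Vmean has phase 0 (atan2(0,0) = 0)
  dim(th) <- c(d[1], d[2], n)
  th
}

#' Phase movie by time-delay embedding
#'
#' Computes the phase
#' `theta(x, y, t) = atan2(V(t + tau) - Vmean, V(t) - Vmean)`
#' at every pixel, i.e. the angle in the plane spanned by the signal and
#' its delayed copy, each centered on the per-pixel mean. Values lie in
#' (-pi, pi]. Phase frame i corresponds to voltage frame i (time t), using
#' voltage frames i and i + tau/frame_interval; the phase movie is tau
#' shorter than its source.
#'
#' `tau_ms` must be an integer multiple of the frame interval; no
#' interpolation is performed.
#'
#' @param movie A [voltage_movie()].
#' @param vmean A [compute_vmean()] map, or `NULL` to average the whole
#'   record.
#' @param tau_ms Embedding delay in ms (default 30).
#' @param delayed_first If `TRUE` (default) the delayed signal is the first
#'   atan2 argument (ordinate). The opposite order flips the sense of
#'   rotation (chirality) only.
#' @return An object of class `phase_movie`: list with `frames`
#'   (H x W x T'), `tau_ms`, `frame_interval_ms`, `dx_mm`, `t0_ms`,
#'   `degenerate` (H x W logical: pixels flat at Vmean, excluded from PS
#'   candidacy), and `vmean`.
#' @export
compute_phase <- function(movie, vmean = NULL, tau_ms = 30,
                          delayed_first = TRUE) {
  stopifnot(inherits(movie, "voltage_movie"))
  ntau <- tau_frames(tau_ms, movie$frame_interval_ms)
  d <- dim(movie$frames)
  if (d[3] <= ntau) stop("movie shorter than the embedding delay tau")
  if (is.null(vmean)) vmean <- compute_vmean(movie)
  stopifnot(all(dim(vmean) == d[1:2]))
  Tp <- d[3] - ntau
  th <- phase_block(movie$frames, vmean, ntau, 1L, Tp, delayed_first)
  amp <- amplitude_map(movie$frames, vmean)
  structure(
    list(frames = th, tau_ms = tau_ms,
         frame_interval_ms = movie$frame_interval_ms, dx_mm = movie$dx_mm,
         t0_ms = movie$t0_ms, degenerate = amp < 1e-9,
         vmean = vmean, delayed_first = delayed_first),
    class = "phase_movie")
}

# per-pixel max |V - Vmean| without materializing a full-size temporary
amplitude_map <- function(frames, vmean) {
  d <- dim(frames)
  amp <- matrix(0, d[1], d[2])
  vm <- as.vector(vmean)
  for (t in seq_len(d[3])) amp <- pmax(amp, abs(frames[, , t] - vm))
  amp
}

# tau in frames; errors unless tau is aligned to the sampling grid
tau_frames <- function(tau_ms, frame_interval_ms) {
  r <- tau_ms / frame_interval_ms
  if (abs(r - round(r)) > 1e-8)
    stop(sprintf(
      "tau (%g ms) must be an integer multiple of the frame interval (%g ms)",
      tau_ms, frame_interval_ms))
  n <- as.integer(round(r))
  if (n < 1L) stop("tau must be at least one frame interval")
  n
}

#' @export
print.phase_movie <- function(x, ...) {
  d <- dim(x$frames)
  cat(sprintf("<phase_movie> %d x %d px, %d frames @ %g ms, tau = %g ms, t0 = %g ms\n",
              d[1], d[2], d[3], x$frame_interval_ms, x$tau_ms, x$t0_ms))
  invisible(x)
}
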
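#' Specify an analytic spiral
#'
#' Ground-truth fixture: a rigidly rotating pseudo-voltage field
#' `V(r, c, t) = offset + amp * cos(atan2(y - y0(t), x - x0(t)) + k * d - omega * t)`
#' where d is the distance (mm) from pixel (r, c) to the core and
#' (x0, y0) is the core path in mm. The phase singularity location is known
#' exactly at every frame.
#'
#' @param core_path Either a numeric `c(x_mm, y_mm)` for a static core, or a
#'   function `f(t_ms)` returning `c(x_mm, y_mm)`.
#' @param omega_rad_per_ms Angular frequency (default pi/30 rad/ms, one
#'   rotation per 60 ms).
#' @param k_rad_per_mm Spatial wavenumber of the spiral arms (0 gives a
#'   rotating "pinwheel" with straight arms).
#' @param amplitude_mv,offset_mv Map the cosine to pseudo-voltage.
#' @return An object of class `analytic_spiral_spec`.
#' @export
analytic_spiral_spec <- function(core_path, omega_rad_per_ms = pi / 30,
                                 k_rad_per_mm = 0.5,
                                 amplitude_mv = 50, offset_mv = -30) {
  if (is.numeric(core_path)) {
    stopifnot(length(core_path) == 2L)
    xy <- core_path
    core_path <- function(t_ms) xy
  }
  stopifnot(is.function(core_path))
  structure(
    list(core_path = core_path, omega_rad_per_ms = omega_rad_per_ms,
         k_rad_per_mm = k_rad_per_mm, amplitude_mv = amplitude_mv,
         offset_mv = offset_mv),
    class = "analytic_spiral_spec")
}

#' Generate an analytic spiral movie with known core locations
#'
#' @param spec An [analytic_spiral_spec()].
#' @param grid A [sim_grid()].
#' @param duration_ms Movie length; frames at `0, dt, ..., duration_ms`.
#' @param frame_interval_ms Sampling interval (default 1 ms).
#' @return A list with `movie` (a [voltage_movie()]) and `truth`, a
#'   data.frame per frame: `frame`, `t_ms`, `x_mm`, `y_mm` (exact core),
#'   `row`, `col` (nearest grid pixel). If the core lies outside the grid at
#'   some frame, `row`/`col` are NA there.
#' @export
analytic_spiral_movie <- function(spec, grid, duration_ms,
                                  frame_interval_ms = 1) {
  stopifnot(inherits(spec, "analytic_spiral_spec"), inherits(grid, "sim_grid"))
  H <- grid$height_cells; W <- grid$width_cells; dx <- grid$dx_mm
  times <- seq(0, duration_ms, by = frame_interval_ms)
  Tn <- length(times)
  x <- (seq_len(W) - 1) * dx
  y <- (seq_len(H) - 1) * dx
  X <- matrix(x, H, W, byrow = TRUE)
  Y <- matrix(y, H, W)
  frames <- array(NA_real_, c(H, W, Tn))
  truth <- data.frame(frame = seq_len(Tn), t_ms = times,
                      x_mm = NA_real_, y_mm = NA_real_,
                      row = NA_integer_, col = NA_integer_)
  for (i in seq_len(Tn)) {
    core <- spec$core_path(times[i])
    dxm <- X - core[1]; dym <- Y - core[2]
    d <- sqrt(dxm^2 + dym^2)
    phi <- atan2(dym, dxm) + spec$k_rad_per_mm * d -
      spec$omega_rad_per_ms * times[i]
    frames[, , i] <- spec$offset_mv + spec$amplitude_mv * cos(phi)
    truth$x_mm[i] <- core[1]; truth$y_mm[i] <- core[2]
    r <- round(core[2] / dx) + 1; c <- round(core[1] / dx) + 1
    if (r >= 1 && r <= H && c >= 1 && c <= W) {
      truth$row[i] <- as.integer(r); truth$col[i] <- as.integer(c)
    }
  }
  movie <- voltage_movie(frames, dx_mm = dx,
                         frame_interval_ms = frame_interval_ms,
                         meta = list(solver = "analytic-spiral",
                                     scenario = "analytic",
                                     omega_rad_per_ms = spec$omega_rad_per_ms,
                                     k_rad_per_mm = spec$k_rad_per_mm))
  list(movie = movie, truth = truth)
}
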
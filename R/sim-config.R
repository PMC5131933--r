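#' Define a 2D tissue grid
#'
#' A rectangular sheet of cells on a uniform square grid with no-flux
#' boundaries. Pixel (r, c) sits at physical coordinates
#' x = (c - 1) * dx_mm, y = (r - 1) * dx_mm, with the origin at the top-left
#' pixel and rows increasing downward.
#'
#' @param height_cells,width_cells Number of rows / columns (>= 3).
#' @param dx_mm Grid spacing in mm (default 0.25, the compute resolution).
#' @return An object of class `sim_grid`.
#' @export
sim_grid <- function(height_cells, width_cells, dx_mm = 0.25) {
  height_cells <- as.integer(height_cells)
  width_cells <- as.integer(width_cells)
  if (height_cells < 3L || width_cells < 3L)
    stop("grid must be at least 3 x 3 cells")
  if (!is.finite(dx_mm) || dx_mm <= 0) stop("dx_mm must be positive")
  structure(
    list(height_cells = height_cells, width_cells = width_cells,
         dx_mm = dx_mm, boundary = "no_flux"),
    class = "sim_grid")
}

#' Cross-field S1-S2 stimulation protocol
#'
#' S1 is a vertical "field" stimulus applied as a current injection over a
#' full-height strip on the left edge; S2 is a horizontal stimulus over a
#' strip covering the bottom part of the sheet, fired one coupling interval
#' after S1. The crossed activation gradients break the S2 wavefront on the
#' repolarization tail of S1 and initiate a spiral.
#'
#' @param s1_time_ms Onset of the first S1 beat (ms).
#' @param n_s1 Number of S1 conditioning beats (default 2). With a single
#'   beat from rest the first action potential outlasts the 300 ms coupling
#'   interval and S2 is refractory-blocked everywhere; a short conditioning
#'   drive engages APD restitution so that S2 lands in the vulnerable
#'   window, as in standard S1-S2 pacing.
#' @param s1_cycle_ms Interval between S1 beats (default 350 ms).
#' @param s2_coupling_interval_ms Interval from the last S1 beat to S2
#'   (default 300 ms).
#' @param amplitude Stimulus current density in pA/pF (positive =
#'   depolarizing). The default 25 pA/pF is about twice the diastolic
#'   threshold; much stronger pulses fire relative-refractory tissue
#'   directly and suppress the conduction block that initiates reentry.
#' @param duration_ms Stimulus pulse width in ms (default 2).
#' @param s1_region,s2_region Optional rectangular masks
#'   `c(row_min, row_max, col_min, col_max)` in cell indices (1-based,
#'   inclusive); `NULL` selects the default edge-strip geometry for the grid
#'   at hand (S1: full-height strip, leftmost 2 mm; S2: the full bottom
#'   half of the sheet).
#' @return An object of class `stim_protocol`.
#' @export
stim_protocol <- function(s1_time_ms = 1, n_s1 = 2, s1_cycle_ms = 350,
                          s2_coupling_interval_ms = 300,
                          amplitude = 25, duration_ms = 2,
                          s1_region = NULL, s2_region = NULL) {
  if (s2_coupling_interval_ms <= 0) stop("coupling interval must be positive")
  n_s1 <- as.integer(n_s1)
  if (n_s1 < 1L) stop("need at least one S1 beat")
  if (amplitude <= 0 || duration_ms <= 0)
    stop("stimulus amplitude and duration must be positive")
  s1_times <- s1_time_ms + (seq_len(n_s1) - 1L) * s1_cycle_ms
  structure(
    list(s1_time_ms = s1_time_ms, n_s1 = n_s1, s1_cycle_ms = s1_cycle_ms,
         s1_times_ms = s1_times,
         s2_coupling_interval_ms = s2_coupling_interval_ms,
         s2_time_ms = s1_times[n_s1] + s2_coupling_interval_ms,
         amplitude = amplitude, duration_ms = duration_ms,
         s1_region = s1_region, s2_region = s2_region),
    class = "stim_protocol")
}

# resolve the default edge-strip geometry against a concrete grid
resolve_protocol_regions <- function(protocol, grid) {
  strip <- max(2L, as.integer(round(2 / grid$dx_mm)))  # ~2 mm strips
  s1 <- protocol$s1_region
  s2 <- protocol$s2_region
  if (is.null(s1)) s1 <- c(1L, grid$height_cells, 1L, strip)
  if (is.null(s2)) {
    r0 <- as.integer(floor(grid$height_cells / 2)) + 1L
    s2 <- c(r0, grid$height_cells, 1L, grid$width_cells)
  }
  check <- function(m, nm) {
    if (length(m) != 4L || m[1] < 1 || m[3] < 1 ||
        m[2] > grid$height_cells || m[4] > grid$width_cells ||
        m[1] > m[2] || m[3] > m[4])
      stop(sprintf("%s region outside grid", nm))
    as.integer(m)
  }
  list(s1 = check(s1, "s1"), s2 = check(s2, "s2"))
}

#' Monodomain simulation configuration
#'
#' Bundles the grid, diffusion and membrane constants, time-stepping bounds,
#' output cadence, ionic-remodeling scenario, and stimulation protocol for
#' [run_monodomain()].
#'
#' The solver advances diffusion at `dt_max_ms` (explicit 5-point Laplacian,
#' stable for the default D, dx) and sub-steps the ionic reaction term at
#' `dt_min_ms` in any cell whose projected voltage change in one macro step
#' exceeds `dv_max_mv`, so the effective time step varies within
#' `[dt_min_ms, dt_max_ms]` cell by cell.
#'
#' @param grid A [sim_grid()].
#' @param duration_ms Total simulated time (ms).
#' @param D_cm2_per_ms Diffusion coefficient (default 0.001 cm^2/ms).
#' @param Cm_uF_per_cm2 Specific membrane capacitance (default 1; currents
#'   are expressed per unit capacitance so this acts as a pure scale).
#' @param dt_min_ms,dt_max_ms Adaptive time-step bounds (default 0.01, 0.1).
#' @param dv_max_mv Per-step voltage change that triggers sub-stepping
#'   (default 0.8 mV).
#' @param sample_interval_ms Output cadence (default 1 ms).
#' @param record_from_ms First recorded frame time (default 0); earlier
#'   activity is simulated but not stored.
#' @param scenario A [scenario_config()]; default control.
#' @param protocol A [stim_protocol()], or `NULL` for no stimulation.
#' @return An object of class `sim_config`.
#' @export
sim_config <- function(grid, duration_ms,
                       D_cm2_per_ms = 0.001, Cm_uF_per_cm2 = 1,
                       dt_min_ms = 0.01, dt_max_ms = 0.1, dv_max_mv = 0.8,
                       sample_interval_ms = 1, record_from_ms = 0,
                       scenario = scenario_config(),
                       protocol = stim_protocol()) {
  stopifnot(inherits(grid, "sim_grid"))
  if (!(dt_min_ms > 0 && dt_min_ms <= dt_max_ms &&
        dt_max_ms <= sample_interval_ms))
    stop("need 0 < dt_min_ms <= dt_max_ms <= sample_interval_ms")
  if (D_cm2_per_ms <= 0 || Cm_uF_per_cm2 <= 0) stop("D and Cm must be positive")
  if (duration_ms <= 0) stop("duration_ms must be positive")
  if (record_from_ms < 0 || record_from_ms >= duration_ms)
    stop("record_from_ms must lie in [0, duration_ms)")
  stopifnot(inherits(scenario, "scenario_config"))
  if (!is.null(protocol)) stopifnot(inherits(protocol, "stim_protocol"))
  structure(
    list(grid = grid, duration_ms = duration_ms,
         D_cm2_per_ms = D_cm2_per_ms, Cm_uF_per_cm2 = Cm_uF_per_cm2,
         dt_min_ms = dt_min_ms, dt_max_ms = dt_max_ms, dv_max_mv = dv_max_mv,
         sample_interval_ms = sample_interval_ms,
         record_from_ms = record_from_ms,
         scenario = scenario, protocol = protocol),
    class = "sim_config")
}
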
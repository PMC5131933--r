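#' Run a 2D monodomain simulation
#'
#' Solves the monodomain reaction-diffusion equation
#' dV/dt = -(I_ion + I_stim)/Cm + D (d2V/dx2 + d2V/dy2)
#' on a rectangular sheet with no-flux boundaries, with the
#' Courtemanche-Ramirez-Nattel human atrial model supplying I_ion. Every
#' cell starts from the model's resting steady state. The Laplacian is the
#' explicit 5-point stencil; ghost nodes mirror the boundary cells so that
#' the discrete spatial mean is conserved exactly when the reaction term is
#' off. Time stepping is locally adaptive between `dt_min_ms` and
#' `dt_max_ms` (see [sim_config()]).
#'
#' The solver is fully deterministic: identical configurations produce
#' identical movies.
#'
#' @param config A [sim_config()].
#' @param passive If `TRUE`, disable the ionic model and stimulation and
#'   integrate pure diffusion (used for conservation checks).
#' @param init_v Optional H x W matrix of initial voltages (mV); the other
#'   state variables still start from the resting steady state.
#' @return A [voltage_movie()] sampled every `sample_interval_ms` from
#'   `record_from_ms` onward, with provenance metadata.
#' @export
run_monodomain <- function(config, passive = FALSE, init_v = NULL) {
  stopifnot(inherits(config, "sim_config"))
  g <- config$grid
  D_eff <- config$D_cm2_per_ms * config$scenario$multipliers[["D_scale"]]

  if (is.null(config$protocol) || passive) {
    rect <- matrix(0L, 0, 4)
    tim <- matrix(0, 0, 3)
  } else {
    p <- config$protocol
    reg <- resolve_protocol_regions(p, g)
    # C++ uses 0-based inclusive rectangles; one row per S1 beat plus S2
    rect <- do.call(rbind, c(rep(list(reg$s1 - 1L), p$n_s1),
                             list(reg$s2 - 1L)))
    tim <- rbind(cbind(p$s1_times_ms, p$duration_ms, p$amplitude),
                 c(p$s2_time_ms, p$duration_ms, p$amplitude))
  }

  res <- sim_monodomain_cpp(
    H = g$height_cells, W = g$width_cells, dx_mm = g$dx_mm,
    D_cm2_ms = D_eff / config$Cm_uF_per_cm2,
    dt_min = config$dt_min_ms, dt_max = config$dt_max_ms,
    dv_max = config$dv_max_mv,
    duration_ms = config$duration_ms,
    record_from_ms = config$record_from_ms,
    sample_interval_ms = config$sample_interval_ms,
    mult = scenario_mult_vector(config$scenario),
    stim_rect = rect, stim_time = tim, passive = passive,
    init_v = init_v)

  voltage_movie(res$frames, dx_mm = g$dx_mm,
                frame_interval_ms = config$sample_interval_ms,
                t0_ms = res$t0_ms,
                meta = list(scenario = config$scenario$name,
                            solver = if (passive) "monodomain-passive"
                                     else "monodomain-courtemanche",
                            D_cm2_per_ms = D_eff,
                            dt_min_ms = config$dt_min_ms,
                            dt_max_ms = config$dt_max_ms,
                            protocol = if (!is.null(config$protocol) && !passive)
                              "cross-field S1-S2 (edge strips)" else "none"))
}

#' Single-cell Courtemanche action potential
#'
#' Integrates one isolated Courtemanche cell with the same stepper as the
#' tissue solver (Rush-Larsen gates, locally adaptive dt, tabulated rates).
#'
#' @param duration_ms Simulated time.
#' @param stim_times_ms Onsets of depolarizing current pulses.
#' @param stim_amplitude Pulse amplitude in pA/pF (positive depolarizes).
#' @param stim_duration_ms Pulse width.
#' @param scenario A [scenario_config()].
#' @param sample_interval_ms Output cadence.
#' @param dt_min_ms,dt_max_ms,dv_max_mv Stepper controls as in [sim_config()].
#' @param init_state Optional full 21-element state vector to start from
#'   (default: published resting state).
#' @return A data.frame with columns `time_ms`, `V`; the final state vector
#'   is attached as attribute `"state"`.
#' @export
sim_courtemanche_cell <- function(duration_ms = 600,
                                  stim_times_ms = 10,
                                  stim_amplitude = 20,
                                  stim_duration_ms = 2,
                                  scenario = scenario_config(),
                                  sample_interval_ms = 1,
                                  dt_min_ms = 0.01, dt_max_ms = 0.1,
                                  dv_max_mv = 0.8,
                                  init_state = NULL) {
  stopifnot(inherits(scenario, "scenario_config"))
  n <- length(stim_times_ms)
  res <- sim_cell_cpp(duration_ms, sample_interval_ms, dt_min_ms, dt_max_ms,
                      dv_max_mv, scenario_mult_vector(scenario),
                      stim_start = as.numeric(stim_times_ms),
                      stim_dur = rep(stim_duration_ms, n),
                      stim_amp = rep(stim_amplitude, n),
                      init_state = init_state)
  out <- data.frame(time_ms = res$time_ms, V = res$V)
  attr(out, "state") <- res$state
  out
}

#' Action potential duration at a repolarization fraction
#'
#' APD is measured from the time of maximum upstroke velocity to the
#' crossing of `V_rest + (1 - level) * (V_peak - V_rest)` on the way down,
#' with linear interpolation between samples.
#'
#' @param time_ms,V Sampled action-potential trace.
#' @param level Repolarization fraction (0.9 gives APD90).
#' @return APD in ms (NA if the trace never repolarizes to the level).
#' @export
apd <- function(time_ms, V, level = 0.9) {
  i_up <- which.max(diff(V))
  v_rest <- V[max(1, i_up - 2)]
  v_peak <- max(V[i_up:length(V)])
  v_cross <- v_peak - level * (v_peak - v_rest)
  i_pk <- which.max(V)
  below <- which(V[(i_pk + 1):length(V)] <= v_cross)
  if (!length(below)) return(NA_real_)
  j <- i_pk + below[1]
  # linear interpolation between samples j-1 and j
  f <- (V[j - 1] - v_cross) / (V[j - 1] - V[j])
  t_cross <- time_ms[j - 1] + f * (time_ms[j] - time_ms[j - 1])
  t_cross - time_ms[i_up]
}
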
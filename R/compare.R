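# Chunked detection engine: computes the phase movie block-by-block (so
# long high-rate movies never materialize a full phase array) and runs the
# Iyer-Gray detector plus the location-centric detector at one or more
# thresholds M. Returns pooled ps_set data.frames.
detect_both_chunked <- function(movie, tau_ms = 30, M = -pi,
                                vmean_window = NULL, delayed_first = TRUE,
                                chunk_frames = 128L,
                                ig_config = NULL, lc_frame_assign = "next") {
  stopifnot(inherits(movie, "voltage_movie"))
  ntau <- tau_frames(tau_ms, movie$frame_interval_ms)
  d <- dim(movie$frames)
  Tp <- d[3] - ntau
  if (Tp < 2L) stop("movie shorter than the embedding delay tau")
  vmean <- compute_vmean(movie, vmean_window)
  amp <- amplitude_map(movie$frames, vmean)
  degen <- amp < 1e-9
  if (is.null(ig_config)) ig_config <- detector_config("iyer_gray")
  lc_cfgs <- lapply(M, function(m)
    detector_config("location_centric", M_threshold = m,
                    frame_assign = lc_frame_assign))
  ig_out <- list()
  lc_out <- rep(list(list()), length(M))
  p0 <- 1L
  prev_last <- NULL  # last phase frame of the previous block (H x W)
  while (p0 <= Tp) {
    p1 <- min(p0 + chunk_frames - 1L, Tp)
    th <- phase_block(movie$frames, vmean, ntau, p0, p1, delayed_first)
    pm <- structure(
      list(frames = th, tau_ms = tau_ms,
           frame_interval_ms = movie$frame_interval_ms, dx_mm = movie$dx_mm,
           t0_ms = movie$t0_ms + (p0 - 1L) * movie$frame_interval_ms,
           degenerate = degen, vmean = vmean, delayed_first = delayed_first),
      class = "phase_movie")
    nblk <- p1 - p0 + 1L
    for (i in seq_len(nblk)) {
      df <- detect_iyer_gray(pm, ig_config, frame = i)
      if (nrow(df)) {
        df$frame <- df$frame + (p0 - 1L)
        ig_out[[length(ig_out) + 1L]] <- as.data.frame(df)
      }
    }
    for (mi in seq_along(M)) {
      cfg <- lc_cfgs[[mi]]
      # pair spanning the block boundary
      if (!is.null(prev_last)) {
        dth <- th[, , 1L] - prev_last
        flag <- dth < cfg$M_threshold & !degen
        idx <- which(flag, arr.ind = TRUE)
        if (nrow(idx)) {
          fr <- if (cfg$frame_assign == "next") p0 else p0 - 1L
          t_ms <- movie$t0_ms + (fr - 1L) * movie$frame_interval_ms
          lc_out[[mi]][[length(lc_out[[mi]]) + 1L]] <-
            ps_points(idx[, 1], idx[, 2], as.integer(fr), t_ms,
                      movie$dx_mm, NA_integer_, "location_centric")
        }
      }
      for (i in seq_len(nblk - 1L)) {
        df <- detect_location_centric(pm, i, cfg)
        if (nrow(df)) {
          df$frame <- df$frame + (p0 - 1L)
          df$t_ms <- movie$t0_ms + (df$frame - 1L) * movie$frame_interval_ms
          lc_out[[mi]][[length(lc_out[[mi]]) + 1L]] <- as.data.frame(df)
        }
      }
    }
    prev_last <- th[, , nblk]
    p0 <- p1 + 1L
    rm(th, pm)
    invisible(gc(FALSE))  # long high-rate movies: release chunk temporaries
  }
  bindup <- function(lst, cfg) {
    df <- do.call(rbind, c(list(empty_ps()), lst))
    as_ps_set(df, movie$dx_mm, cfg)
  }
  list(ig = bindup(ig_out, ig_config),
       lc = lapply(seq_along(M), function(mi) bindup(lc_out[[mi]], lc_cfgs[[mi]])),
       M = M, vmean = vmean)
}

#' Compare the two PS detectors on one movie
#'
#' Computes the phase once (delay `tau_ms`, whole-record Vmean unless a
#' window is given), runs the Iyer-Gray and location-centric detectors over
#' the full movie, pools each method's detections across frames into a
#' spatial trajectory point set, snaps both to `resolution_mm`, and returns
#' the directed and symmetric Hausdorff distances.
#'
#' @param movie A [voltage_movie()].
#' @param tau_ms Embedding delay (default 30 ms).
#' @param M Location-centric threshold (default -pi). May be a vector: the
#'   report then contains one Hausdorff result per threshold (the Iyer-Gray
#'   set does not depend on M and is reused).
#' @param resolution_mm Snap resolution for the distance (default 0.5 mm).
#' @param vmean_window Optional `c(start_ms, end_ms)` for the Vmean average.
#' @param keep_points If `TRUE`, attach the pooled `ps_set`s to the result.
#' @param chunk_frames Internal phase-block size (memory control).
#' @return For scalar `M`: a `hausdorff_report` with the per-frame counts of
#'   both methods (and the point sets if requested). For vector `M`: a list
#'   of reports, one per threshold, with attribute `M`.
#' @export
compare_methods <- function(movie, tau_ms = 30, M = -pi, resolution_mm = 0.5,
                            vmean_window = NULL, keep_points = FALSE,
                            chunk_frames = 128L) {
  both <- detect_both_chunked(movie, tau_ms = tau_ms, M = M,
                              vmean_window = vmean_window,
                              chunk_frames = chunk_frames)
  one <- function(mi) {
    lc <- both$lc[[mi]]
    if (!nrow(both$ig) || !nrow(lc))
      stop(sprintf(
        "empty PS set: iyer_gray %d points, location_centric %d points (M = %.3f)",
        nrow(both$ig), nrow(lc), both$M[mi]))
    rep <- hausdorff(both$ig, lc, resolution_mm)
    rep$tau_ms <- tau_ms
    rep$M <- both$M[mi]
    if (keep_points) { rep$ps_ig <- both$ig; rep$ps_lc <- lc }
    rep
  }
  if (length(M) == 1L) return(one(1L))
  out <- lapply(seq_along(M), one)
  attr(out, "M") <- M
  out
}

#' Sweep a parameter of the method comparison
#'
#' Runs [compare_methods()] for each value of one swept parameter:
#' \describe{
#'   \item{`tau_ms`}{embedding delay; values not aligned to the frame
#'     interval are skipped with a warning.}
#'   \item{`M`}{location-centric threshold (phase computed once).}
#'   \item{`sample_interval_ms`}{the movie must be stored at the finest
#'     interval; each value decimates it temporally before recomputing
#'     the phase. Non-multiples are skipped with a warning.}
#'   \item{`scenario`}{`x` must be a [sim_config()]; each value (a scenario
#'     name for [scenario_preset()] or a [scenario_config()]) reruns the
#'     simulation.}
#' }
#'
#' @param x A [voltage_movie()] (or a [sim_config()] for scenario sweeps).
#' @param parameter One of `"tau_ms"`, `"M"`, `"sample_interval_ms"`,
#'   `"scenario"`.
#' @param values Vector (or list) of swept values.
#' @param ... Fixed arguments passed to [compare_methods()].
#' @return An object of class `sweep_result`: list with `parameter`,
#'   `values`, `hd_mm` (symmetric Hausdorff per value, NA where skipped),
#'   `n_ig`, `n_lc` (pooled set sizes) and `reports`.
#' @export
sweep_compare <- function(x, parameter = c("tau_ms", "M",
                                           "sample_interval_ms", "scenario"),
                          values, ...) {
  parameter <- match.arg(parameter)
  n <- length(values)
  reports <- vector("list", n)
  if (parameter == "M") {
    reports <- compare_methods(x, M = unlist(values), ...)
    if (n == 1L) reports <- list(reports)
  } else {
    for (i in seq_len(n)) {
      v <- if (is.list(values)) values[[i]] else values[i]
      reports[[i]] <- tryCatch(
        switch(parameter,
          tau_ms = compare_methods(x, tau_ms = v, ...),
          sample_interval_ms = {
            stopifnot(inherits(x, "voltage_movie"))
            f <- v / x$frame_interval_ms
            if (abs(f - round(f)) > 1e-8)
              stop(sprintf("interval %g ms is not a multiple of the stored %g ms",
                           v, x$frame_interval_ms))
            compare_methods(decimate_movie(x, time_factor = round(f)), ...)
          },
          scenario = {
            stopifnot(inherits(x, "sim_config"))
            sc <- if (inherits(v, "scenario_config")) v else scenario_preset(v)
            cfg <- x; cfg$scenario <- sc
            compare_methods(run_monodomain(cfg), ...)
          }),
        error = function(e) {
          warning(sprintf("sweep value %s skipped: %s",
                          format(if (inherits(v, "scenario_config")) v$name else v),
                          conditionMessage(e)), call. = FALSE)
          NULL
        })
    }
  }
  hd <- vapply(reports, function(r) if (is.null(r)) NA_real_ else r$H_mm,
               numeric(1))
  n_ig <- vapply(reports, function(r) if (is.null(r)) NA_integer_ else r$n_a_raw,
                 integer(1))
  n_lc <- vapply(reports, function(r) if (is.null(r)) NA_integer_ else r$n_b_raw,
                 integer(1))
  structure(
    list(parameter = parameter,
         values = if (parameter == "scenario")
           vapply(values, function(v)
             if (inherits(v, "scenario_config")) v$name else as.character(v),
             character(1))
         else unlist(values),
         hd_mm = hd, n_ig = n_ig, n_lc = n_lc, reports = reports),
    class = "sweep_result")
}

#' @export
print.sweep_result <- function(x, ...) {
  cat("<sweep_result> parameter:", x$parameter, "\n")
  print(data.frame(value = x$values, hd_mm = round(x$hd_mm, 3),
                   n_ig = x$n_ig, n_lc = x$n_lc))
  invisible(x)
}

#' Benchmark the two detectors
#'
#' Times PS detection (detection only: the phase movie is computed once and
#' shared, and I/O is excluded) for the Iyer-Gray and location-centric
#' methods on the same input. A warm-up run of each detector is discarded;
#' the median of `repeats` timed runs on a monotonic clock is reported.
#' Absolute times are hardware-dependent; the quantity of interest is the
#' ratio.
#'
#' @param movie A [voltage_movie()] (phase computed here) or a
#'   `phase_movie`.
#' @param tau_ms,M Detection parameters.
#' @param repeats Number of timed repetitions (>= 3).
#' @return List with `ig_ms`, `lc_ms` (median wall-clock in ms), `ratio`
#'   (Iyer-Gray / location-centric, guarded against division by ~0),
#'   `repeats`, and the detection counts.
#' @export
benchmark_detectors <- function(movie, tau_ms = 30, M = -pi, repeats = 3L) {
  if (repeats < 3L) stop("repeats must be >= 3")
  pm <- if (inherits(movie, "phase_movie")) movie
        else compute_phase(movie, tau_ms = tau_ms)
  cfg_ig <- detector_config("iyer_gray")
  cfg_lc <- detector_config("location_centric", M_threshold = M)
  time_one <- function(cfg) {
    invisible(detect_movie(pm, cfg))  # warm-up, discarded
    ts <- vapply(seq_len(repeats), function(i) {
      t0 <- proc.time()[["elapsed"]]
      invisible(detect_movie(pm, cfg))
      proc.time()[["elapsed"]] - t0
    }, numeric(1))
    stats::median(ts) * 1000
  }
  ig_ms <- time_one(cfg_ig)
  lc_ms <- time_one(cfg_lc)
  list(ig_ms = ig_ms, lc_ms = lc_ms,
       ratio = ig_ms / max(lc_ms, 1e-6),
       repeats = repeats,
       n_ig = nrow(detect_movie(pm, cfg_ig)),
       n_lc = nrow(detect_movie(pm, cfg_lc)))
}
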
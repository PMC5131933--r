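#' Wrapped phase difference
#'
#' `a - b` wrapped into (-pi, pi], the elementary operation of any discrete
#' line integral of phase.
#'
#' @param a,b Phases in radians (vectorized).
#' @return `(a - b)` wrapped into (-pi, pi].
#' @export
wrapped_diff <- function(a, b) {
  d <- (a - b) %% (2 * pi)
  d[d > pi] <- d[d > pi] - 2 * pi
  d
}

#' Detector configuration
#'
#' @param method `"iyer_gray"` (line-integral winding criterion) or
#'   `"location_centric"` (temporal phase-discontinuity criterion).
#' @param M_threshold Threshold for the location-centric criterion, in
#'   radians; must be negative (only negative phase jumps mark a
#'   singularity; depolarization produces positive jumps). Default -pi.
#' @param include_positive_winding,include_negative_winding Which winding
#'   signs count as detections for Iyer-Gray (default both, the +/- 2pi
#'   criterion).
#' @param border_margin Cells to exclude at the border. Default 1 for
#'   Iyer-Gray (the 8-neighbor loop needs interior pixels) and 0 for
#'   location-centric, which needs no neighbors.
#' @param frame_assign For location-centric: report a detection from the
#'   pair (n, n+1) at frame `"next"` (n+1, default: the frame where the new
#'   phase holds) or `"current"` (n).
#' @return An object of class `detector_config`.
#' @export
detector_config <- function(method = c("iyer_gray", "location_centric"),
                            M_threshold = -pi,
                            include_positive_winding = TRUE,
                            include_negative_winding = TRUE,
                            border_margin = NULL,
                            frame_assign = c("next", "current")) {
  method <- match.arg(method)
  frame_assign <- match.arg(frame_assign)
  if (!is.finite(M_threshold) || M_threshold >= 0)
    stop("M_threshold must be negative (only negative phase jumps are singular)")
  if (is.null(border_margin))
    border_margin <- if (method == "iyer_gray") 1L else 0L
  border_margin <- as.integer(border_margin)
  if (method == "iyer_gray" && border_margin < 1L)
    stop("iyer_gray needs border_margin >= 1 (8-neighbor loop)")
  structure(
    list(method = method, M_threshold = M_threshold,
         include_positive_winding = include_positive_winding,
         include_negative_winding = include_negative_winding,
         border_margin = border_margin, frame_assign = frame_assign),
    class = "detector_config")
}

# closed 8-neighbor loop, declared start at the east neighbor and traversed
# in the sense of increasing atan2(row - r0, col - c0) (counter-clockwise in
# the x = col, y = row frame), so that such a vortex has winding +1
ring_offsets <- function() {
  list(c(0L, 1L), c(1L, 1L), c(1L, 0L), c(1L, -1L),
       c(0L, -1L), c(-1L, -1L), c(-1L, 0L), c(-1L, 1L))
}

#' Winding number of a phase frame around one pixel
#'
#' Sum of wrapped phase differences between consecutive neighbors along the
#' closed 8-neighbor loop around (row, col), divided by 2 pi and rounded to
#' the nearest integer. A value of +/-1 signals an enclosed phase
#' singularity.
#'
#' @param phase_frame H x W matrix of phases in (-pi, pi].
#' @param row,col Probe pixel (1-based); must be at least one cell from the
#'   border.
#' @return Integer winding number.
#' @export
winding_number <- function(phase_frame, row, col) {
  d <- dim(phase_frame)
  if (row < 2 || col < 2 || row > d[1] - 1 || col > d[2] - 1)
    stop("winding_number needs an interior pixel (8 neighbors)")
  off <- ring_offsets()
  ph <- vapply(off, function(o) phase_frame[row + o[1], col + o[2]],
               numeric(1))
  tot <- sum(wrapped_diff(ph[c(2:8, 1)], ph))
  as.integer(round(tot / (2 * pi)))
}

# winding numbers of all pixels with the given border margin;
# returns an (H - 2m) x (W - 2m) integer matrix (compiled kernel)
winding_field <- function(phase_frame, margin = 1L) {
  winding_field_cpp(phase_frame, as.integer(margin))
}

# pure-R reference implementation of the same field, kept as the
# cross-check for the compiled kernel
winding_field_r <- function(phase_frame, margin = 1L) {
  d <- dim(phase_frame)
  m <- as.integer(margin)
  rows <- (1L + m):(d[1] - m)
  cols <- (1L + m):(d[2] - m)
  off <- ring_offsets()
  sub <- function(o) phase_frame[rows + o[1], cols + o[2], drop = FALSE]
  tot <- 0
  prev <- sub(off[[1L]])
  for (k in 2:9) {
    cur <- if (k <= 8) sub(off[[k]]) else sub(off[[1L]])
    tot <- tot + wrapped_diff(cur, prev)
    prev <- cur
  }
  w <- round(tot / (2 * pi))
  storage.mode(w) <- "integer"
  w
}

# assemble a PS point data.frame from flagged (row, col) indices
ps_points <- function(rows, cols, frame, t_ms, dx_mm, chirality, method) {
  data.frame(method = method, frame = frame, t_ms = t_ms,
             row = rows, col = cols,
             x_mm = (cols - 1) * dx_mm, y_mm = (rows - 1) * dx_mm,
             chirality = chirality)
}

empty_ps <- function() {
  data.frame(method = character(), frame = integer(), t_ms = numeric(),
             row = integer(), col = integer(), x_mm = numeric(),
             y_mm = numeric(), chirality = integer())
}

as_ps_set <- function(df, dx_mm, config) {
  df <- df[order(df$frame, df$row, df$col), , drop = FALSE]
  rownames(df) <- NULL
  structure(df, dx_mm = dx_mm, config = config,
            class = c("ps_set", "data.frame"))
}

#' Iyer-Gray line-integral PS detection on one frame
#'
#' Flags every interior pixel whose 8-neighbor loop carries a winding of
#' +/-1 (line integral of the phase gradient equal to +/- 2 pi). All
#' flagged pixels are reported (a rotor typically shows as a small cluster
#' of flagged pixels); no centroid merging is applied.
#'
#' @param phase_frame H x W phase matrix, or a `phase_movie` together with
#'   `frame`.
#' @param config A [detector_config()] with method `"iyer_gray"`.
#' @param frame Frame index when `phase_frame` is a `phase_movie`.
#' @return A `ps_set` data.frame (method, frame, t_ms, row, col, x_mm,
#'   y_mm, chirality = winding sign).
#' @export
detect_iyer_gray <- function(phase_frame,
                             config = detector_config("iyer_gray"),
                             frame = 1L) {
  stopifnot(config$method == "iyer_gray")
  degen <- NULL
  dx <- NA_real_; t_ms <- NA_real_
  if (inherits(phase_frame, "phase_movie")) {
    pm <- phase_frame
    dx <- pm$dx_mm
    t_ms <- pm$t0_ms + (frame - 1) * pm$frame_interval_ms
    degen <- pm$degenerate
    phase_frame <- pm$frames[, , frame]
  }
  m <- config$border_margin
  w <- winding_field(phase_frame, margin = m)
  keep <- (w == 1L & config$include_positive_winding) |
          (w == -1L & config$include_negative_winding)
  idx <- which(keep, arr.ind = TRUE)
  if (!nrow(idx)) return(as_ps_set(empty_ps(), dx, config))
  rows <- idx[, 1] + m; cols <- idx[, 2] + m
  chir <- w[keep]
  if (!is.null(degen)) {
    ok <- !degen[cbind(rows, cols)]
    rows <- rows[ok]; cols <- cols[ok]; chir <- chir[ok]
  }
  if (!length(rows)) return(as_ps_set(empty_ps(), dx, config))
  as_ps_set(ps_points(rows, cols, as.integer(frame), t_ms, dx, chir,
                      "iyer_gray"), dx, config)
}

#' Location-centric PS detection on one frame pair
#'
#' Flags every pixel whose raw successive-frame phase difference
#' `theta(n+1) - theta(n)` falls below the negative threshold M. The
#' difference is deliberately not wrapped: wrapping into (-pi, pi] would
#' make values below -pi impossible and empty the criterion. No neighbor
#' information is used, so the criterion runs on any grid point including
#' borders, and carries no chirality.
#'
#' @param phase_movie A `phase_movie`.
#' @param frame_n Index n of the earlier frame of the pair (n + 1 must
#'   exist).
#' @param config A [detector_config()] with method `"location_centric"`.
#' @return A `ps_set` data.frame; chirality is NA (unknown).
#' @export
detect_location_centric <- function(phase_movie, frame_n,
                                    config = detector_config("location_centric")) {
  stopifnot(inherits(phase_movie, "phase_movie"),
            config$method == "location_centric")
  d <- dim(phase_movie$frames)
  if (frame_n < 1L || frame_n + 1L > d[3])
    stop("frame_n + 1 must exist (the last frame cannot be evaluated)")
  hits <- lc_hits_cpp(phase_movie$frames[, , frame_n],
                      phase_movie$frames[, , frame_n + 1L],
                      config$M_threshold)
  flag <- matrix(FALSE, d[1], d[2])
  flag[hits] <- TRUE
  flag <- flag & !phase_movie$degenerate
  m <- config$border_margin
  if (m > 0L) {
    keep <- matrix(FALSE, d[1], d[2])
    keep[(1L + m):(d[1] - m), (1L + m):(d[2] - m)] <- TRUE
    flag <- flag & keep
  }
  idx <- which(flag, arr.ind = TRUE)
  rep_frame <- if (config$frame_assign == "next") frame_n + 1L else frame_n
  t_ms <- phase_movie$t0_ms + (rep_frame - 1) * phase_movie$frame_interval_ms
  if (!nrow(idx))
    return(as_ps_set(empty_ps(), phase_movie$dx_mm, config))
  as_ps_set(ps_points(idx[, 1], idx[, 2], as.integer(rep_frame), t_ms,
                      phase_movie$dx_mm, NA_integer_, "location_centric"),
            phase_movie$dx_mm, config)
}

#' Detect phase singularities over a whole phase movie
#'
#' Maps the configured per-frame detector over all frames (Iyer-Gray) or
#' all consecutive frame pairs (location-centric) and pools the detections.
#'
#' @param phase_movie A `phase_movie`.
#' @param config A [detector_config()].
#' @return A `ps_set` data.frame over all frames, sorted by frame then
#'   row-major position.
#' @export
detect_movie <- function(phase_movie, config = detector_config("iyer_gray")) {
  stopifnot(inherits(phase_movie, "phase_movie"))
  d <- dim(phase_movie$frames)
  out <- vector("list", d[3])
  if (config$method == "iyer_gray") {
    for (i in seq_len(d[3]))
      out[[i]] <- detect_iyer_gray(phase_movie, config, frame = i)
  } else {
    for (i in seq_len(d[3] - 1L))
      out[[i]] <- detect_location_centric(phase_movie, i, config)
  }
  out <- out[!vapply(out, is.null, logical(1))]
  df <- do.call(rbind, c(list(empty_ps()), lapply(out, as.data.frame)))
  as_ps_set(df, phase_movie$dx_mm, config)
}

#' Reduce detection clusters to connected-component centroids
#'
#' Optional post-processing: both detectors report all flagged pixels, so a
#' single rotor can appear as a small cluster per frame. This reducer
#' replaces each 8-connected cluster within a frame by its centroid pixel.
#' Off by default everywhere.
#'
#' @param ps A `ps_set`.
#' @return A `ps_set` with one centroid point per (frame, cluster).
#' @export
reduce_clusters <- function(ps) {
  stopifnot(inherits(ps, "ps_set"))
  if (!nrow(ps)) return(ps)
  dx <- attr(ps, "dx_mm"); cfg <- attr(ps, "config")
  pieces <- lapply(split(seq_len(nrow(ps)), ps$frame), function(ii) {
    sub <- ps[ii, , drop = FALSE]
    n <- nrow(sub)
    comp <- seq_len(n)
    # union neighbors (Chebyshev distance <= 1)
    repeat {
      changed <- FALSE
      for (i in seq_len(n)) {
        nb <- which(abs(sub$row - sub$row[i]) <= 1 &
                    abs(sub$col - sub$col[i]) <= 1)
        mc <- min(comp[nb])
        if (any(comp[nb] != mc)) { comp[nb] <- mc; changed <- TRUE }
      }
      if (!changed) break
    }
    do.call(rbind, lapply(split(seq_len(n), comp), function(jj) {
      s <- sub[jj, , drop = FALSE]
      r <- as.integer(round(mean(s$row))); cc <- as.integer(round(mean(s$col)))
      data.frame(method = s$method[1], frame = s$frame[1], t_ms = s$t_ms[1],
                 row = r, col = cc,
                 x_mm = (cc - 1) * dx, y_mm = (r - 1) * dx,
                 chirality = if (all(s$chirality == s$chirality[1]))
                   s$chirality[1] else NA_integer_)
    }))
  })
  as_ps_set(do.call(rbind, pieces), dx, cfg)
}
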
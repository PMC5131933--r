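#' Write / read a voltage movie
#'
#' Movies are stored in the package's container format (R native
#' serialization, version 3): the frame array plus the mandatory metadata
#' `dx_mm` and `frame_interval_ms` and the provenance list. Reading a file
#' that lacks mandatory metadata is a hard error naming the missing field;
#' there are no silent defaults. `write_movie` then `read_movie` is the
#' identity on frames and metadata.
#'
#' @param movie A [voltage_movie()].
#' @param path Output file path (conventionally `.rds`).
#' @return `write_movie` returns `path` invisibly; `read_movie` returns a
#'   [voltage_movie()].
#' @export
write_movie <- function(movie, path) {
  stopifnot(inherits(movie, "voltage_movie"))
  obj <- list(container = "spiralps-movie", version = 1L,
              frames = movie$frames, dx_mm = movie$dx_mm,
              frame_interval_ms = movie$frame_interval_ms,
              t0_ms = movie$t0_ms, meta = movie$meta)
  saveRDS(obj, path, version = 3)
  invisible(path)
}

#' @rdname write_movie
#' @export
read_movie <- function(path) {
  obj <- readRDS(path)
  if (!is.list(obj) || !identical(obj$container, "spiralps-movie"))
    stop("not a spiralps movie container: ", path)
  for (field in c("frames", "dx_mm", "frame_interval_ms")) {
    if (is.null(obj[[field]]))
      stop("movie container is missing mandatory field '", field, "'")
  }
  voltage_movie(obj$frames, dx_mm = obj$dx_mm,
                frame_interval_ms = obj$frame_interval_ms,
                t0_ms = if (is.null(obj$t0_ms)) 0 else obj$t0_ms,
                meta = if (is.null(obj$meta)) list() else obj$meta)
}

#' Write / read a PS point set as CSV
#'
#' Plain-text interchange with columns
#' `method,frame,t_ms,row,col,x_mm,y_mm,chirality` (1-based row/col;
#' x = (col-1)*dx, y = (row-1)*dx, origin at the top-left pixel). The grid
#' spacing is kept in a `# dx_mm:` comment header so the set reads back
#' losslessly.
#'
#' @param ps A `ps_set`.
#' @param path CSV file path.
#' @return `write_ps_csv` returns `path` invisibly; `read_ps_csv` returns
#'   a `ps_set`.
#' @export
write_ps_csv <- function(ps, path) {
  stopifnot(inherits(ps, "ps_set"))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("# dx_mm: %.17g", attr(ps, "dx_mm")), con)
  write.csv(as.data.frame(ps), con, row.names = FALSE)
  invisible(path)
}

#' @rdname write_ps_csv
#' @export
read_ps_csv <- function(path) {
  hdr <- readLines(path, n = 1L)
  dx <- NA_real_
  if (startsWith(hdr, "# dx_mm:"))
    dx <- as.numeric(sub("# dx_mm:", "", hdr))
  df <- read.csv(path, comment.char = "#")
  df$method <- as.character(df$method)
  as_ps_set(df, dx, NULL)
}

#' Read / write a run configuration
#'
#' A YAML file bundling the simulation, phase, detector and comparison
#' settings of a full pipeline run. Round-trips losslessly. Unspecified
#' fields take the package defaults documented in [sim_config()],
#' [compute_phase()], [detector_config()] and [compare_methods()].
#'
#' @param path YAML file path.
#' @param config Named list as returned by `read_run_config`.
#' @return `read_run_config` returns the configuration list (class
#'   `run_config`); `write_run_config` returns `path` invisibly.
#' @export
read_run_config <- function(path) {
  cfg <- yaml::read_yaml(path)
  structure(cfg, class = "run_config")
}

#' @rdname read_run_config
#' @export
write_run_config <- function(config, path) {
  yaml::write_yaml(unclass(config), path, precision = 15)
  invisible(path)
}

# build a sim_config from a run_config list
sim_config_from_run <- function(cfg) {
  sim <- cfg$sim
  if (is.null(sim)) stop("run config has no 'sim' section")
  grid <- sim_grid(sim$grid$height_cells %||% 200L,
                   sim$grid$width_cells %||% 200L,
                   sim$grid$dx_mm %||% 0.25)
  scen <- if (is.null(sim$scenario)) scenario_config()
          else scenario_preset(sim$scenario)
  prot <- stim_protocol(
    s1_time_ms = sim$protocol$s1_time_ms %||% 0,
    s2_coupling_interval_ms = sim$protocol$s2_coupling_interval_ms %||% 300,
    amplitude = sim$protocol$amplitude %||% 25,
    duration_ms = sim$protocol$duration_ms %||% 2)
  sim_config(grid, duration_ms = sim$duration_ms %||% 1000,
             D_cm2_per_ms = sim$D_cm2_per_ms %||% 0.001,
             dt_min_ms = sim$dt_min_ms %||% 0.01,
             dt_max_ms = sim$dt_max_ms %||% 0.1,
             sample_interval_ms = sim$sample_interval_ms %||% 1,
             record_from_ms = sim$record_from_ms %||% 0,
             scenario = scen, protocol = prot)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
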
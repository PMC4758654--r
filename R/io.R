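#' Read a scenario configuration from a YAML file
#'
#' The file holds top-level keys matching the [scenario_config()] arguments
#' (`mode`, `R_t`, `seed`, `nx`, ...), plus optional `params:` and
#' `numerics:` mappings with named overrides of [model_parameters()] and
#' [numerics_options()]. Example configurations for all four modes ship in
#' `system.file("extdata", package = "angiophase")`.
#'
#' @param path Path to the YAML file.
#' @return A [scenario_config()] object.
#' @export
read_scenario_config <- function(path) {
  raw <- yaml::read_yaml(path)
  params <- do.call(model_parameters, raw$params %||% list())
  numerics <- do.call(numerics_options, raw$numerics %||% list())
  raw$params <- NULL
  raw$numerics <- NULL
  do.call(scenario_config, c(raw, list(params = params, numerics = numerics)))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Write a scenario configuration to YAML
#'
#' Only scalar scenario fields and any parameter values differing from the
#' defaults are written, so the file stays readable.
#'
#' @param config A [scenario_config()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_scenario_config <- function(config, path) {
  out <- unclass(config)
  defaults <- model_parameters()
  devs <- Filter(Negate(is.null), lapply(names(defaults), function(n) {
    if (!identical(config$params[[n]], defaults[[n]])) config$params[[n]]
  }))
  names(devs) <- names(defaults)[!vapply(names(defaults), function(n)
    identical(config$params[[n]], defaults[[n]]), logical(1))]
  out$params <- if (length(devs)) devs else NULL
  ndef <- numerics_options()
  ndevs <- names(ndef)[!vapply(names(ndef), function(n)
    identical(config$numerics[[n]], ndef[[n]]), logical(1))]
  out$numerics <- if (length(ndevs)) config$numerics[ndevs] else NULL
  out <- Filter(Negate(is.null), out)
  if (length(out$snapshot_days) == 0) out$snapshot_days <- NULL
  yaml::write_yaml(out, path)
  invisible(path)
}

#' Write the outputs of a run
#'
#' Produces, under `outdir`: `series.csv` (one row per observable record),
#' `events.csv` (the TEC event log), `network.csv` (segment table),
#' `manifest.yaml` (config, seed, grid, package version), and one legacy
#' ASCII VTK image-data file per stored snapshot plus the final state
#' (`phi`, `sigma`, `c`, `f` as point scalars), readable by standard
#' viewers.
#'
#' @param run An `angio_run` from [run_scenario()].
#' @param outdir Output directory (created if missing).
#' @return Character vector of the files written, invisibly.
#' @export
write_outputs <- function(run, outdir) {
  dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
  if (file.access(outdir, 2) != 0) stop("output dir not writable: ", outdir)
  files <- character(0)
  fp <- function(x) file.path(outdir, x)
  # 17 significant digits so numeric columns round-trip exactly through text
  fmt <- run$series
  for (nm in names(fmt))
    if (is.double(fmt[[nm]])) {
      v <- sprintf("%.17g", fmt[[nm]])
      plain <- !grepl("[.eE]|Inf|NaN|NA", v)
      v[plain] <- paste0(v[plain], ".0")  # keep double typing on re-read
      fmt[[nm]] <- v
    }
  utils::write.csv(fmt, fp("series.csv"), row.names = FALSE, quote = FALSE)
  files <- c(files, fp("series.csv"))
  ev <- run$events
  if (nrow(ev) == 0)
    ev <- data.frame(t = numeric(0), t_days = numeric(0),
                     event = character(0), tec_id = integer(0),
                     x = numeric(0), y = numeric(0))
  utils::write.csv(ev, fp("events.csv"), row.names = FALSE)
  utils::write.csv(run$network$segments, fp("network.csv"), row.names = FALSE)
  files <- c(files, fp("events.csv"), fp("network.csv"))
  manifest <- list(
    mode = run$config$mode, seed = run$config$seed,
    t_end_days = run$config$t_end_days,
    grid = list(nx = run$grid$nx, ny = run$grid$ny,
                width = run$grid$width, height = run$grid$height),
    area_threshold = run$config$area_threshold,
    delta4 = run$params$delta4, n_steps = run$n_steps,
    package = "angiophase",
    version = as.character(utils::packageVersion("angiophase")))
  yaml::write_yaml(manifest, fp("manifest.yaml"))
  files <- c(files, fp("manifest.yaml"))
  snaps <- c(run$snapshots, list(run$state))
  for (s in snaps) {
    f <- fp(sprintf("snapshot_t%09.2f.vtk", s$t))
    write_vtk_image(s, run$grid, f)
    files <- c(files, f)
  }
  invisible(files)
}

#' Write a field snapshot as a legacy ASCII VTK image-data file
#'
#' @param state A [field_state()].
#' @param grid The [sim_grid()].
#' @param path Output path (`.vtk`).
#' @return `path`, invisibly.
#' @export
write_vtk_image <- function(state, grid, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c("# vtk DataFile Version 3.0",
               sprintf("angiophase fields at t = %.6g", state$t),
               "ASCII",
               "DATASET STRUCTURED_POINTS",
               sprintf("DIMENSIONS %d %d 1", grid$nx, grid$ny),
               sprintf("ORIGIN %g %g 0", grid$dx / 2, grid$dy / 2),
               sprintf("SPACING %g %g 1", grid$dx, grid$dy),
               sprintf("POINT_DATA %d", grid$nx * grid$ny)), con)
  for (nm in c("phi", "sigma", "c", "f")) {
    writeLines(c(sprintf("SCALARS %s double 1", nm),
                 "LOOKUP_TABLE default"), con)
    # column-major vector = x-fastest ordering, as VTK expects
    writeLines(formatC(as.vector(state[[nm]]), format = "g", digits = 9), con)
  }
  invisible(path)
}

#' Read back a time-series CSV
#'
#' Inverse of the `series.csv` part of [write_outputs()].
#'
#' @param path Path to `series.csv`.
#' @return Data frame of observable records.
#' @export
read_series <- function(path) {
  utils::read.csv(path, stringsAsFactors = FALSE)
}
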
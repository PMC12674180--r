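#' Assemble a pipeline configuration
#'
#' A plain nested list (YAML round-trippable) describing every stage of the
#' end-to-end simulation: synthetic flow -> tracking -> transmit simulation
#' -> beamforming -> Doppler -> vector flow. Every run writes the resolved
#' configuration beside its outputs so results are reproducible from the
#' single `rng_seed`.
#'
#' @param flow Arguments for [synthetic_field_spec()].
#' @param tracking Tracker settings: concentration, wavelength,
#'   elevation_half_width, substeps, stagnation (v_threshold,
#'   d_threshold_factor), zones (list of list(name, box)), probes (named
#'   list of length-6 boxes). The tracking step dt is tied to the transmit
#'   PRF (one advection per transmit) unless `dt` is given explicitly.
#' @param array Arguments for [linear_array()].
#' @param scheme Arguments for [plane_wave_scheme()].
#' @param image Arguments for [image_grid()] (x_range, z_range, pixel).
#' @param doppler Arguments for [doppler_config()].
#' @param vectorflow List with `threshold_db`.
#' @param scene_offset Translation c(dx, dy, dz) \[mm\] applied to the
#'   tracked scatterers before the ultrasound stage, placing the flow
#'   geometry at the imaging depth (the flow generators use geometry-local
#'   coordinates).
#' @param n_transmits Number of transmits to simulate.
#' @param rng_seed Global seed.
#' @return An object of class `pipeline_config`.
#' @export
pipeline_config <- function(flow = list(), tracking = list(),
                            array = list(), scheme = list(),
                            image = list(), doppler = list(),
                            vectorflow = list(threshold_db = -30),
                            scene_offset = c(0, 0, 0),
                            n_transmits = 96, rng_seed = 1L) {
  structure(list(flow = flow, tracking = tracking, array = array,
                 scheme = scheme, image = image, doppler = doppler,
                 vectorflow = vectorflow, scene_offset = scene_offset,
                 n_transmits = as.integer(n_transmits),
                 rng_seed = as.integer(rng_seed)),
            class = "pipeline_config")
}

#' Demo pipeline configuration
#'
#' A small straight-pipe case sized to run end to end in well under five
#' minutes on one CPU: a 4 mm pipe, 0.25 pts/lambda^3, three angles at
#' 30 kHz, 96 transmits (32 compounded frames).
#'
#' @param n_transmits Number of transmits.
#' @param rng_seed Seed.
#' @return A `pipeline_config`.
#' @export
demo_pipeline_config <- function(n_transmits = 96, rng_seed = 1L) {
  pipeline_config(
    flow = list(kind = "pulsatile_pipe", peak_speed = 150,
                cycle_period = 100, frame_step = 2, spacing = 0.1,
                geometry = list(radius = 0.5, length = 4)),
    tracking = list(
      concentration = 0.25, wavelength = 0.1,
      elevation_half_width = 0.25,
      stagnation = list(v_threshold = 1, d_threshold_factor = 2),
      zones = list(list(name = "inlet", box = c(0, 0.5, -1, 1, -1, 1)),
                   list(name = "outlet", box = c(3.5, 4, -1, 1, -1, 1))),
      probes = list(centre = c(2, 0, 0) |> probe_box())),
    array = list(n_elements = 96, pitch = 0.1, center_frequency = 15,
                 fractional_bandwidth = 0.6, sound_speed = 1540),
    scheme = list(angles = c(-10, 0, 10), prf = 30),
    image = list(x_range = c(-1.5, 1.5), z_range = c(8, 10),
                 pixel = c(50, 50)),
    doppler = list(wall_cutoff = 0.1, window = 16, shift = 4, nfft = 64),
    vectorflow = list(threshold_db = -30),
    scene_offset = c(-2, 0, 9),
    n_transmits = n_transmits, rng_seed = rng_seed)
}

#' Read / write a pipeline configuration
#'
#' YAML serialization; `read_pipeline_config(write_pipeline_config(x))`
#' round-trips losslessly.
#'
#' @param config A `pipeline_config`.
#' @param path YAML file path.
#' @return The config (read) or `path` invisibly (write).
#' @export
write_pipeline_config <- function(config, path) {
  yaml::write_yaml(unclass(config), path)
  invisible(path)
}

#' @rdname write_pipeline_config
#' @export
read_pipeline_config <- function(path) {
  obj <- yaml::read_yaml(path)
  do.call(pipeline_config, obj[intersect(names(obj),
                                         names(formals(pipeline_config)))])
}

#' Validate a pipeline configuration
#'
#' Cross-module consistency checks. Error-level findings stop
#' [run_pipeline()]; warnings are informative. In particular a seeding
#' concentration below 0.23 pts/lambda^3 is flagged because it yields
#' fewer than 10 scatterers per 4 x 5.3 x 2 lambda resolution cell —
#' below the accepted floor for fully developed speckle.
#'
#' @param config A `pipeline_config`.
#' @return A tibble report with columns `level` ("error"/"warning") and
#'   `message`; zero rows when the config is fully consistent.
#' @export
validate_config <- function(config) {
  rows <- list()
  add <- function(level, msg) rows[[length(rows) + 1]] <<-
    tibble(level = level, message = msg)
  fl <- config$flow
  if (!is.null(fl$cycle_period) && !is.null(fl$frame_step)) {
    r <- fl$cycle_period / fl$frame_step
    if (abs(r - round(r)) > 1e-9)
      add("error", "flow frame_step does not divide cycle_period")
  }
  tr <- config$tracking
  sc <- do.call(plane_wave_scheme, config$scheme)
  if (!is.null(tr$dt)) {
    dt_prf <- 1 / sc$prf
    if (abs(tr$dt - dt_prf) > 1e-9 * dt_prf)
      add("error", sprintf(
        "tracking dt (%g ms) is inconsistent with the transmit PRF (1/%g kHz = %g ms)",
        tr$dt, sc$prf, dt_prf))
  }
  conc <- if (is.null(tr$concentration)) 0.25 else tr$concentration
  per_cell <- scatterers_per_resolution_cell(conc)
  if (per_cell < 10)
    add("warning", sprintf(
      paste0("concentration %.3g pts/lambda^3 gives %.1f scatterers per ",
             "4 x 5.3 x 2 lambda resolution cell; >= 10 per cell ",
             "(>= 0.23 pts/lambda^3) is needed for fully developed speckle"),
      conc, per_cell))
  ar <- do.call(linear_array, config$array)
  ehw <- if (is.null(tr$elevation_half_width)) 0.25 else tr$elevation_half_width
  if (ehw <= 0) add("error", "elevation_half_width must be > 0")
  if (ehw > 10 * ar$wavelength)
    add("warning", sprintf(
      "elevation half-width %g mm is much wider than the elevation cell (~5.3 lambda = %.2f mm)",
      ehw, 5.3 * ar$wavelength))
  dp <- tryCatch(do.call(doppler_config, config$doppler),
                 error = function(e) {
                   add("error", sprintf("doppler config invalid: %s",
                                        conditionMessage(e)))
                   NULL
                 })
  n_frames <- config$n_transmits %/% sc$n_angles
  if (!is.null(dp) && dp$window > n_frames)
    add("error", sprintf(
      "Doppler window (%d) exceeds the number of compounded frames (%d)",
      dp$window, n_frames))
  if (length(rows) == 0)
    tibble(level = character(), message = character())
  else bind_rows(rows)
}

#' Run the end-to-end pipeline
#'
#' Executes all stages in order and writes each stage's artifact to
#' `out_dir` (flow grid, tracking run + concentration CSV, beamformed IQ
#' cube, Doppler map, vector-flow field) plus the resolved configuration
#' as YAML. Identical config + seed give bit-identical outputs. Existing
#' stage artifacts are reused unless `overwrite = TRUE`, so interrupted
#' runs are resumable.
#'
#' @param config A `pipeline_config`.
#' @param out_dir Output directory (created if needed).
#' @param seed Optional seed override.
#' @param overwrite Recompute stages whose artifact already exists.
#' @param quiet Suppress per-stage messages.
#' @return Invisibly, a named list of artifact paths.
#' @export
run_pipeline <- function(config, out_dir, seed = NULL, overwrite = FALSE,
                         quiet = FALSE) {
  stopifnot(inherits(config, "pipeline_config"))
  if (!is.null(seed)) config$rng_seed <- as.integer(seed)
  report <- validate_config(config)
  if (any(report$level == "error"))
    abort(paste0("invalid pipeline config:\n  ",
                 paste(report$message[report$level == "error"],
                       collapse = "\n  ")))
  for (msg in report$message[report$level == "warning"]) warn(msg)
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  paths <- list(config = file.path(out_dir, "config_resolved.yaml"),
                flow = file.path(out_dir, "flow_grid.rds"),
                tracking = file.path(out_dir, "tracking.rds"),
                concentration = file.path(out_dir, "concentration.csv"),
                iq = file.path(out_dir, "iq_cube.rds"),
                doppler = file.path(out_dir, "doppler_map.rds"),
                vectorflow = file.path(out_dir, "vector_flow.rds"))
  write_pipeline_config(config, paths$config)
  say <- function(stage, fmt, ...) {
    if (!quiet) message(sprintf("[%s] %s", stage, sprintf(fmt, ...)))
  }
  stage <- function(name, path, compute) {
    if (file.exists(path) && !overwrite) {
      say(name, "reusing %s", basename(path))
      return(readRDS(path))
    }
    t0 <- Sys.time()
    out <- tryCatch(compute(), error = function(e)
      abort(sprintf("stage '%s' failed: %s", name, conditionMessage(e))))
    saveRDS(out, path)
    say(name, "done in %.1f s", as.numeric(Sys.time() - t0, units = "secs"))
    out
  }
  grid <- stage("synth-flow", paths$flow, function() {
    spec <- do.call(synthetic_field_spec, config$flow)
    make_field(spec)
  })
  scheme <- do.call(plane_wave_scheme, config$scheme)
  track <- stage("track", paths$tracking, function() {
    tr <- config$tracking
    zones <- lapply(tr$zones, function(z) refresh_zone(z$box, z$name))
    stag <- do.call(stagnation_policy,
                    if (is.null(tr$stagnation)) list() else tr$stagnation)
    tc <- tracker_config(
      concentration = tr$concentration %||% 0.25,
      wavelength = tr$wavelength %||% 0.1,
      dt = tr$dt %||% (1 / scheme$prf),
      substeps = tr$substeps %||% 1L,
      elevation_half_width = tr$elevation_half_width %||% 0.25,
      rng_seed = config$rng_seed,
      zones = zones, stagnation = stag,
      probes = tr$probes %||% list())
    run_tracking(grid, tc, config$n_transmits, keep = "sliced")
  })
  log <- tidy(track)
  write.csv(log, paths$concentration, row.names = FALSE)
  say("track", "%d transmits, %d scatterers tracked / %d passed on",
      config$n_transmits, track$counts$n_tracked[nrow(track$counts)],
      track$counts$n_sliced[nrow(track$counts)])
  arr <- do.call(linear_array, config$array)
  img <- do.call(image_grid, config$image)
  iq <- stage("simulate+beamform", paths$iq, function() {
    off <- config$scene_offset %||% c(0, 0, 0)
    sets <- lapply(track$sliced[-1], function(s) {   # post-advance states
      s$x <- s$x + off[1]; s$y <- s$y + off[2]; s$z <- s$z + off[3]
      s
    })
    beamform_sequence(sets, arr, scheme, img)
  })
  dconf <- do.call(doppler_config, config$doppler)
  dmap <- stage("doppler", paths$doppler, function()
    doppler_map(iq, dconf))
  vf <- stage("vectorflow", paths$vectorflow, function()
    estimate_vector_flow(iq, dconf,
                         threshold_db =
                           config$vectorflow$threshold_db %||% -30))
  invisible(c(paths, list(artifacts = list(grid = grid, tracking = track,
                                           iq = iq, doppler = dmap,
                                           vectorflow = vf))))
}

`%||%` <- function(a, b) if (is.null(a)) b else a
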
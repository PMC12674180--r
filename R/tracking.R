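#' Refresh zone at a flow port
#'
#' An axis-aligned box at a flow inlet or outlet. Its scatterers are deleted
#' and randomly re-drawn every tracking step, acting as a particle source
#' and sink while preserving slow-time speckle continuity elsewhere. Boxes
#' are closed: boundary points belong to the zone.
#'
#' @param box Numeric length 6: c(xmin, xmax, ymin, ymax, zmin, zmax) \[mm\].
#' @param name Optional label.
#' @return An object of class `refresh_zone`.
#' @export
refresh_zone <- function(box, name = NULL) {
  box <- as.numeric(box)
  if (length(box) != 6) abort("box must be c(xmin,xmax,ymin,ymax,zmin,zmax)")
  if (any(box[c(2, 4, 6)] < box[c(1, 3, 5)])) abort("box limits reversed")
  structure(list(box = box, name = name), class = "refresh_zone")
}

in_box <- function(pos, box) {
  pos[, 1] >= box[1] & pos[, 1] <= box[2] &
  pos[, 2] >= box[3] & pos[, 2] <= box[4] &
  pos[, 3] >= box[5] & pos[, 3] <= box[6]
}

zone_flow_nodes <- function(zone, grid) {
  fc <- grid_node_coords(grid, "flow")
  which(in_box(fc, zone$box))
}

#' Flow volume inside a refresh zone
#'
#' The flow region is the union of the d-cells (cubes of edge d centred on
#' flow nodes, i.e. the lattice Voronoi cells); the zone flow volume is the
#' exact overlap of those cells with the zone box. This matches the
#' acceptance region of the rejection sampler used for repopulation, so a
#' repopulated zone holds exactly the configured concentration.
#'
#' @param zone A [refresh_zone()].
#' @param grid A [flow_grid()].
#' @return Volume \[mm^3\].
#' @export
zone_flow_volume <- function(zone, grid) {
  fc <- grid_node_coords(grid, "flow")
  h <- grid$spacing / 2
  b <- zone$box
  ov <- function(lo, hi, blo, bhi) pmax(0, pmin(hi, bhi) - pmax(lo, blo))
  sum(ov(fc[, 1] - h, fc[, 1] + h, b[1], b[2]) *
      ov(fc[, 2] - h, fc[, 2] + h, b[3], b[4]) *
      ov(fc[, 3] - h, fc[, 3] + h, b[5], b[6]))
}

#' Stagnation pruning policy
#'
#' A scatterer is stagnant, and removed, when its speed is below
#' `v_threshold` AND its distance to the nearest null (non-flow) grid node
#' is below `d_threshold_factor * d`. The defaults, 1 mm/s and 2d, keep the
#' local concentration stable while restricting removal to the edge of the
#' flow.
#'
#' @param v_threshold Speed threshold \[mm/s\].
#' @param d_threshold_factor Distance threshold as a multiple of the grid
#'   spacing d.
#' @return An object of class `stagnation_policy`.
#' @export
stagnation_policy <- function(v_threshold = 1, d_threshold_factor = 2) {
  if (v_threshold < 0) abort("v_threshold must be >= 0")
  if (d_threshold_factor <= 0) abort("d_threshold_factor must be > 0")
  structure(list(v_threshold = v_threshold,
                 d_threshold_factor = d_threshold_factor),
            class = "stagnation_policy")
}

#' Probe box for concentration monitoring
#'
#' @param center Box centre \[mm\].
#' @param size_lambda Box edge lengths in wavelengths (default 10x10x10).
#' @param wavelength Wavelength \[mm\].
#' @return Numeric length 6 box (c(xmin,xmax,ymin,ymax,zmin,zmax)).
#' @export
probe_box <- function(center, size_lambda = c(10, 10, 10), wavelength = 0.1) {
  h <- size_lambda * wavelength / 2
  c(center[1] - h[1], center[1] + h[1],
    center[2] - h[2], center[2] + h[2],
    center[3] - h[3], center[3] + h[3])
}

#' Tracker configuration
#'
#' @param concentration Seeding concentration \[pts/lambda^3\].
#' @param wavelength Wavelength lambda \[mm\].
#' @param dt Simulation time step \[ms\] (one advection per ultrasound
#'   transmit in the full pipeline).
#' @param substeps Intermediate advection steps per emitted frame (>= 1);
#'   each substep runs the full advance/purge/prune/repopulate cycle at
#'   dt/substeps.
#' @param elevation_half_width Half-width of the elevation slice passed to
#'   the ultrasound simulator \[mm\] (|y| < half-width).
#' @param rng_seed Integer seed; the tracker owns one RNG stream so runs
#'   are reproducible from this single seed.
#' @param zones List of [refresh_zone()]s.
#' @param stagnation A [stagnation_policy()].
#' @param probes Named list of probe boxes (see [probe_box()]).
#' @return An object of class `tracker_config`.
#' @export
tracker_config <- function(concentration = 0.25, wavelength = 0.1,
                           dt = 0.5, substeps = 1L,
                           elevation_half_width = 0.25, rng_seed = 1L,
                           zones = list(), stagnation = stagnation_policy(),
                           probes = list()) {
  if (dt <= 0) abort("dt must be > 0")
  if (concentration < 0) abort("concentration must be >= 0")
  if (wavelength <= 0) abort("wavelength must be > 0")
  substeps <- as.integer(substeps)
  if (substeps < 1) abort("substeps must be >= 1")
  if (length(zones) > 0 && inherits(zones, "refresh_zone"))
    zones <- list(zones)
  structure(list(concentration = concentration, wavelength = wavelength,
                 dt = dt, substeps = substeps,
                 elevation_half_width = elevation_half_width,
                 rng_seed = as.integer(rng_seed), zones = zones,
                 stagnation = stagnation, probes = probes),
            class = "tracker_config")
}

new_scatterer_set <- function(pos, amp, ids) {
  out <- tibble(id = as.integer(ids),
                x = pos[, 1], y = pos[, 2], z = pos[, 3],
                amp = amp)
  class(out) <- c("scatterer_set", class(out))
  out
}

scatterer_pos <- function(s) cbind(s$x, s$y, s$z)

as_velocity_matrix <- function(v, n) {
  if (is.data.frame(v)) v <- cbind(v$vx, v$vy, v$vz)
  v <- as.matrix(v)
  if (nrow(v) != n) abort("velocities are not aligned with the scatterers")
  v
}

#' Seed scatterers uniformly in the flow region
#'
#' Draws scatterers uniformly at random in the bounding box of the flow
#' region, then removes those that fall in the null region (nearest grid
#' node outside the flow mask). Each scatterer carries a standard-normal
#' (Gaussian-weighted) scattering amplitude and a stable integer id. The
#' expected surviving count is `concentration * flow volume / lambda^3`.
#'
#' @param grid A [flow_grid()].
#' @param config A [tracker_config()].
#' @return A `scatterer_set` tibble with columns id, x, y, z, amp.
#' @export
seed_scatterers <- function(grid, config) {
  if (sum(grid$flow_mask) == 0) abort("zero flow volume")
  bb <- flow_bbox(grid)
  vol_lambda <- prod(bb["hi", ] - bb["lo", ]) / config$wavelength^3
  n_draw <- round(config$concentration * vol_lambda)
  if (n_draw == 0) return(new_scatterer_set(matrix(0, 0, 3), numeric(0),
                                            integer(0)))
  pos <- cbind(runif(n_draw, bb["lo", 1], bb["hi", 1]),
               runif(n_draw, bb["lo", 2], bb["hi", 2]),
               runif(n_draw, bb["lo", 3], bb["hi", 3]))
  keep <- in_flow_region(grid, pos)
  pos <- pos[keep, , drop = FALSE]
  new_scatterer_set(pos, rnorm(nrow(pos)), seq_len(nrow(pos)))
}

#' Is a point in the flow region?
#'
#' A point is in the flow region when its nearest grid node is flow-masked
#' (and it lies inside the grid bounding box).
#'
#' @param grid A [flow_grid()].
#' @param pos Matrix (n x 3) \[mm\].
#' @return Logical vector.
#' @export
in_flow_region <- function(grid, pos) {
  nx <- length(grid$x); ny <- length(grid$y); nz <- length(grid$z)
  ix <- round((pos[, 1] - grid$x[1]) / grid$spacing)
  iy <- round((pos[, 2] - grid$y[1]) / grid$spacing)
  iz <- round((pos[, 3] - grid$z[1]) / grid$spacing)
  inside <- ix >= 0 & ix <= nx - 1 & iy >= 0 & iy <= ny - 1 &
            iz >= 0 & iz <= nz - 1
  out <- logical(nrow(pos))
  idx <- 1 + ix[inside] + nx * (iy[inside] + ny * iz[inside])
  out[inside] <- grid$flow_mask[idx]
  out
}

#' Sample the flow-field velocity at scatterer positions
#'
#' Trilinear spatial interpolation of the two bracketing frames followed by
#' a linear temporal blend. For a periodic grid, `t` is first rolled over
#' modulo the cycle period (so the simulation can run an arbitrary number
#' of cardiac cycles over a single-cycle field). Scatterers outside the
#' grid bounding box get zero velocity and are flagged for removal via the
#' `"inside"` attribute.
#'
#' @param scatterers A `scatterer_set` (or an (n x 3) position matrix).
#' @param grid A [flow_grid()].
#' @param t Time \[ms\].
#' @return Matrix (n x 3) of velocities \[mm/s\] with attribute `inside`.
#' @export
sample_velocity <- function(scatterers, grid, t) {
  pos <- if (is.data.frame(scatterers)) scatterer_pos(scatterers)
         else as.matrix(scatterers)
  br <- bracket_frames(grid, t)
  res <- .cpp_sample_trilinear(
    grid$v, length(grid$x), length(grid$y), length(grid$z),
    grid$x[1], grid$y[1], grid$z[1], grid$spacing,
    pos, br$f0 - 1L, br$f1 - 1L, br$alpha)
  v <- res$v
  colnames(v) <- c("vx", "vy", "vz")
  attr(v, "inside") <- res$inside
  v
}

bracket_frames <- function(grid, t) {
  ft <- grid$frame_times
  n <- length(ft)
  if (grid$periodic) {
    tr <- (t - ft[1]) %% grid$cycle_period + ft[1]
    step <- grid$cycle_period / n
    f0 <- floor((tr - ft[1]) / step)
    alpha <- (tr - ft[1]) / step - f0
    f0 <- as.integer(f0) + 1L
    f1 <- if (f0 == n) 1L else f0 + 1L
    if (f0 > n) { f0 <- 1L; f1 <- if (n > 1) 2L else 1L; alpha <- 0 }
  } else {
    if (t < ft[1] || t > ft[n]) abort("t outside the frame-time span")
    f0 <- max(1L, min(n - 1L, findInterval(t, ft)))
    f1 <- f0 + 1L
    alpha <- (t - ft[f0]) / (ft[f1] - ft[f0])
    if (n == 1) { f1 <- 1L; alpha <- 0 }
  }
  list(f0 = f0, f1 = f1, alpha = alpha)
}

#' Advance scatterers one explicit-Euler step
#'
#' position(n+1) = position(n) + v * dt; ids and amplitudes are preserved.
#'
#' @param scatterers A `scatterer_set`.
#' @param velocities Matrix (n x 3) \[mm/s\] aligned with `scatterers`.
#' @param dt Time step \[ms\].
#' @return The displaced `scatterer_set`.
#' @export
advance <- function(scatterers, velocities, dt) {
  v <- as_velocity_matrix(velocities, nrow(scatterers))
  scatterers$x <- scatterers$x + v[, 1] * dt * 1e-3
  scatterers$y <- scatterers$y + v[, 2] * dt * 1e-3
  scatterers$z <- scatterers$z + v[, 3] * dt * 1e-3
  scatterers
}

#' Remove all scatterers inside the refresh zones
#'
#' Zone boxes are closed, so a scatterer exactly on a zone boundary is
#' removed.
#'
#' @param scatterers A `scatterer_set`.
#' @param zones List of [refresh_zone()]s.
#' @return The purged `scatterer_set`.
#' @export
purge_refresh_zones <- function(scatterers, zones) {
  if (length(zones) == 0 || nrow(scatterers) == 0) return(scatterers)
  pos <- scatterer_pos(scatterers)
  drop <- Reduce(`|`, lapply(zones, function(z) in_box(pos, z$box)))
  scatterers[!drop, ]
}

#' Remove stagnant scatterers at the edge of the flow
#'
#' Removes exactly those scatterers whose speed is below the policy's
#' velocity threshold AND whose distance to the nearest null grid node is
#' below `d_threshold_factor * d`. Momentarily slow scatterers in the core
#' of a pulsatile flow are thereby retained.
#'
#' @param scatterers A `scatterer_set`.
#' @param velocities Matrix (n x 3) \[mm/s\] aligned with `scatterers`.
#' @param grid A [flow_grid()] (provides the null node set).
#' @param policy A [stagnation_policy()].
#' @return The pruned `scatterer_set`.
#' @export
remove_stagnant <- function(scatterers, velocities, grid,
                            policy = stagnation_policy()) {
  n <- nrow(scatterers)
  if (n == 0) return(scatterers)
  v <- as_velocity_matrix(velocities, n)
  speed <- sqrt(rowSums(v^2))
  cand <- which(speed < policy$v_threshold)
  if (length(cand) == 0) return(scatterers)
  null_coords <- grid_node_coords(grid, "null")
  if (nrow(null_coords) == 0) return(scatterers)
  d_near <- .cpp_nn_dist(scatterer_pos(scatterers)[cand, , drop = FALSE],
                         null_coords, cell = grid$spacing)
  drop <- cand[d_near < policy$d_threshold_factor * grid$spacing]
  if (length(drop) == 0) return(scatterers)
  scatterers[-drop, ]
}

#' Randomly repopulate the refresh zones
#'
#' For each zone, draws `round(concentration * zone flow volume / lambda^3)`
#' fresh scatterers uniformly within the zone's flow-mask region (rejection
#' sampling against the flow mask), with fresh standard-normal amplitudes
#' and fresh ids. Randomness comes from the session RNG stream, so
#' repopulation differs every step; re-running from the same RNG state
#' reproduces the same points.
#'
#' @param scatterers A `scatterer_set` (zone points already purged).
#' @param zones List of [refresh_zone()]s.
#' @param grid A [flow_grid()].
#' @param config A [tracker_config()].
#' @return The `scatterer_set` with fresh zone scatterers appended.
#' @export
repopulate_refresh_zones <- function(scatterers, zones, grid, config) {
  if (length(zones) == 0) return(scatterers)
  next_id <- if (nrow(scatterers) > 0) max(scatterers$id) + 1L else 1L
  for (zone in zones) {
    zone_vol <- zone_flow_volume(zone, grid)
    n_new <- round(config$concentration * zone_vol / config$wavelength^3)
    if (zone_vol == 0) {
      warn(sprintf("refresh zone%s has zero flow volume; skipped",
                   if (is.null(zone$name)) "" else paste0(" '", zone$name, "'")))
      next
    }
    if (n_new < 1) {
      warn(sprintf("refresh zone%s expects < 1 scatterer",
                   if (is.null(zone$name)) "" else paste0(" '", zone$name, "'")))
      next
    }
    acc <- matrix(0, 0, 3)
    tries <- 0L
    while (nrow(acc) < n_new && tries < 200L) {
      m <- max(16L, 2L * (n_new - nrow(acc)))
      cand <- cbind(runif(m, zone$box[1], zone$box[2]),
                    runif(m, zone$box[3], zone$box[4]),
                    runif(m, zone$box[5], zone$box[6]))
      cand <- cand[in_flow_region(grid, cand), , drop = FALSE]
      acc <- rbind(acc, cand)
      tries <- tries + 1L
    }
    acc <- acc[seq_len(min(n_new, nrow(acc))), , drop = FALSE]
    fresh <- new_scatterer_set(acc, rnorm(nrow(acc)),
                               next_id + seq_len(nrow(acc)) - 1L)
    next_id <- next_id + nrow(acc)
    scatterers <- bind_rows(scatterers, fresh)
    class(scatterers) <- unique(c("scatterer_set", class(scatterers)))
  }
  scatterers
}

#' Elevation slice for the ultrasound simulator
#'
#' Returns the scatterers with |y| < `half_width` (the imaging plane is
#' y = 0). Scatterers outside the slice contribute little backscatter and
#' are skipped by the simulator; the full set is untouched and keeps being
#' tracked.
#'
#' @param scatterers A `scatterer_set`.
#' @param half_width Elevation half-width \[mm\] (default 0.25).
#' @return The sliced `scatterer_set`.
#' @export
elevation_slice <- function(scatterers, half_width = 0.25) {
  scatterers[abs(scatterers$y) < half_width, ]
}

#' Local scatterer concentration in a probe box
#'
#' @param scatterers A `scatterer_set`.
#' @param box Probe box (length-6 numeric, see [probe_box()]).
#' @param wavelength Wavelength \[mm\].
#' @return Concentration \[pts/lambda^3\].
#' @export
measure_concentration <- function(scatterers, box, wavelength = 0.1) {
  vol_lambda <- prod(box[c(2, 4, 6)] - box[c(1, 3, 5)]) / wavelength^3
  if (vol_lambda <= 0) abort("probe box has zero volume")
  if (nrow(scatterers) == 0) return(0)
  sum(in_box(scatterer_pos(scatterers), box)) / vol_lambda
}

#' Run the continuous tracking loop
#'
#' Executes the per-step sequence: sample velocity (with cycle rollover) ->
#' explicit-Euler advance -> purge refresh zones (and any scatterer that
#' escaped the grid bounding box) -> remove stagnant scatterers -> slice
#' the elevation for the ultrasound simulator -> randomly repopulate the
#' refresh zones. Probe concentrations and tracked/sliced counts are logged
#' each step. Fully deterministic given `config$rng_seed`.
#'
#' @param grid A [flow_grid()].
#' @param config A [tracker_config()].
#' @param n_steps Number of steps (of `config$dt` ms each). With
#'   `n_steps = 0` only the seeded state is emitted.
#' @param keep Which per-step scatterer sets to retain: "sliced" (default;
#'   what the ultrasound simulator consumes), "full", "both", or "none".
#' @param t_start Simulation start time \[ms\].
#' @return An object of class `tracking_run` with elements `log` (tibble:
#'   step, time_ms, probe, concentration), `counts` (tibble: step, time_ms,
#'   n_tracked, n_sliced), `final`, and (per `keep`) `sliced` / `full`
#'   lists of per-step scatterer sets.
#' @export
run_tracking <- function(grid, config, n_steps,
                         keep = c("sliced", "full", "both", "none"),
                         t_start = 0) {
  keep <- match.arg(keep)
  stopifnot(inherits(grid, "flow_grid"), inherits(config, "tracker_config"))
  old_seed <- get0(".Random.seed", envir = globalenv())
  on.exit(if (!is.null(old_seed)) assign(".Random.seed", old_seed,
                                         envir = globalenv()))
  set.seed(config$rng_seed)
  s <- seed_scatterers(grid, config)
  bb <- grid_bbox(grid)
  probes <- config$probes
  if (length(probes) > 0 && is.null(names(probes)))
    names(probes) <- paste0("probe", seq_along(probes))
  log_rows <- vector("list", n_steps + 1)
  count_rows <- vector("list", n_steps + 1)
  sliced_sets <- if (keep %in% c("sliced", "both")) vector("list", n_steps + 1)
  full_sets <- if (keep %in% c("full", "both")) vector("list", n_steps + 1)
  emit <- function(step, t, full, sliced) {
    i <- step + 1
    if (length(probes) > 0)
      log_rows[[i]] <<- tibble(
        step = step, time_ms = t, probe = names(probes),
        concentration = map_dbl(probes, measure_concentration,
                                scatterers = full,
                                wavelength = config$wavelength))
    count_rows[[i]] <<- tibble(step = step, time_ms = t,
                               n_tracked = nrow(full),
                               n_sliced = nrow(sliced))
    if (!is.null(sliced_sets)) sliced_sets[[i]] <<- sliced
    if (!is.null(full_sets)) full_sets[[i]] <<- full
  }
  t <- t_start
  emit(0L, t, s, elevation_slice(s, config$elevation_half_width))
  dt_sub <- config$dt / config$substeps
  if (n_steps > 0) for (step in seq_len(n_steps)) {
    for (sub in seq_len(config$substeps)) {
      v <- sample_velocity(s, grid, t)
      s <- advance(s, v, dt_sub)
      t <- t + dt_sub
      inside <- s$x >= bb["lo", 1] & s$x <= bb["hi", 1] &
                s$y >= bb["lo", 2] & s$y <= bb["hi", 2] &
                s$z >= bb["lo", 3] & s$z <= bb["hi", 3]
      keep_row <- inside
      v <- v[keep_row, , drop = FALSE]; s <- s[keep_row, ]
      if (length(config$zones) > 0) {
        pos <- scatterer_pos(s)
        in_zone <- Reduce(`|`, lapply(config$zones,
                                      function(z) in_box(pos, z$box)))
        v <- v[!in_zone, , drop = FALSE]; s <- s[!in_zone, ]
      }
      n_before <- nrow(s)
      s2 <- remove_stagnant(s, v, grid, config$stagnation)
      s <- s2
      s <- repopulate_refresh_zones(s, config$zones, grid, config)
    }
    emit(step, t, s, elevation_slice(s, config$elevation_half_width))
  }
  structure(list(
    log = if (length(probes) > 0) bind_rows(log_rows) else
      tibble(step = integer(), time_ms = numeric(), probe = character(),
             concentration = numeric()),
    counts = bind_rows(count_rows),
    final = s,
    sliced = sliced_sets,
    full = full_sets,
    config = config, n_steps = n_steps,
    seeded_concentration = config$concentration),
    class = "tracking_run")
}

#' @export
print.tracking_run <- function(x, ...) {
  cat(sprintf("<tracking_run> %d steps of %g ms (dt), %d scatterers at end\n",
              x$n_steps, x$config$dt, nrow(x$final)))
  if (nrow(x$log) > 0) {
    g <- x$log |> group_by(.data$probe) |>
      summarise(mean = mean(.data$concentration),
                sd = stats::sd(.data$concentration), .groups = "drop")
    for (i in seq_len(nrow(g)))
      cat(sprintf("  %s: %.3f +/- %.3f pts/lambda^3 (seeded %.3f)\n",
                  g$probe[i], g$mean[i], g$sd[i], x$seeded_concentration))
  }
  invisible(x)
}
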
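#' Carreau-Yasuda blood rheology parameters
#'
#' Shear-thinning apparent-viscosity law for whole blood with zero- and
#' infinite-shear limits. Defaults are the values used for the aorta-like
#' flow model: eta_inf = 2 cP, eta_0 = 11 cP, lambda = 1.5 s, n = 0.71,
#' a = 0.2 (the relaxation time is taken in seconds).
#'
#' @param eta_inf Infinite-shear-rate viscosity \[cP\].
#' @param eta_0 Zero-shear-rate viscosity \[cP\].
#' @param lambda Relaxation time \[s\].
#' @param n Power-law index.
#' @param a Transition parameter.
#' @return An object of class `carreau_yasuda_params`.
#' @export
carreau_yasuda_params <- function(eta_inf = 2, eta_0 = 11, lambda = 1.5,
                                  n = 0.71, a = 0.2) {
  if (!(eta_0 >= eta_inf && eta_inf > 0)) abort("need eta_0 >= eta_inf > 0")
  if (a <= 0) abort("need a > 0")
  structure(list(eta_inf = eta_inf, eta_0 = eta_0, lambda = lambda,
                 n = n, a = a),
            class = "carreau_yasuda_params")
}

#' Carreau-Yasuda apparent viscosity
#'
#' eta(g) = eta_inf + (eta_0 - eta_inf) * (1 + (lambda*g)^a)^((n-1)/a)
#'
#' @param shear_rate Shear rate(s) \[1/s\], non-negative.
#' @param params A [carreau_yasuda_params()].
#' @return Apparent viscosity \[cP\], same length as `shear_rate`.
#' @export
carreau_yasuda_viscosity <- function(shear_rate,
                                     params = carreau_yasuda_params()) {
  if (any(shear_rate < 0)) abort("shear_rate must be non-negative")
  with(params,
       eta_inf + (eta_0 - eta_inf) *
         (1 + (lambda * shear_rate)^a)^((n - 1) / a))
}

#' Synthetic flow-field specification
#'
#' Describes an analytic, periodic velocity-field time series with the
#' statistical structure of a pulsatile cardiovascular flow model:
#' a periodic waveform over one cycle, peak speeds well above the
#' stagnation threshold with troughs near it, inflow/outflow ports, and a
#' near-wall low-velocity shell.
#'
#' Kinds:
#' * `uniform`: constant direction (+x) inside a full box (no null nodes).
#' * `rotation`: solid-body rotation about the +y axis inside a cylinder.
#' * `pulsatile_pipe`: waveform-modulated Poiseuille profile along +x in a
#'   straight circular pipe.
#' * `helical_tube`: half-torus (U-bend) in the x-z plane with a
#'   Poiseuille-like axial profile plus an azimuthal swirl component;
#'   ports open at the top (low z).
#'
#' @param kind One of "uniform", "rotation", "pulsatile_pipe",
#'   "helical_tube".
#' @param peak_speed Peak speed \[mm/s\] (waveform value 1 at profile peak).
#' @param cycle_period Cycle length \[ms\].
#' @param frame_step Frame step \[ms\]; must divide `cycle_period` with at
#'   least 2 frames per cycle.
#' @param spacing Grid spacing d \[mm\].
#' @param waveform Periodic modulation samples over one cycle (resampled to
#'   the frame cadence if the length differs). Default all ones.
#' @param geometry Named list of geometry parameters \[mm\]:
#'   `radius` (pipe/cylinder/tube radius), `length` (pipe/cylinder extent),
#'   `bend_radius` (torus centreline radius), `swirl` (swirl-to-axial speed
#'   ratio for `helical_tube`), `box` (c(lx, ly, lz) for `uniform`),
#'   `radial_drift` (pipe only: outward radial speed at the wall as a
#'   fraction of `peak_speed`, default 0 — a stand-in for the
#'   cross-streamline transport of complex 3-D flow that carries particles
#'   into the low-velocity wall shell).
#' @param rng_seed Seed reserved for any stochastic extension (unused by the
#'   analytic kinds; recorded in the spec for provenance).
#' @return An object of class `synthetic_field_spec`.
#' @export
synthetic_field_spec <- function(kind = c("uniform", "rotation",
                                          "pulsatile_pipe", "helical_tube"),
                                 peak_speed = 100,
                                 cycle_period = 100, frame_step = 2,
                                 spacing = 0.1, waveform = NULL,
                                 geometry = list(), rng_seed = 1L) {
  kind <- match.arg(kind)
  if (peak_speed <= 0) abort("peak_speed must be > 0")
  n_frames <- cycle_period / frame_step
  if (abs(n_frames - round(n_frames)) > 1e-9 || round(n_frames) < 2)
    abort("cycle_period / frame_step must be an integer >= 2")
  geo_default <- switch(kind,
    uniform = list(box = c(2, 1, 2)),
    rotation = list(radius = 1, length = 1),
    pulsatile_pipe = list(radius = 0.5, length = 6, radial_drift = 0),
    helical_tube = list(radius = 0.8, bend_radius = 2, swirl = 0.3))
  geometry <- utils::modifyList(geo_default, geometry)
  structure(list(kind = kind, peak_speed = peak_speed,
                 cycle_period = cycle_period, frame_step = frame_step,
                 spacing = spacing, waveform = waveform,
                 geometry = geometry, rng_seed = rng_seed),
            class = "synthetic_field_spec")
}

#' Aorta-like default flow specification
#'
#' A helical U-bend tube with a 100 ms cycle sampled every 2 ms on a 0.1 mm
#' grid, peak speed 500 mm/s, and a cardiac-like waveform: a systolic pulse,
#' a brief reverse-flow lobe, and a diastolic trough near zero (so that both
#' back-flow and stagnation code paths are exercised).
#'
#' @return A [synthetic_field_spec()].
#' @export
default_aorta_like_spec <- function() {
  t <- seq(0, 98, by = 2)
  w <- exp(-((t - 20) / 7)^2) - 0.12 * exp(-((t - 38) / 5)^2) + 0.02
  synthetic_field_spec("helical_tube", peak_speed = 500,
                       cycle_period = 100, frame_step = 2, spacing = 0.1,
                       waveform = w,
                       geometry = list(radius = 0.8, bend_radius = 2,
                                       swirl = 0.3))
}

resample_waveform <- function(w, n_frames) {
  if (is.null(w)) return(rep(1, n_frames))
  if (length(w) == n_frames) return(as.numeric(w))
  # periodic linear resampling onto the frame cadence
  ph_in <- seq(0, 1, length.out = length(w) + 1)
  ph_out <- (seq_len(n_frames) - 1) / n_frames
  approx(ph_in, c(w, w[1]), xout = ph_out)$y
}

#' Generate a synthetic flow grid
#'
#' Evaluates the analytic velocity field of `spec` on a uniform grid. All
#' nodes outside the geometry are null with exactly zero velocity and the
#' flow mask matches the geometry. The field is periodic: advancing one
#' full cycle reproduces frame 1 exactly.
#'
#' @param spec A [synthetic_field_spec()].
#' @return A [flow_grid()].
#' @export
make_field <- function(spec) {
  stopifnot(inherits(spec, "synthetic_field_spec"))
  d <- spec$spacing
  n_frames <- as.integer(round(spec$cycle_period / spec$frame_step))
  w <- resample_waveform(spec$waveform, n_frames)
  g <- spec$geometry
  ax <- function(lo, hi) seq(lo, hi, by = d)
  if (spec$kind == "uniform") {
    axes <- list(x = ax(0, g$box[1]), y = ax(0, g$box[2]), z = ax(0, g$box[3]))
    nodes <- axes_node_coords(axes)
    mask <- rep(TRUE, nrow(nodes))
    unit <- cbind(mask * 1, 0, 0)
  } else if (spec$kind == "rotation") {
    R <- g$radius; L <- g$length
    m <- ceiling(R / d) * d + 2 * d
    axes <- list(x = ax(-m, m), y = ax(0, L), z = ax(-m, m))
    nodes <- axes_node_coords(axes)
    r2 <- nodes[, 1]^2 + nodes[, 3]^2
    mask <- r2 <= R^2
    omega <- spec$peak_speed / R   # rad/s; applied via unit field below
    unit <- cbind(nodes[, 3] / R, 0, -nodes[, 1] / R)  # |unit| = r/R
    unit[!mask, ] <- 0
  } else if (spec$kind == "pulsatile_pipe") {
    R <- g$radius; L <- g$length
    m <- ceiling(R / d) * d + 2 * d
    axes <- list(x = ax(0, L), y = ax(-m, m), z = ax(-m, m))
    nodes <- axes_node_coords(axes)
    r2 <- nodes[, 2]^2 + nodes[, 3]^2
    mask <- r2 <= R^2
    fr <- if (is.null(g$radial_drift)) 0 else g$radial_drift
    unit <- cbind(pmax(0, 1 - r2 / R^2),
                  fr * nodes[, 2] / R,
                  fr * nodes[, 3] / R)
    unit[!mask, ] <- 0
  } else { # helical_tube
    R <- g$radius; Rb <- g$bend_radius; sw <- g$swirl
    z0 <- 0.2   # port plane depth offset [mm]
    m <- Rb + R + 2 * d
    axes <- list(x = ax(-m, m), y = ax(-(R + 2 * d), R + 2 * d),
                 z = ax(z0 - 2 * d, z0 + Rb + R + 2 * d))
    nodes <- axes_node_coords(axes)
    zrel <- nodes[, 3] - z0
    rr <- sqrt(nodes[, 1]^2 + zrel^2)
    s2 <- (rr - Rb)^2 + nodes[, 2]^2
    mask <- s2 <= R^2 & zrel >= 0
    # centreline tangent at angle phi = atan2(zrel, -x): (sin phi, 0, cos phi)
    phi <- atan2(zrel, -nodes[, 1])
    tx <- sin(phi); tz <- cos(phi)
    axial <- pmax(0, 1 - s2 / R^2)
    # swirl: rotation about the local centreline (tangent x radial_unit)
    rad_x <- ifelse(rr > 1e-12, nodes[, 1] / rr, 0)
    rad_z <- ifelse(rr > 1e-12, zrel / rr, 0)
    nrm <- sqrt(pmax((rr - Rb)^2 + nodes[, 2]^2, 1e-24))
    nux <- (rr - Rb) / nrm * rad_x
    nuy <- nodes[, 2] / nrm
    nuz <- (rr - Rb) / nrm * rad_z
    # e_swirl = t x nu
    ex <- 0 * tx - tz * nuy
    ey <- tz * nux - tx * nuz
    ez <- tx * nuy - 0 * tz
    sfrac <- sw * sqrt(pmax(s2, 0)) / R   # zero on the centreline
    unit <- cbind(axial * tx + sfrac * axial * ex,
                  sfrac * axial * ey,
                  axial * tz + sfrac * axial * ez)
    unit[!mask, ] <- 0
  }
  n_nodes <- nrow(nodes)
  v <- array(0, dim = c(n_nodes, 3, n_frames))
  for (k in seq_len(n_frames)) v[, , k] <- unit * (spec$peak_speed * w[k])
  frame_times <- (seq_len(n_frames) - 1) * spec$frame_step
  flow_grid(axes$x, axes$y, axes$z, v, frame_times, mask,
            cycle_period = spec$cycle_period, periodic = TRUE)
}

#' Scatterers per transducer resolution cell
#'
#' Converts a seeding concentration in points per wavelength cubed into the
#' expected number of scatterers in one resolution cell. The default cell,
#' 4 x 5.3 x 2 wavelengths (lateral x elevation x axial), is the plane-wave
#' focal volume of a 15-MHz linear array; at least 10 scatterers per cell
#' are needed for fully developed speckle.
#'
#' @param concentration Concentration \[pts/lambda^3\].
#' @param cell_lambda Cell dimensions in wavelengths.
#' @return Expected scatterers per resolution cell.
#' @export
scatterers_per_resolution_cell <- function(concentration,
                                           cell_lambda = c(4, 5.3, 2)) {
  concentration * prod(cell_lambda)
}
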
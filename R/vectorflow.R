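#' Per-angle lag-one phase maps
#'
#' Computes the lag-one autocorrelation phase independently for each
#' steering angle on the un-compounded per-angle slow time (rate = PRF /
#' number of angles), in the same sliding windows as the Doppler map.
#'
#' @param per_angle List of complex arrays (z x x x slow time), one per
#'   angle (e.g. `iq_cube$per_angle`).
#' @param config A [doppler_config()] (window/shift reused).
#' @param filter Wall-filter each angle first (default TRUE).
#' @return List with `phase` (array z x x x window x angle), `power`
#'   (z x x x window, mean across angles), `times`.
#' @export
per_angle_phase <- function(per_angle, config = doppler_config(),
                            filter = TRUE) {
  na <- length(per_angle)
  d <- dim(per_angle[[1]])
  if (filter) per_angle <- lapply(per_angle, wall_filter,
                                  cutoff = config$wall_cutoff,
                                  order = config$filter_order)
  starts <- window_starts(d[3], config$window, config$shift,
                          if (filter) config$edge_guard else 0)
  ph <- array(NA_real_, dim = c(d[1], d[2], length(starts), na))
  pw <- array(0, dim = c(d[1], d[2], length(starts)))
  for (a in seq_len(na)) {
    m <- matrix(aperm(per_angle[[a]], c(3, 1, 2)), nrow = d[3])
    for (w in seq_along(starts)) {
      seg <- m[starts[w]:(starts[w] + config$window - 1), , drop = FALSE]
      n <- nrow(seg)
      r1 <- colSums(seg[2:n, , drop = FALSE] *
                      Conj(seg[1:(n - 1), , drop = FALSE]))
      ph[, , w, a] <- Arg(r1)
      pw[, , w] <- pw[, , w] + colMeans(Mod(seg)^2) / na
    }
  }
  list(phase = ph, power = pw, times = starts + (config$window - 1) / 2)
}

vf_design_matrix <- function(angles, f0, prf_per_angle, sound_speed) {
  th <- angles * pi / 180
  (2 * pi * f0 * 1e6) / (sound_speed * prf_per_angle * 1e3) *
    cbind(sin(th), 1 + cos(th))
}

#' Least-squares lateral/axial velocity from multi-angle phases
#'
#' Solves, in the least-squares sense, the multi-angle vector-Doppler
#' forward model (transmit steered by theta_i, receive broadside):
#'
#'   dphi_i = (2 pi f0) / (c PRF_a) * (Vz (1 + cos theta_i) + Vx sin theta_i)
#'
#' for (Vx, Vz). With 3 angles the 3 x 2 system is overdetermined and
#' solved by QR; the solution is exact on consistent (noise-free) phases.
#' Velocities are in the measurement convention of the phases supplied
#' (positive phase rate = positive Vz); [estimate_vector_flow()] maps the
#' result onto image axes (Vz positive downward).
#'
#' @param phases Lag-one phases \[rad\]: vector of length n_angles, or
#'   matrix (n_angles x n_pixels).
#' @param angles Steering angles \[degrees\] (>= 2 distinct).
#' @param f0 Centre frequency \[MHz\].
#' @param prf_per_angle Per-angle slow-time rate \[kHz\].
#' @param sound_speed c \[m/s\].
#' @return Matrix (2 x n_pixels): rows Vx, Vz \[cm/s\].
#' @export
least_squares_vxvz <- function(phases, angles, f0, prf_per_angle,
                               sound_speed = 1540) {
  if (length(unique(angles)) < 2)
    abort("rank deficiency: need >= 2 distinct steering angles")
  if (is.null(dim(phases))) phases <- matrix(phases, ncol = 1)
  if (nrow(phases) != length(angles))
    abort("one phase row required per angle")
  G <- vf_design_matrix(angles, f0, prf_per_angle, sound_speed)
  qrG <- qr(G)
  if (qrG$rank < 2) abort("rank deficiency: angle set does not span (Vx, Vz)")
  sol <- qr.coef(qrG, phases)   # velocities in m/s
  rownames(sol) <- c("Vx", "Vz")
  sol * 100
}

#' Power-gate a vector-flow field
#'
#' Pixels whose power is below the threshold are forced to exactly
#' (Vx, Vz) = (0, 0) and masked out, suppressing estimates where there is
#' no flow signal.
#'
#' @param vx,vz Velocity arrays \[cm/s\].
#' @param power Power array (linear), same shape.
#' @param threshold_db Gate threshold in dB relative to the maximum power
#'   (default -30).
#' @return An object of class `vector_flow_field`: `vx`, `vz`, `mask`
#'   (TRUE = retained), `power_db`.
#' @export
power_gate <- function(vx, vz, power, threshold_db = -30) {
  power_db <- 10 * log10(pmax(power, .Machine$double.xmin))
  mask <- power_db >= max(power_db) + threshold_db
  vx[!mask] <- 0
  vz[!mask] <- 0
  structure(list(vx = vx, vz = vz, mask = mask, power_db = power_db,
                 threshold_db = threshold_db),
            class = "vector_flow_field")
}

#' Multi-angle vector-flow estimation
#'
#' The full estimator: wall filter each angle's slow time, compute per-angle
#' lag-one phases in sliding windows, invert the multi-angle forward model
#' per pixel by least squares, and power-gate the result. Output velocities
#' follow the image axes: Vx positive to the right, Vz positive downward
#' (away from the transducer); note the colour-Doppler map of
#' [doppler_map()] uses the opposite (toward-transducer positive) axial
#' convention.
#'
#' @param iq An `iq_cube` (with per-angle sub-cubes) from
#'   [beamform_sequence()].
#' @param config A [doppler_config()].
#' @param threshold_db Power-gate threshold \[dB\] relative to maximum.
#' @param filter Wall-filter first (default TRUE).
#' @return A `vector_flow_field` (see [power_gate()]) with extra elements
#'   `times`, `grid`, `aliasing_velocity`.
#' @export
estimate_vector_flow <- function(iq, config = doppler_config(),
                                 threshold_db = -30, filter = TRUE) {
  stopifnot(inherits(iq, "iq_cube"))
  angles <- iq$scheme$angles
  prf_a <- iq$scheme$effective_frame_rate  # per-angle slow-time rate
  pap <- per_angle_phase(iq$per_angle, config, filter = filter)
  d <- dim(pap$phase)
  npix <- d[1] * d[2] * d[3]
  phases <- t(matrix(pap$phase, nrow = npix, ncol = d[4]))
  sol <- least_squares_vxvz(phases, angles, iq$array$center_frequency,
                            prf_a, iq$array$sound_speed)
  # phases measure toward-transducer motion as positive; flip onto image axes
  vx <- array(-sol["Vx", ], dim = d[1:3])
  vz <- array(-sol["Vz", ], dim = d[1:3])
  out <- power_gate(vx, vz, pap$power, threshold_db)
  out$times <- pap$times
  out$grid <- iq$grid
  out$aliasing_velocity <- aliasing_velocity(iq$array$center_frequency,
                                             prf_a, iq$array$sound_speed)
  out
}
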
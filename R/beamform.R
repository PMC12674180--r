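#' Beamforming pixel grid
#'
#' Pixel origin at the array centre; z is depth (positive downward), x is
#' lateral. Default spacing 25 x 25 um.
#'
#' @param x_range Lateral extent c(min, max) \[mm\].
#' @param z_range Axial extent c(min, max) \[mm\].
#' @param pixel Pixel spacing c(lateral, axial) \[um\].
#' @return An object of class `image_grid` with pixel-centre vectors
#'   `x` and `z` \[mm\].
#' @export
image_grid <- function(x_range, z_range, pixel = c(25, 25)) {
  if (any(pixel <= 0)) abort("pixel spacing must be > 0")
  structure(list(x = seq(x_range[1], x_range[2], by = pixel[1] * 1e-3),
                 z = seq(z_range[1], z_range[2], by = pixel[2] * 1e-3),
                 pixel = pixel),
            class = "image_grid")
}

#' Delay-and-sum beamforming of one IQ transmit
#'
#' For each pixel, sums the elements whose lateral distance is within the
#' constant-F-number aperture half-width z / (2 F#) (never narrower than
#' one element), delaying by the exact two-way time with linear
#' interpolation of the complex samples and phase rotation at f0.
#' No apodization by default.
#'
#' @param iq An `iq_channel_data` object (see [demodulate_iq()]).
#' @param array A [linear_array()].
#' @param angle Steering angle \[degrees\] of this transmit.
#' @param grid An [image_grid()].
#' @param f_number Receive F-number (default 2).
#' @param apodization Receive apodization: "none" (default) or "hann".
#' @return Complex matrix (n_z x n_x).
#' @export
das_beamform <- function(iq, array, angle, grid, f_number = 2,
                         apodization = c("none", "hann")) {
  apodization <- match.arg(apodization)
  stopifnot(inherits(iq, "iq_channel_data"), inherits(grid, "image_grid"))
  res <- .cpp_das_iq(Re(iq$iq), Im(iq$iq), array$element_positions,
                     angle * pi / 180, array$sound_speed / 1e3,
                     iq$f0, iq$sample_rate, iq$t0,
                     grid$x, grid$z, f_number,
                     if (apodization == "hann") 1L else 0L)
  res$re + 1i * res$im
}

#' Coherent compounding of per-angle images
#'
#' Complex mean across steering angles. The per-angle images are what the
#' vector-flow estimator consumes; the compounded frame feeds B-mode and
#' colour Doppler.
#'
#' @param per_angle_images List of complex matrices (same size).
#' @return Complex matrix.
#' @export
compound_angles <- function(per_angle_images) {
  if (length(per_angle_images) == 1) return(per_angle_images[[1]])
  Reduce(`+`, per_angle_images) / length(per_angle_images)
}

#' Simulate, demodulate, and beamform a transmit sequence
#'
#' Drives the whole front end: for each per-transmit scatterer set, fires
#' the next steering angle in the scheme, simulates RF, demodulates to IQ,
#' and beamforms onto the pixel grid. Transmits are grouped into compounded
#' slow-time frames of `length(scheme$angles)` each; per-angle sub-cubes
#' are retained for vector flow.
#'
#' @param scatterer_sets List of per-transmit `scatterer_set`s (e.g. the
#'   `sliced` stream of [run_tracking()]); length should be a multiple of
#'   the number of angles.
#' @param array A [linear_array()].
#' @param scheme A [plane_wave_scheme()].
#' @param grid An [image_grid()].
#' @param f_number Receive F-number.
#' @param apodization Receive apodization ("none" or "hann").
#' @param sample_rate RF sample rate \[MHz\].
#' @param decimate IQ decimation factor before beamforming.
#' @return An object of class `iq_cube`: `iq` (n_z x n_x x n_frames complex
#'   array, compounded), `per_angle` (list per angle of n_z x n_x x
#'   n_frames arrays), `frame_rate` \[kHz\] (effective), `prf` \[kHz\],
#'   `grid`, `array`, `scheme`.
#' @export
beamform_sequence <- function(scatterer_sets, array, scheme, grid,
                              f_number = 2, apodization = "none",
                              sample_rate = 4 * array$center_frequency,
                              decimate = 2L) {
  na <- scheme$n_angles
  n_tx <- length(scatterer_sets)
  n_frames <- n_tx %/% na
  if (n_frames == 0) abort("need at least one full angle set of transmits")
  z_range <- range(grid$z) + c(-0.5, 0.5)
  x_extent <- max(vapply(scatterer_sets,
                         function(s) if (nrow(s) > 0) max(abs(s$x)) else 0,
                         numeric(1)))
  nz <- length(grid$z); nx <- length(grid$x)
  per_angle <- lapply(seq_len(na), function(a)
    array(0i, dim = c(nz, nx, n_frames)))
  for (f in seq_len(n_frames)) {
    imgs <- vector("list", na)
    for (a in seq_len(na)) {
      tx <- (f - 1) * na + a
      ang <- scheme$angles[a]
      ch <- simulate_channel_data(scatterer_sets[[tx]], array, ang,
                                  sample_rate = sample_rate,
                                  z_range = z_range, x_extent = x_extent)
      iq <- demodulate_iq(ch, decimate = decimate)
      imgs[[a]] <- das_beamform(iq, array, ang, grid, f_number, apodization)
      per_angle[[a]][, , f] <- imgs[[a]]
    }
  }
  compounded <- array(0i, dim = c(nz, nx, n_frames))
  for (f in seq_len(n_frames))
    compounded[, , f] <- compound_angles(lapply(per_angle,
                                                function(p) p[, , f]))
  structure(list(iq = compounded, per_angle = per_angle,
                 frame_rate = scheme$effective_frame_rate,
                 prf = scheme$prf, grid = grid, array = array,
                 scheme = scheme),
            class = "iq_cube")
}

#' @export
print.iq_cube <- function(x, ...) {
  d <- dim(x$iq)
  cat(sprintf(
    "<iq_cube> %d x %d pixels, %d compounded frames at %g kHz (%d angles)\n",
    d[1], d[2], d[3], x$frame_rate, length(x$per_angle)))
  invisible(x)
}
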
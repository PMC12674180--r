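#' Linear-array transducer description
#'
#' Elements lie on the x axis at z = 0, centred at x = 0. Defaults describe
#' a 15-MHz high-frequency linear array; the element count and pitch are
#' configuration, not claims about a particular probe.
#'
#' @param n_elements Number of elements.
#' @param pitch Element pitch \[mm\].
#' @param center_frequency f0 \[MHz\].
#' @param fractional_bandwidth -6 dB fractional bandwidth of the pulse.
#'   The default 0.53 corresponds to a passband of roughly 14-22 MHz at a
#'   15-MHz centre frequency, typical of high-frequency linear arrays.
#' @param sound_speed c \[m/s\]. 1540 is conventional for soft tissue.
#' @return An object of class `linear_array` with derived
#'   `element_positions` \[mm\] and `wavelength` \[mm\].
#' @export
linear_array <- function(n_elements = 128, pitch = 0.1,
                         center_frequency = 15, fractional_bandwidth = 0.53,
                         sound_speed = 1540) {
  if (n_elements < 2) abort("n_elements must be >= 2")
  if (pitch <= 0 || center_frequency <= 0) abort("pitch and f0 must be > 0")
  ex <- (seq_len(n_elements) - (n_elements + 1) / 2) * pitch
  structure(list(n_elements = as.integer(n_elements), pitch = pitch,
                 center_frequency = center_frequency,
                 fractional_bandwidth = fractional_bandwidth,
                 sound_speed = sound_speed,
                 element_positions = ex,
                 wavelength = sound_speed / (center_frequency * 1e6) * 1e3),
            class = "linear_array")
}

#' Plane-wave transmit scheme
#'
#' @param angles Steering angles \[degrees\].
#' @param prf Absolute pulse repetition frequency \[kHz\]. The effective
#'   (compounded) frame rate is `prf / length(angles)`.
#' @return An object of class `plane_wave_scheme`.
#' @export
plane_wave_scheme <- function(angles = c(-10, 0, 10), prf = 30) {
  structure(list(angles = angles, prf = prf,
                 n_angles = length(angles),
                 effective_frame_rate = prf / length(angles)),
            class = "plane_wave_scheme")
}

#' Plane-wave transmit delay to a field point
#'
#' For a plane wave steered by `angle` the wavefront reaches (x, z) at
#' (z cos(angle) + x sin(angle)) / c after firing.
#'
#' @param angle Steering angle \[degrees\].
#' @param x,z Field point \[mm\].
#' @param sound_speed c \[m/s\].
#' @return Delay \[s\].
#' @export
transmit_delay <- function(angle, x, z, sound_speed = 1540) {
  th <- angle * pi / 180
  (z * cos(th) + x * sin(th)) * 1e-3 / sound_speed
}

#' Receive delay from a field point back to an element
#'
#' @param x,z Field point \[mm\] (optionally `y` off-plane).
#' @param element_x Element x position \[mm\].
#' @param sound_speed c \[m/s\].
#' @param y Elevation offset \[mm\].
#' @return Delay \[s\].
#' @export
receive_delay <- function(x, z, element_x, sound_speed = 1540, y = 0) {
  sqrt((x - element_x)^2 + y^2 + z^2) * 1e-3 / sound_speed
}

pulse_sigma_us <- function(array) {
  # Gaussian envelope whose -6 dB (amplitude) spectral width equals the
  # fractional bandwidth: sigma_t = sqrt(2 ln 2) / (pi * b * f0)
  sqrt(2 * log(2)) /
    (pi * array$fractional_bandwidth * array$center_frequency)
}

#' Simulate one plane-wave transmit of RF channel data
#'
#' Linear point-target model: each scatterer contributes a
#' Gaussian-enveloped sinusoid at f0 delayed by the two-way geometric time
#' of flight (plane-wave transmit delay plus exact element distance on
#' receive). No attenuation, no element directivity, no elevation
#' weighting, no noise; the model is amplitude-linear by construction.
#'
#' @param scatterers A `scatterer_set` (columns x, y, z, amp) or an
#'   (n x 3) position matrix (unit amplitudes).
#' @param array A [linear_array()].
#' @param angle Steering angle \[degrees\].
#' @param sample_rate RF sample rate \[MHz\] (>= 4 f0; default 4 f0).
#' @param z_range Recorded depth span c(zmin, zmax) \[mm\]; fixes the
#'   sample window so successive transmits align in fast time.
#' @param x_extent Lateral half-extent \[mm\] used to size the record
#'   window; defaults to the scatterer extent. Supply it to make windows
#'   identical across transmits.
#' @return An object of class `channel_data`: list with `rf` (samples x
#'   elements), `sample_rate` \[MHz\], `t0` \[us\], `angle`, `array`.
#' @export
simulate_channel_data <- function(scatterers, array, angle,
                                  sample_rate = 4 * array$center_frequency,
                                  z_range = NULL, x_extent = NULL) {
  if (sample_rate < 4 * array$center_frequency)
    abort("sample_rate must be >= 4 * f0")
  if (is.data.frame(scatterers)) {
    pos <- scatterer_pos(scatterers)
    amp <- if ("amp" %in% names(scatterers)) scatterers$amp
           else rep(1, nrow(pos))
  } else {
    pos <- as.matrix(scatterers)
    amp <- rep(1, nrow(pos))
  }
  c_mm_us <- array$sound_speed / 1e3
  sigma <- pulse_sigma_us(array)
  if (is.null(z_range)) {
    z_range <- if (nrow(pos) > 0) range(pos[, 3]) + c(-0.5, 0.5) else c(0, 10)
  }
  if (is.null(x_extent)) x_extent <- max(abs(pos[, 1]), 0)
  half_x <- max(abs(array$element_positions)) + x_extent + 0.001
  t_min <- max(0, 2 * z_range[1] / c_mm_us -
                 abs(sin(angle * pi / 180)) * half_x / c_mm_us - 6 * sigma)
  t_max <- 2 * sqrt(z_range[2]^2 + half_x^2) / c_mm_us +
    abs(sin(angle * pi / 180)) * half_x / c_mm_us + 6 * sigma
  n_samples <- ceiling((t_max - t_min) * sample_rate) + 1
  rf <- .cpp_simulate_rf(pos, amp, array$element_positions,
                         angle * pi / 180, c_mm_us,
                         array$center_frequency, sigma, sample_rate,
                         t_min, as.integer(n_samples))
  structure(list(rf = rf, sample_rate = sample_rate, t0 = t_min,
                 angle = angle, array = array),
            class = "channel_data")
}

#' Demodulate RF channel data to complex baseband (IQ)
#'
#' Mixes down by f0 and low-pass filters (zero-phase Butterworth) at the
#' pulse bandwidth; the factor 2 preserves the envelope magnitude so
#' |IQ| matches the RF envelope.
#'
#' @param channel A `channel_data` object (or a samples x elements RF
#'   matrix, in which case `f0`, `sample_rate`, `t0` must be given).
#' @param f0 Centre frequency \[MHz\].
#' @param sample_rate Sample rate \[MHz\].
#' @param t0 Time of first sample \[us\].
#' @param cutoff Low-pass cutoff \[MHz\]; default the centre frequency.
#' @param decimate Integer decimation factor applied after filtering.
#' @return An `iq_channel_data` object: complex `iq` (samples x elements),
#'   `sample_rate`, `t0`, `f0`, `angle`.
#' @export
demodulate_iq <- function(channel, f0 = NULL, sample_rate = NULL, t0 = 0,
                          cutoff = NULL, decimate = 1L) {
  if (inherits(channel, "channel_data")) {
    rf <- channel$rf
    f0 <- channel$array$center_frequency
    sample_rate <- channel$sample_rate
    t0 <- channel$t0
    angle <- channel$angle
  } else {
    rf <- as.matrix(channel)
    if (is.null(f0) || is.null(sample_rate))
      abort("f0 and sample_rate are required for a bare RF matrix")
    angle <- NA_real_
  }
  n <- nrow(rf)
  t_us <- t0 + (seq_len(n) - 1) / sample_rate
  mix <- exp(-2i * pi * f0 * t_us)
  if (is.null(cutoff)) cutoff <- f0
  w <- min(0.95, cutoff / (sample_rate / 2))
  bf <- butter(4, w, type = "low")
  xm <- rf * mix   # column-recycled: mix is length n
  re <- apply(Re(xm), 2, function(col) filtfilt_ss(bf$b, bf$a, col))
  im <- apply(Im(xm), 2, function(col) filtfilt_ss(bf$b, bf$a, col))
  iq <- 2 * (re + 1i * im)
  decimate <- as.integer(decimate)
  if (decimate > 1) {
    idx <- seq(1, n, by = decimate)
    iq <- iq[idx, , drop = FALSE]
    sample_rate <- sample_rate / decimate
  }
  structure(list(iq = iq, sample_rate = sample_rate, t0 = t0, f0 = f0,
                 angle = angle),
            class = "iq_channel_data")
}
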
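#' Doppler processing configuration
#'
#' @param wall_cutoff Wall-filter cutoff, normalized to the slow-time
#'   Nyquist (default 0.1).
#' @param window Sliding-window length in slow-time samples (default 64).
#' @param shift Window shift in samples (default 4).
#' @param nfft Zero-padded FFT length for spectrograms (default 256).
#' @param window_function Spectrogram taper ("hann" or "rect").
#' @param filter_order Wall-filter Butterworth order (applied zero-phase).
#' @param edge_guard Slow-time samples excluded at each end of the
#'   wall-filtered series before windowing, so estimation windows stay
#'   clear of the filter's edge ring. `NULL` (default) chooses
#'   `ceiling(0.6 / wall_cutoff)`; shortened automatically on short
#'   ensembles.
#' @return An object of class `doppler_config`.
#' @export
doppler_config <- function(wall_cutoff = 0.1, window = 64, shift = 4,
                           nfft = 256, window_function = "hann",
                           filter_order = 4, edge_guard = NULL) {
  if (wall_cutoff <= 0 || wall_cutoff >= 1) abort("0 < wall_cutoff < 1")
  if (shift > window) abort("shift must be <= window")
  if (nfft < window) abort("nfft must be >= window")
  if (is.null(edge_guard)) edge_guard <- ceiling(0.6 / wall_cutoff)
  structure(list(wall_cutoff = wall_cutoff, window = as.integer(window),
                 shift = as.integer(shift), nfft = as.integer(nfft),
                 window_function = window_function,
                 filter_order = as.integer(filter_order),
                 edge_guard = as.integer(edge_guard)),
            class = "doppler_config")
}

#' Slow-time wall (clutter) filter
#'
#' Zero-phase Butterworth high-pass along the slow-time axis: the DC
#' (static tissue) component is rejected while frequencies above about
#' twice the cutoff pass within 1 dB. Zero-phase filtering preserves
#' slow-time alignment across angles for vector flow.
#'
#' @param x Complex vector, matrix (slow time x pixels), or 3-D array
#'   (z x x x slow time).
#' @param cutoff Normalized cutoff (fraction of the slow-time Nyquist).
#' @param order Butterworth order.
#' @return Filtered object of the same shape.
#' @export
wall_filter <- function(x, cutoff = 0.1, order = 4) {
  bf <- butter(order, cutoff, type = "high")
  filt1 <- function(v) zerophase_filter(bf$b, bf$a, v)
  if (is.null(dim(x))) return(filt1(x))
  if (length(dim(x)) == 2) {
    out <- x
    for (j in seq_len(ncol(x))) out[, j] <- filt1(x[, j])
    return(out)
  }
  d <- dim(x)
  m <- matrix(aperm(x, c(3, 1, 2)), nrow = d[3])
  for (j in seq_len(ncol(m))) m[, j] <- filt1(m[, j])
  aperm(array(m, dim = c(d[3], d[1], d[2])), c(2, 3, 1))
}

#' Lag-one (Kasai) autocorrelation velocity estimate
#'
#' R1 = sum_n x(n+1) conj(x(n)); the axial velocity is
#' v = c * PRF * arg(R1) / (4 pi f0), positive toward the transducer.
#' Power is the mean squared magnitude of the window.
#'
#' @param x Complex slow-time window: vector, or matrix (slow time x
#'   pixels).
#' @param f0 Centre frequency \[MHz\].
#' @param prf Slow-time rate \[kHz\].
#' @param sound_speed c \[m/s\].
#' @return List with `velocity` \[cm/s\] and `power` (linear), each of
#'   length n_pixels.
#' @export
lag_one_velocity <- function(x, f0, prf, sound_speed = 1540) {
  if (is.null(dim(x))) x <- matrix(x, ncol = 1)
  n <- nrow(x)
  if (n < 2) abort("need at least 2 slow-time samples")
  r1 <- colSums(x[2:n, , drop = FALSE] * Conj(x[1:(n - 1), , drop = FALSE]))
  v <- sound_speed * (prf * 1e3) * Arg(r1) / (4 * pi * f0 * 1e6) * 100
  list(velocity = v, power = colMeans(Mod(x)^2))
}

#' Doppler aliasing velocity
#'
#' v_alias = c * PRF / (4 f0).
#'
#' @param f0 Centre frequency \[MHz\].
#' @param prf Slow-time rate \[kHz\].
#' @param sound_speed c \[m/s\].
#' @return Aliasing velocity \[cm/s\].
#' @export
aliasing_velocity <- function(f0, prf, sound_speed = 1540) {
  sound_speed * (prf * 1e3) / (4 * f0 * 1e6) * 100
}

window_starts <- function(n, window, shift, guard = 0) {
  if (n < window) abort(sprintf("need >= %d slow-time samples", window))
  guard <- min(guard, (n - window) %/% 2)
  seq(1 + guard, n - window + 1 - guard, by = shift)
}

#' Colour-Doppler velocity map
#'
#' Wall-filters the compounded IQ along slow time, then applies the
#' lag-one estimator in a sliding window over every pixel.
#'
#' @param iq An `iq_cube` (see [beamform_sequence()]) or a complex 3-D
#'   array (z x x x slow time) with `f0`/`prf` supplied.
#' @param config A [doppler_config()].
#' @param f0,prf,sound_speed Overrides when `iq` is a bare array
#'   (f0 \[MHz\], prf = effective frame rate \[kHz\], c \[m/s\]).
#' @param filter Apply the wall filter first (default TRUE).
#' @return An object of class `velocity_map`: `velocity` \[cm/s\] and
#'   `power` (linear) arrays (z x x x window), `times` (window-centre
#'   indices), `aliasing_velocity` \[cm/s\].
#' @export
doppler_map <- function(iq, config = doppler_config(), f0 = NULL,
                        prf = NULL, sound_speed = NULL, filter = TRUE) {
  if (inherits(iq, "iq_cube")) {
    f0 <- iq$array$center_frequency
    if (is.null(sound_speed)) sound_speed <- iq$array$sound_speed
    prf <- iq$frame_rate
    cube <- iq$iq
  } else {
    cube <- iq
    if (is.null(f0) || is.null(prf))
      abort("f0 and prf are required for a bare array")
    if (is.null(sound_speed)) sound_speed <- 1540
  }
  d <- dim(cube)
  if (filter) cube <- wall_filter(cube, config$wall_cutoff,
                                  config$filter_order)
  starts <- window_starts(d[3], config$window, config$shift,
                          if (filter) config$edge_guard else 0)
  vel <- array(NA_real_, dim = c(d[1], d[2], length(starts)))
  pow <- vel
  m <- matrix(aperm(cube, c(3, 1, 2)), nrow = d[3])
  for (w in seq_along(starts)) {
    seg <- m[starts[w]:(starts[w] + config$window - 1), , drop = FALSE]
    est <- lag_one_velocity(seg, f0, prf, sound_speed)
    vel[, , w] <- est$velocity
    pow[, , w] <- est$power
  }
  structure(list(velocity = vel, power = pow,
                 times = starts + (config$window - 1) / 2,
                 f0 = f0, prf = prf, sound_speed = sound_speed,
                 aliasing_velocity = aliasing_velocity(f0, prf, sound_speed)),
            class = "velocity_map")
}

#' Doppler spectrogram of one pixel's slow-time series
#'
#' Windowed FFT magnitude (window `config$window`, zero-padded to
#' `config$nfft`, shifted by `config$shift`), frequencies centred on zero.
#'
#' @param x Complex slow-time series at a pixel.
#' @param prf Slow-time rate \[kHz\].
#' @param config A [doppler_config()].
#' @return An object of class `doppler_spectrogram`: `magnitude`
#'   (nfft x n_windows), `frequency` \[kHz\] (centred), `time_index`.
#' @export
doppler_spectrogram <- function(x, prf, config = doppler_config()) {
  n <- length(x)
  starts <- window_starts(n, config$window, config$shift)
  taper <- if (config$window_function == "hann")
    0.5 * (1 - cos(2 * pi * seq(0, config$window - 1) / (config$window - 1)))
  else rep(1, config$window)
  mags <- vapply(starts, function(s) {
    seg <- x[s:(s + config$window - 1)] * taper
    seg <- c(seg, rep(0i, config$nfft - config$window))
    Mod(fft(seg))
  }, numeric(config$nfft))
  half <- config$nfft %/% 2
  ord <- c((half + 1):config$nfft, 1:half)    # fftshift
  freq <- ((seq_len(config$nfft) - 1) / config$nfft)
  freq <- ifelse(freq >= 0.5, freq - 1, freq) * prf
  structure(list(magnitude = mags[ord, , drop = FALSE],
                 frequency = freq[ord],
                 time_index = starts + (config$window - 1) / 2,
                 prf = prf),
            class = "doppler_spectrogram")
}
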
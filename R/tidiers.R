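#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' Tidy a tracking run
#'
#' One row per step per probe: the probe concentration log.
#'
#' @param x A `tracking_run`.
#' @param ... Unused.
#' @return A tibble with columns step, time_ms, probe, concentration, and
#'   the per-step tracked/sliced counts joined in.
#' @export
tidy.tracking_run <- function(x, ...) {
  if (nrow(x$log) == 0) return(x$counts)
  left_join(x$log, x$counts, by = c("step", "time_ms"))
}

#' Summarise a tracking run
#'
#' One row per probe: mean and SD of concentration, the slope and intercept
#' of a linear fit over time (a near-zero slope and mean-intercept gap
#' indicate a stable concentration), and the seeded concentration.
#'
#' @param x A `tracking_run`.
#' @param ... Unused.
#' @return A tibble.
#' @export
glance.tracking_run <- function(x, ...) {
  if (nrow(x$log) == 0)
    return(tibble(probe = character(), mean = numeric(), sd = numeric(),
                  slope = numeric(), intercept = numeric(),
                  mean_minus_intercept = numeric(),
                  seeded = numeric(), n_steps = integer()))
  x$log |>
    group_by(.data$probe) |>
    summarise(
      mean = mean(.data$concentration),
      sd = stats::sd(.data$concentration),
      slope = unname(coef(lm(concentration ~ time_ms,
                             data = data.frame(
                               concentration = .data$concentration,
                               time_ms = .data$time_ms)))[2]),
      intercept = unname(coef(lm(concentration ~ time_ms,
                                 data = data.frame(
                                   concentration = .data$concentration,
                                   time_ms = .data$time_ms)))[1]),
      .groups = "drop") |>
    mutate(mean_minus_intercept = .data$mean - .data$intercept,
           seeded = x$seeded_concentration,
           n_steps = x$n_steps)
}

map_pixel_tibble <- function(vals, x_axis, z_axis, wname) {
  d <- dim(vals)
  grid <- expand.grid(z = z_axis, x = x_axis,
                      window = seq_len(d[3]))
  tibble(x = grid$x, z = grid$z, window = grid$window,
         !!wname := as.vector(vals))
}

#' Tidy a colour-Doppler velocity map
#'
#' @param x A `velocity_map`.
#' @param grid Optional [image_grid()] supplying pixel coordinates.
#' @param ... Unused.
#' @return A tibble with columns x, z (mm, or pixel indices if no grid),
#'   window, velocity \[cm/s\], power_db.
#' @export
tidy.velocity_map <- function(x, grid = NULL, ...) {
  d <- dim(x$velocity)
  xs <- if (is.null(grid)) seq_len(d[2]) else grid$x
  zs <- if (is.null(grid)) seq_len(d[1]) else grid$z
  out <- map_pixel_tibble(x$velocity, xs, zs, "velocity")
  out$power_db <- 10 * log10(pmax(as.vector(x$power), .Machine$double.xmin))
  out
}

#' Tidy a vector-flow field
#'
#' @param x A `vector_flow_field`.
#' @param ... Unused.
#' @return A tibble with columns x, z \[mm\], window, vx, vz \[cm/s\],
#'   speed, gated (TRUE when forced to zero by the power gate).
#' @export
tidy.vector_flow_field <- function(x, ...) {
  d <- dim(x$vx)
  xs <- if (is.null(x$grid)) seq_len(d[2]) else x$grid$x
  zs <- if (is.null(x$grid)) seq_len(d[1]) else x$grid$z
  out <- map_pixel_tibble(x$vx, xs, zs, "vx")
  out$vz <- as.vector(x$vz)
  out$speed <- sqrt(out$vx^2 + out$vz^2)
  out$gated <- !as.vector(x$mask)
  out
}

#' Summarise a vector-flow field
#'
#' @param x A `vector_flow_field`.
#' @param ... Unused.
#' @return One-row tibble: pixel counts, gated fraction, mean/max speed of
#'   retained pixels, aliasing velocity.
#' @export
glance.vector_flow_field <- function(x, ...) {
  sp <- sqrt(x$vx^2 + x$vz^2)
  tibble(n_pixels = length(x$vx),
         gated_fraction = mean(!x$mask),
         mean_speed = mean(sp[x$mask]),
         max_speed = if (any(x$mask)) max(sp[x$mask]) else NA_real_,
         aliasing_velocity =
           if (is.null(x$aliasing_velocity)) NA_real_
           else x$aliasing_velocity)
}

#' Tidy a Doppler spectrogram
#'
#' @param x A `doppler_spectrogram`.
#' @param ... Unused.
#' @return A tibble with columns time_index, frequency_khz, magnitude.
#' @export
tidy.doppler_spectrogram <- function(x, ...) {
  grid <- expand.grid(frequency_khz = x$frequency,
                      time_index = x$time_index)
  tibble(time_index = grid$time_index,
         frequency_khz = grid$frequency_khz,
         magnitude = as.vector(x$magnitude))
}
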
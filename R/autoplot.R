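#' @importFrom ggplot2 autoplot ggplot aes geom_line geom_hline geom_raster
#'   geom_segment scale_fill_gradient2 scale_y_reverse labs facet_wrap
#'   theme_minimal arrow unit
#' @export
ggplot2::autoplot

#' Plot the concentration time history of a tracking run
#'
#' Concentration in each probe volume versus time, with the seeded
#' concentration as a reference line.
#'
#' @param object A `tracking_run`.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.tracking_run <- function(object, ...) {
  stopifnot(nrow(object$log) > 0)
  ggplot(object$log, aes(x = .data$time_ms, y = .data$concentration,
                         colour = .data$probe)) +
    geom_line() +
    geom_hline(yintercept = object$seeded_concentration,
               linetype = "dashed") +
    labs(x = "time [ms]", y = "concentration [pts/lambda^3]",
         colour = "probe") +
    theme_minimal()
}

#' Plot one window of a colour-Doppler velocity map
#'
#' @param object A `velocity_map`.
#' @param window Window index (default 1).
#' @param grid Optional [image_grid()] for mm axes.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.velocity_map <- function(object, window = 1, grid = NULL, ...) {
  df <- tidy(object, grid = grid)
  df <- df[df$window == window, ]
  ggplot(df, aes(x = .data$x, y = .data$z, fill = .data$velocity)) +
    geom_raster() +
    scale_fill_gradient2(low = "blue", mid = "black", high = "red") +
    scale_y_reverse() +
    labs(x = "x [mm]", y = "z [mm]", fill = "v [cm/s]") +
    theme_minimal()
}

#' Quiver plot of a vector-flow field
#'
#' Arrows for retained (un-gated) pixels of one estimation window,
#' subsampled for legibility.
#'
#' @param object A `vector_flow_field`.
#' @param window Window index (default 1).
#' @param every Plot every n-th pixel along each axis.
#' @param scale Arrow length per cm/s \[mm\].
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.vector_flow_field <- function(object, window = 1, every = 4,
                                       scale = 0.02, ...) {
  df <- tidy(object)
  df <- df[df$window == window & !df$gated, ]
  xs <- sort(unique(df$x)); zs <- sort(unique(df$z))
  df <- df[df$x %in% xs[seq(1, length(xs), by = every)] &
           df$z %in% zs[seq(1, length(zs), by = every)], ]
  ggplot(df, aes(x = .data$x, y = .data$z)) +
    geom_segment(aes(xend = .data$x + scale * .data$vx,
                     yend = .data$z + scale * .data$vz),
                 arrow = arrow(length = unit(1.2, "mm"))) +
    scale_y_reverse() +
    labs(x = "x [mm]", y = "z [mm]") +
    theme_minimal()
}

#' Plot a Doppler spectrogram
#'
#' @param object A `doppler_spectrogram`.
#' @param dynamic_range Display range \[dB\] below the maximum.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.doppler_spectrogram <- function(object, dynamic_range = 40, ...) {
  df <- tidy(object)
  db <- 20 * log10(pmax(df$magnitude, .Machine$double.xmin))
  df$db <- pmax(db - max(db), -dynamic_range)
  ggplot(df, aes(x = .data$time_index, y = .data$frequency_khz,
                 fill = .data$db)) +
    geom_raster() +
    labs(x = "slow-time sample", y = "Doppler frequency [kHz]",
         fill = "dB") +
    theme_minimal()
}
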
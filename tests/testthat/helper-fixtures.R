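# Shared fixtures: small analytic flow fields and scatterer clouds built in
# code at test time.

pipe_field <- function(radius = 1, length = 6, peak = 200,
                       waveform = NULL, radial_drift = 0) {
  if (is.null(waveform)) {
    t <- seq(0, 98, by = 2)
    waveform <- 0.05 + 0.95 * exp(-((t - 25) / 12)^2)
  }
  make_field(synthetic_field_spec(
    "pulsatile_pipe", peak_speed = peak, waveform = waveform,
    geometry = list(radius = radius, length = length,
                    radial_drift = radial_drift)))
}

pipe_zones <- function(length = 6, half = 2) {
  list(refresh_zone(c(0, 0.5, -half, half, -half, half), "inlet"),
       refresh_zone(c(length - 0.5, length, -half, half, -half, half),
                    "outlet"))
}

# uniform random cloud in a box at imaging depth, amp ~ N(0,1)
speckle_cloud <- function(n, x = c(-2, 2), y = c(-0.25, 0.25),
                          z = c(8.7, 10.3)) {
  tibble::tibble(id = seq_len(n),
                 x = runif(n, x[1], x[2]),
                 y = runif(n, y[1], y[2]),
                 z = runif(n, z[1], z[2]),
                 amp = rnorm(n))
}

# per-transmit scatterer sets for a cloud translating at (vx, vz) mm/s
translating_sets <- function(cloud, vx, vz, n_tx, prf_khz = 30) {
  dt <- 1 / prf_khz
  lapply(seq_len(n_tx), function(i) {
    s <- cloud
    s$x <- s$x + vx * (i - 1) * dt * 1e-3
    s$z <- s$z + vz * (i - 1) * dt * 1e-3
    s
  })
}

# brute-force nearest-neighbour distances (oracle for the cell-list index)
brute_nn_dist <- function(query, ref) {
  apply(query, 1, function(q)
    sqrt(min(colSums((t(ref) - q)^2))))
}

# brute-force trilinear + temporal interpolation oracle for one position
brute_sample <- function(grid, p, t) {
  ft <- grid$frame_times
  n <- length(ft)
  tr <- (t - ft[1]) %% grid$cycle_period + ft[1]
  step <- grid$cycle_period / n
  f0 <- floor((tr - ft[1]) / step)
  a <- (tr - ft[1]) / step - f0
  f0 <- f0 + 1
  f1 <- if (f0 == n) 1 else f0 + 1
  interp1 <- function(fr) {
    nx <- length(grid$x); ny <- length(grid$y)
    ix <- findInterval(p[1], grid$x); iy <- findInterval(p[2], grid$y)
    iz <- findInterval(p[3], grid$z)
    ix <- min(max(ix, 1), length(grid$x) - 1)
    iy <- min(max(iy, 1), length(grid$y) - 1)
    iz <- min(max(iz, 1), length(grid$z) - 1)
    tx <- (p[1] - grid$x[ix]) / grid$spacing
    ty <- (p[2] - grid$y[iy]) / grid$spacing
    tz <- (p[3] - grid$z[iz]) / grid$spacing
    out <- numeric(3)
    for (dz in 0:1) for (dy in 0:1) for (dx in 0:1) {
      w <- (if (dx) tx else 1 - tx) * (if (dy) ty else 1 - ty) *
           (if (dz) tz else 1 - tz)
      node <- (ix + dx) + nx * ((iy + dy) - 1 + ny * ((iz + dz) - 1))
      out <- out + w * grid$v[node, , fr]
    }
    out
  }
  (1 - a) * interp1(f0) + a * interp1(f1)
}
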
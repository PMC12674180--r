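va_forward <- function(vx, vz, angles, f0 = 15, prf_a = 10, c0 = 1540) {
  th <- angles * pi / 180
  (2 * pi * f0 * 1e6) / (c0 * prf_a * 1e3) *
    (vz / 100 * (1 + cos(th)) + vx / 100 * sin(th))
}

test_that("least-squares inversion is exact on noiseless forward phases", {
  angles <- c(-10, 0, 10)
  ph <- va_forward(10, 5, angles)
  sol <- least_squares_vxvz(ph, angles, 15, 10)
  expect_equal(unname(sol[, 1]), c(10, 5), tolerance = 1e-9)
  expect_equal(unname(least_squares_vxvz(va_forward(0, 0, angles),
                                         angles, 15, 10)[, 1]),
               c(0, 0), tolerance = 1e-12)
  # matrix of pixels at once
  vxs <- c(-8, 3, 12); vzs <- c(2, -6, 9)
  phm <- vapply(1:3, function(i) va_forward(vxs[i], vzs[i], angles),
                numeric(3))
  solm <- least_squares_vxvz(phm, angles, 15, 10)
  expect_equal(unname(solm["Vx", ]), vxs, tolerance = 1e-9)
  expect_equal(unname(solm["Vz", ]), vzs, tolerance = 1e-9)
  expect_error(least_squares_vxvz(c(1, 1, 1), c(5, 5, 5), 15, 10),
               "rank")
})

test_that("per-angle phases follow the multi-angle forward model", {
  # build per-angle cubes directly from the forward model
  angles <- c(-10, 0, 10)
  nz <- 3; nx <- 3; nt <- 40
  set.seed(10)
  base <- matrix(rnorm(nz * nx) + 1i * rnorm(nz * nx), nz, nx)
  make_cubes <- function(vx, vz) {
    lapply(seq_along(angles), function(a) {
      ph <- va_forward(vx, vz, angles[a])
      cube <- array(0i, dim = c(nz, nx, nt))
      for (n in seq_len(nt)) cube[, , n] <- base * exp(1i * ph * (n - 1))
      cube
    })
  }
  cfg <- doppler_config(window = 16, shift = 16)
  # static scene: zero phase at every angle
  pap0 <- per_angle_phase(make_cubes(0, 0), cfg, filter = FALSE)
  expect_lt(max(abs(pap0$phase)), 1e-9)
  # pure axial motion: phases scale as (1 + cos theta)
  papz <- per_angle_phase(make_cubes(0, 6), cfg, filter = FALSE)
  ratio <- papz$phase[1, 1, 1, ] / (1 + cos(angles * pi / 180))
  expect_lt(diff(range(ratio)) / mean(ratio), 1e-9)
  # pure lateral motion: sign flips between +-theta, zero at broadside
  papx <- per_angle_phase(make_cubes(9, 0), cfg, filter = FALSE)
  expect_equal(papx$phase[1, 1, 1, 1], -papx$phase[1, 1, 1, 3],
               tolerance = 1e-9)
  expect_lt(abs(papx$phase[1, 1, 1, 2]), 1e-9)
})

test_that("power gating zeroes exactly the below-threshold pixels", {
  set.seed(12)
  vx <- matrix(rnorm(30), 5, 6); vz <- matrix(rnorm(30), 5, 6)
  power <- matrix(10^runif(30, -6, 0), 5, 6)
  out <- power_gate(vx, vz, power, threshold_db = -30)
  pdb <- 10 * log10(power)
  below <- pdb < max(pdb) - 30
  expect_identical(unname(out$mask), unname(!below))
  expect_true(all(out$vx[below] == 0 & out$vz[below] == 0))
  expect_equal(out$vx[!below], vx[!below])
  # -Inf threshold keeps everything; +Inf-like threshold gates everything
  expect_true(all(power_gate(vx, vz, power, -Inf)$mask))
  allz <- power_gate(vx, vz, power, 1e6)
  expect_true(all(allz$vx == 0 & allz$vz == 0))
})

test_that("solid-body rotation yields a consistent-sign curl in vector flow", {
  # rotating disk of scatterers imaged through the full chain
  arr <- linear_array(n_elements = 48, pitch = 0.1)
  scheme <- plane_wave_scheme(c(-10, 0, 10), prf = 30)
  img <- image_grid(c(-0.9, 0.9), c(8.6, 10.4), pixel = c(50, 50))
  omega <- 150  # rad/s -> edge speed 12 cm/s at r = 0.8 mm
  set.seed(19)
  disk <- speckle_cloud(650, x = c(-0.85, 0.85), z = c(8.65, 10.35))
  keep <- (disk$x^2 + (disk$z - 9.5)^2) < 0.85^2
  disk <- disk[keep, ]
  dt <- 1 / 30 * 1e-3  # s per transmit
  sets <- lapply(seq_len(96), function(i) {
    ang <- omega * (i - 1) * dt
    s <- disk
    x0 <- disk$x; z0 <- disk$z - 9.5
    s$x <- x0 * cos(ang) - z0 * sin(ang)
    s$z <- 9.5 + x0 * sin(ang) + z0 * cos(ang)
    s
  })
  iq <- beamform_sequence(sets, arr, scheme, img, apodization = "hann")
  vf <- estimate_vector_flow(iq, doppler_config(window = 24, shift = 8),
                             threshold_db = -25)
  df <- tidy(vf)
  df <- df[df$window == 1 & !df$gated, ]
  # curl sign via the tangential component: v . t with t = (-dz, dx)/r
  dx <- df$x; dz <- df$z - 9.5
  r <- sqrt(dx^2 + dz^2)
  core <- r > 0.35 & r < 0.7
  tang <- (-dz * df$vx + dx * df$vz) / r
  # counter-clockwise throughout the annulus (consistent-sign curl); the
  # magnitude is degraded where the local flow is near-horizontal, so only
  # the sign is asserted
  expect_gt(mean(tang[core] > 0), 0.9)
})
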
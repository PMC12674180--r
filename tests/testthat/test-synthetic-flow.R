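test_that("Carreau-Yasuda viscosity hits its limits and midpoint", {
  p <- carreau_yasuda_params()    # 2 / 11 cP, lambda 1.5 s, n 0.71, a 0.2
  expect_equal(carreau_yasuda_viscosity(0, p), 11)
  expect_lt(carreau_yasuda_viscosity(1e12, p), 2.01)
  # gamma = 1/lambda: eta = 2 + 9 * 2^((n-1)/a) = 2 + 9 * 2^(-1.45)
  expect_equal(carreau_yasuda_viscosity(1 / 1.5, p), 2 + 9 * 2^(-1.45),
               tolerance = 1e-12)
  expect_error(carreau_yasuda_viscosity(-1, p), "non-negative")
  expect_error(carreau_yasuda_params(eta_inf = 5, eta_0 = 2), "eta_0")
})

test_that("viscosity is non-increasing in shear rate for shear-thinning blood", {
  p <- carreau_yasuda_params()
  g <- 10^seq(-3, 6, length.out = 200)
  eta <- carreau_yasuda_viscosity(g, p)
  expect_true(all(diff(eta) <= 1e-12))
  expect_true(all(eta <= 11 & eta >= 2))
})

test_that("uniform field fills every flow node with the peak velocity", {
  g <- make_field(synthetic_field_spec("uniform", peak_speed = 10))
  expect_true(all(g$flow_mask))
  for (k in seq_along(g$frame_times)) {
    expect_true(all(g$v[, 1, k] == 10))
    expect_true(all(g$v[, 2:3, k] == 0))
  }
})

test_that("pulsatile pipe has a Poiseuille profile and a geometric mask", {
  g <- pipe_field(radius = 0.5, length = 2, peak = 100,
                  waveform = rep(1, 50))
  nodes <- grid_node_coords(g)
  r2 <- nodes[, 2]^2 + nodes[, 3]^2
  expect_identical(unname(g$flow_mask), unname(r2 <= 0.25))
  centre <- which(abs(nodes[, 1] - 1) < 1e-9 & r2 < 1e-12)
  expect_equal(g$v[centre, 1, 1], 100)
  near_wall <- which(g$flow_mask & r2 > (0.5 - 0.1)^2)
  expect_true(all(g$v[near_wall, 1, 1] <=
                  100 * (1 - (0.5 - 0.1)^2 / 0.25) + 1e-9))
})

test_that("solid-body rotation is divergence-free on the grid interior", {
  g <- make_field(synthetic_field_spec("rotation", peak_speed = 50,
                                       geometry = list(radius = 1, length = 0.4)))
  nx <- length(g$x); ny <- length(g$y); nz <- length(g$z)
  v <- array(g$v[, , 1], dim = c(nx, ny, nz, 3))
  nodes <- grid_node_coords(g)
  r <- sqrt(nodes[, 1]^2 + nodes[, 3]^2)
  interior <- array(r <= 1 - 2 * g$spacing, dim = c(nx, ny, nz))
  div <- (v[3:nx, 2:(ny - 1), 2:(nz - 1), 1] - v[1:(nx - 2), 2:(ny - 1), 2:(nz - 1), 1] +
          v[2:(nx - 1), 3:ny, 2:(nz - 1), 2] - v[2:(nx - 1), 1:(ny - 2), 2:(nz - 1), 2] +
          v[2:(nx - 1), 2:(ny - 1), 3:nz, 3] - v[2:(nx - 1), 2:(ny - 1), 1:(nz - 2), 3]) /
    (2 * g$spacing)
  core <- interior[2:(nx - 1), 2:(ny - 1), 2:(nz - 1)]
  expect_lt(max(abs(div[core])), 1e-9)
})

test_that("synthetic fields are periodic over one cycle", {
  g <- pipe_field(radius = 0.3, length = 1)
  p <- matrix(c(0.5, 0, 0.1), 1, 3)
  expect_identical(sample_velocity(p, g, 37)[1, ],
                   sample_velocity(p, g, 37 + g$cycle_period)[1, ])
  # t = 1.23 cycles samples the field at 0.23 cycles
  expect_equal(sample_velocity(p, g, 1.23 * g$cycle_period)[1, ],
               sample_velocity(p, g, 0.23 * g$cycle_period)[1, ],
               tolerance = 1e-9)
})

test_that("aorta-like default spec has the cardiac cadence and a reverse lobe", {
  spec <- default_aorta_like_spec()
  expect_equal(spec$cycle_period, 100)
  expect_equal(spec$cycle_period / spec$frame_step, 50)
  expect_equal(spec$spacing, 0.1)
  expect_lt(min(spec$waveform), 0)
  expect_gt(max(spec$waveform), 0)
  g <- make_field(spec)
  expect_equal(length(g$frame_times), 50)
  speed <- sqrt(rowSums(g$v[, , 11]^2))   # systolic frame (t = 20 ms)
  expect_gt(max(speed), 400)
})

test_that("waveforms are resampled periodically onto the frame cadence", {
  w <- sin(seq(0, 2 * pi, length.out = 17))[-17]
  spec <- synthetic_field_spec("uniform", peak_speed = 1, waveform = w)
  g <- make_field(spec)
  expect_equal(dim(g$v)[3], 50)
  expect_error(synthetic_field_spec("uniform", cycle_period = 100,
                                    frame_step = 3),
               "integer")
})

test_that("resolution-cell arithmetic matches the concentration table", {
  expect_equal(scatterers_per_resolution_cell(0.25), 10.6)
  expect_equal(round(scatterers_per_resolution_cell(c(0.05, 0.1, 0.5)), 1),
               c(2.1, 4.2, 21.2))
})
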
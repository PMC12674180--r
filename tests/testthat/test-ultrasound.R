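test_that("plane-wave and receive delays follow the two-way geometry", {
  # broadside point 10 mm above an element: two-way time 2*10mm / 1540 m/s
  tw <- transmit_delay(0, x = 0.35, z = 10) +
    receive_delay(0.35, 10, element_x = 0.35)
  expect_equal(tw * 1e6, 12.987, tolerance = 1e-3)
  # theta = 0 transmit delay is independent of x
  expect_equal(transmit_delay(0, x = -3, z = 5), transmit_delay(0, x = 3, z = 5))
  # steered delay increases with x sin(theta)
  xs <- seq(-2, 2, 0.5)
  expect_true(all(diff(transmit_delay(10, xs, z = 5)) > 0))
  expect_true(all(diff(transmit_delay(-10, xs, z = 5)) < 0))
})

test_that("channel-data synthesis is linear and zero for no scatterers", {
  arr <- linear_array(n_elements = 16, pitch = 0.1)
  empty <- speckle_cloud(0)
  ch0 <- simulate_channel_data(empty, arr, 0, z_range = c(4, 6))
  expect_true(all(ch0$rf == 0))

  set.seed(2)
  s <- speckle_cloud(20, x = c(-0.5, 0.5), z = c(4.5, 5.5))
  ch1 <- simulate_channel_data(s, arr, 0, z_range = c(4, 6), x_extent = 0.5)
  s2 <- s; s2$amp <- 2 * s2$amp
  ch2 <- simulate_channel_data(s2, arr, 0, z_range = c(4, 6))
  expect_equal(ch2$rf, 2 * ch1$rf, tolerance = 1e-12)

  # superposition: splitting the cloud and summing reproduces the whole
  cha <- simulate_channel_data(s[1:10, ], arr, 0, z_range = c(4, 6),
                               x_extent = 0.5)
  chb <- simulate_channel_data(s[11:20, ], arr, 0, z_range = c(4, 6),
                               x_extent = 0.5)
  expect_equal(cha$rf + chb$rf, ch1$rf, tolerance = 1e-12)
})

test_that("per-element envelope peaks at the analytic two-way delay", {
  arr <- linear_array(n_elements = 32, pitch = 0.1)
  s <- tibble::tibble(id = 1L, x = 0.25, y = 0, z = 7, amp = 1)
  ch <- simulate_channel_data(s, arr, 0, z_range = c(6, 8))
  iq <- demodulate_iq(ch)
  for (e in c(1, 8, 16, 24, 32)) {
    t_pk <- iq$t0 + (which.max(Mod(iq$iq[, e])) - 1) / iq$sample_rate
    tau <- (transmit_delay(0, 0.25, 7) +
              receive_delay(0.25, 7, arr$element_positions[e])) * 1e6
    expect_lt(abs(t_pk - tau), 1 / iq$sample_rate + 1e-9)
  }
  # |IQ| envelope reproduces the unit scattering amplitude
  e0 <- which.min(abs(arr$element_positions - 0.25))
  expect_equal(max(Mod(iq$iq[, e0])), 1, tolerance = 0.02)
})

test_that("IQ demodulation preserves envelopes and nulls", {
  # pure tone at f0 -> constant magnitude away from the record edges
  fs <- 60; f0 <- 15
  t <- (0:999) / fs
  rf <- matrix(cos(2 * pi * f0 * t), ncol = 1)
  iq <- demodulate_iq(rf, f0 = f0, sample_rate = fs)
  mid <- Mod(iq$iq[200:800, 1])
  expect_lt(max(abs(mid - 1)), 0.02)
  # zero RF -> zero IQ
  iq0 <- demodulate_iq(matrix(0, 500, 2), f0 = f0, sample_rate = fs)
  expect_true(all(iq0$iq == 0))
  # real pulse: |IQ| peak time equals the RF envelope peak within a sample
  env <- exp(-(t - 8)^2 / (2 * 0.05^2))
  rfp <- matrix(env * cos(2 * pi * f0 * (t - 8)), ncol = 1)
  iqp <- demodulate_iq(rfp, f0 = f0, sample_rate = fs)
  expect_lt(abs(which.max(Mod(iqp$iq[, 1])) - which.max(env)), 1.5)
  expect_equal(max(Mod(iqp$iq[, 1])), 1, tolerance = 0.02)
})

test_that("time-shift equivariance holds at broadside", {
  arr <- linear_array(n_elements = 8, pitch = 0.1)
  dz <- 0.154   # 2 dz / c = 0.2 us exactly
  ch1 <- simulate_channel_data(cbind(0, 0, 7), arr, 0, z_range = c(6, 9))
  ch2 <- simulate_channel_data(cbind(0, 0, 7 + dz), arr, 0, z_range = c(6, 9))
  for (e in c(1, 4, 8)) {
    p1 <- which.max(abs(ch1$rf[, e]))
    p2 <- which.max(abs(ch2$rf[, e]))
    shift_us <- (p2 - p1) / ch1$sample_rate
    expect_lt(abs(shift_us - 2 * dz / 1.54), 1.5 / ch1$sample_rate)
  }
  expect_error(simulate_channel_data(cbind(0, 0, 7), arr, 0,
                                     sample_rate = 20), ">= 4")
})
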
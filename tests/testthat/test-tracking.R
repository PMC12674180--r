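test_that("seeding matches the concentration x volume expectation", {
  g <- make_field(synthetic_field_spec("uniform", peak_speed = 1,
                                       geometry = list(box = c(2, 1, 1))))
  cfg0 <- tracker_config(concentration = 0)
  expect_equal(nrow(seed_scatterers(g, cfg0)), 0)

  # full-box flow: every draw in the 2 mm^3 bounding box survives,
  # so the expected count is exactly 0.25 * 2000 lambda^3 = 500
  cfg <- tracker_config(concentration = 0.25, wavelength = 0.1)
  counts <- vapply(1:20, function(i) {
    set.seed(i); nrow(seed_scatterers(g, cfg))
  }, numeric(1))
  expect_true(all(counts == 500))

  # masked geometry: survivors ~ concentration x flow volume (binomial)
  gp <- pipe_field(radius = 0.5, length = 2, waveform = rep(1, 50))
  counts <- vapply(1:40, function(i) {
    set.seed(i); nrow(seed_scatterers(gp, cfg))
  }, numeric(1))
  s <- seed_scatterers(gp, cfg)
  expect_true(all(table(s$id) == 1))            # unique ids
  # node-cell volume slightly overstates the sampled region (boundary
  # cells are clipped at the bounding box), so the mean sits just below
  expected <- 0.25 * flow_volume(gp, wavelength = 0.1)
  expect_lt(mean(counts), expected * 1.02)
  expect_gt(mean(counts), expected * 0.85)
})

test_that("velocity sampling matches a brute-force space-time oracle", {
  g <- pipe_field(radius = 0.4, length = 2)
  # exact node at an exact frame time returns the stored velocity
  nodes <- grid_node_coords(g)
  i <- which(g$flow_mask)[100]
  v <- sample_velocity(nodes[i, , drop = FALSE], g, g$frame_times[4])
  expect_equal(unname(v[1, ]), unname(g$v[i, , 4]))

  set.seed(9)
  for (k in 1:25) {
    p <- c(runif(1, 0.2, 1.8), runif(1, -0.3, 0.3), runif(1, -0.3, 0.3))
    t <- runif(1, 0, 300)
    v <- sample_velocity(matrix(p, 1, 3), g, t)
    expect_equal(unname(v[1, ]), brute_sample(g, p, t), tolerance = 1e-9)
  }

  # outside the bounding box: zero velocity, flagged
  v <- sample_velocity(matrix(c(50, 0, 0), 1, 3), g, 0)
  expect_true(all(v[1, ] == 0))
  expect_false(attr(v, "inside"))
})

test_that("explicit Euler advance displaces by v * dt and composes", {
  s <- speckle_cloud(10)
  v0 <- matrix(0, 10, 3)
  expect_equal(advance(s, v0, 1), s)
  v <- matrix(rep(c(10, 0, 0), each = 10), ncol = 3)
  s1 <- advance(s, v, 0.5)
  expect_equal(s1$x, s$x + 0.005)   # 10 mm/s * 0.5 ms = 5 um
  expect_equal(s1$id, s$id)
  expect_equal(s1$amp, s$amp)
  expect_equal(advance(advance(s, v, 0.25), v, 0.25), advance(s, v, 0.5))
})

test_that("refresh-zone purge removes closed-box members only", {
  s <- speckle_cloud(50, x = c(0, 4), z = c(0, 4))
  s$x[1] <- 1; s$y[1] <- 0; s$z[1] <- 1    # exactly on the zone corner
  zone <- refresh_zone(c(1, 2, -1, 1, 1, 2))
  out <- purge_refresh_zones(s, list(zone))
  inside <- s$x >= 1 & s$x <= 2 & abs(s$y) <= 1 & s$z >= 1 & s$z <= 2
  expect_equal(out$id, s$id[!inside])
  expect_false(1 %in% out$id)              # boundary point removed
  expect_equal(purge_refresh_zones(s, list()), s)
  all_zone <- refresh_zone(c(-10, 10, -10, 10, -10, 10))
  expect_equal(nrow(purge_refresh_zones(s, list(all_zone))), 0)
})

test_that("stagnation pruning applies both thresholds, per brute force", {
  g <- pipe_field(radius = 0.5, length = 2, waveform = rep(1, 50))
  null_coords <- grid_node_coords(g, "null")
  set.seed(21)
  s <- speckle_cloud(300, x = c(0.2, 1.8), y = c(-0.55, 0.55),
                     z = c(-0.55, 0.55))
  v <- matrix(rnorm(900, sd = 1), ncol = 3)
  pol <- stagnation_policy(1, 2)
  out <- remove_stagnant(s, v, g, pol)
  speed <- sqrt(rowSums(v^2))
  dnull <- brute_nn_dist(cbind(s$x, s$y, s$z), null_coords)
  drop <- speed < 1 & dnull < 0.2
  expect_setequal(out$id, s$id[!drop])

  # all fast -> identity
  out2 <- remove_stagnant(s, v * 1e3, g, pol)
  expect_equal(nrow(out2), nrow(s))

  # spec'd distances: slow scatterer at 0.15 mm from a null node is removed,
  # at 0.25 mm retained (policy 1 mm/s, 2d, d = 0.1)
  s2 <- tibble::tibble(id = 1:2, x = c(1, 1), y = c(0, 0),
                       z = c(0.45, 0.30), amp = 0)
  # nearest null node to z = 0.45 is (y, z) = (0.1, 0.5) at 0.112 mm;
  # for z = 0.30 it is (0.1, 0.5) at 0.224 mm > 2d
  v2 <- matrix(rep(c(0.5, 0, 0), each = 2), ncol = 3)
  out3 <- remove_stagnant(s2, v2, g, stagnation_policy(1, 2))
  expect_equal(out3$id, 2L)
})

test_that("retained count is non-increasing in the velocity threshold", {
  g <- pipe_field(radius = 0.5, length = 2)
  set.seed(33)
  s <- speckle_cloud(400, x = c(0, 2), y = c(-0.6, 0.6), z = c(-0.6, 0.6))
  v <- sample_velocity(s, g, 30)
  kept <- vapply(c(0, 0.1, 1, 2, 10, 50),
                 function(th) nrow(remove_stagnant(s, v, g,
                                                   stagnation_policy(th, 2))),
                 numeric(1))
  expect_true(all(diff(kept) <= 0))
})

test_that("zone repopulation is deterministic given the RNG state", {
  g <- make_field(synthetic_field_spec("uniform", peak_speed = 1,
                                       geometry = list(box = c(2, 1, 1))))
  zone <- refresh_zone(c(0.2, 0.7, 0.25, 0.75, 0.3, 0.8))  # interior box
  cfg <- tracker_config(concentration = 0.25, wavelength = 0.1,
                        zones = list(zone))
  empty <- speckle_cloud(0)
  expect_equal(zone_flow_volume(zone, g), 0.5 * 0.5 * 0.5, tolerance = 1e-12)
  set.seed(4)
  a <- repopulate_refresh_zones(empty, list(zone), g, cfg)
  expect_equal(nrow(a), round(0.25 * 125))   # 0.125 mm^3 = 125 lambda^3
  set.seed(4)
  b <- repopulate_refresh_zones(empty, list(zone), g, cfg)
  expect_equal(a, b)                          # same RNG state, same points
  c2 <- repopulate_refresh_zones(empty, list(zone), g, cfg)
  expect_false(isTRUE(all.equal(a$x, c2$x)))  # advanced state differs
  expect_true(all(a$x >= 0.2 & a$x <= 0.7))
})

test_that("elevation slicing keeps |y| strictly inside the half-width", {
  s <- tibble::tibble(id = 1:3, x = 0, y = c(0.2, 0.3, -0.2), z = 0, amp = 1)
  out <- elevation_slice(s, 0.25)
  expect_setequal(out$id, c(1L, 3L))
  expect_equal(elevation_slice(s, Inf), s)
})

test_that("probe concentration is count over volume in wavelengths cubed", {
  expect_equal(measure_concentration(speckle_cloud(0),
                                     probe_box(c(0, 0, 0))), 0)
  # 250 deterministic points in a 10x10x10 lambda^3 box
  gpts <- expand.grid(x = seq(-0.45, 0.45, length.out = 10),
                      y = seq(-0.45, 0.45, length.out = 5),
                      z = seq(-0.45, 0.45, length.out = 5))
  s <- tibble::tibble(id = seq_len(250), x = gpts$x, y = gpts$y,
                      z = gpts$z, amp = 1)
  expect_equal(measure_concentration(s, probe_box(c(0, 0, 0)), 0.1), 0.25)
})

test_that("solid-body rotation conserves particle radius under small steps", {
  g <- make_field(synthetic_field_spec("rotation", peak_speed = 20,
                                       geometry = list(radius = 1, length = 0.4)))
  # omega = 20 rad/s; dt = 0.05 ms -> omega dt = 1e-3; the explicit-Euler
  # radius drift over one revolution is bounded by pi * omega * dt
  s <- tibble::tibble(id = 1:2, x = c(0.5, 0), y = 0.2, z = c(0, -0.7),
                      amp = 1)
  r0 <- sqrt(s$x^2 + s$z^2)
  n_rev <- ceiling(2 * pi / (20 * 0.05e-3))   # one revolution
  for (i in seq_len(n_rev)) {
    v <- sample_velocity(s, g, 0)
    s <- advance(s, v, 0.05)
  }
  r1 <- sqrt(s$x^2 + s$z^2)
  expect_lt(max(abs(r1 - r0) / r0), 0.005)
  expect_lt(max(abs(r1 - r0) / r0), 1.2 * pi * 20 * 0.05e-3)
})

test_that("the tracking loop conserves state contracts", {
  g <- pipe_field(radius = 0.5, length = 3)
  zones <- pipe_zones(length = 3, half = 1)
  cfg <- tracker_config(concentration = 0.25, dt = 0.5, rng_seed = 5,
                        zones = zones,
                        probes = list(mid = probe_box(c(1.5, 0, 0))))
  r0 <- run_tracking(g, cfg, 0, keep = "both")
  expect_equal(r0$n_steps, 0)
  expect_equal(length(r0$full), 1)            # only the seeded state

  r1 <- run_tracking(g, cfg, 40, keep = "both")
  r2 <- run_tracking(g, cfg, 40, keep = "both")
  expect_identical(r1$log, r2$log)            # deterministic from the seed
  expect_identical(r1$final, r2$final)
  cfg2 <- tracker_config(concentration = 0.25, dt = 0.5, rng_seed = 6,
                         zones = zones,
                         probes = list(mid = probe_box(c(1.5, 0, 0))))
  r3 <- run_tracking(g, cfg2, 40)
  expect_false(identical(r1$log$concentration, r3$log$concentration))

  # no scatterer persists outside the grid bounding box
  bb <- pulsetrack:::grid_bbox(g)
  for (s in r1$full) {
    expect_true(all(s$x >= bb["lo", 1] & s$x <= bb["hi", 1]))
    expect_true(all(s$z >= bb["lo", 3] & s$z <= bb["hi", 3]))
  }
  # sliced stream obeys the elevation slice
  for (s in r1$sliced) expect_true(all(abs(s$y) < cfg$elevation_half_width))
  # tidy/glance surfaces
  td <- tidy(r1)
  expect_true(all(c("step", "time_ms", "probe", "concentration",
                    "n_tracked", "n_sliced") %in% names(td)))
  gl <- glance(r1)
  expect_equal(nrow(gl), 1)
  expect_lt(abs(gl$mean - 0.25), 0.1)
})
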
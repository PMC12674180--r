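test_that("regridding reproduces constant and linear fields exactly", {
  set.seed(42)
  pts <- matrix(runif(4000 * 3), ncol = 3)
  axes <- list(x = seq(0, 1, 0.1), y = seq(0, 1, 0.1), z = seq(0, 1, 0.1))

  # constant field
  fdm_c <- fdm_series(pts, list(matrix(rep(c(5, 0, 0), each = 4000), ncol = 3)), 0)
  vg <- regrid_frame(fdm_c, 1, axes, 0.1)
  cls <- append_null_points(pts, axes, 0.1)
  expect_true(all(abs(vg[cls$flow, 1] - 5) < 1e-9))
  expect_true(all(vg[cls$null, ] == 0))

  # linear field; oracle = direct evaluation at the node coordinates
  vel <- cbind(pts[, 1], 2 * pts[, 2] - pts[, 3], 0.5 * pts[, 1] + pts[, 3])
  fdm_l <- fdm_series(pts, list(vel), 0)
  vg <- regrid_frame(fdm_l, 1, axes, 0.1)
  nodes <- pulsetrack:::axes_node_coords(axes)
  interior <- rowSums(nodes > 0.15 & nodes < 0.85) == 3
  truth <- cbind(nodes[, 1], 2 * nodes[, 2] - nodes[, 3],
                 0.5 * nodes[, 1] + nodes[, 3])
  expect_lt(max(abs(vg[interior, ] - truth[interior, ])), 1e-6)
})

test_that("null-point classification matches brute-force distances", {
  # single flow point at the origin, d = 0.1: threshold distance 0.15
  axes <- list(x = seq(-0.2, 0.2, 0.1), y = seq(-0.2, 0.2, 0.1),
               z = seq(-0.2, 0.2, 0.1))
  pt <- matrix(0, 1, 3)
  cls <- append_null_points(pt, axes, 0.1)
  nodes <- pulsetrack:::axes_node_coords(axes)
  d <- sqrt(rowSums(nodes^2))
  expect_setequal(cls$flow, which(d <= 0.15))
  # node at (0.1, 0.1, 0) ~ 0.1414 inside; (0.1, 0.1, 0.1) ~ 0.1732 null
  i_in <- which(apply(nodes, 1, function(r) all(abs(r - c(0.1, 0.1, 0)) < 1e-12)))
  i_out <- which(apply(nodes, 1, function(r) all(abs(r - 0.1) < 1e-12)))
  expect_true(i_in %in% cls$flow)
  expect_true(i_out %in% cls$null)

  # random cloud vs brute-force oracle
  set.seed(7)
  pts <- matrix(runif(300 * 3, 0, 0.4), ncol = 3)
  cls2 <- append_null_points(pts, axes, 0.1, factor = 1.5)
  d_brute <- brute_nn_dist(nodes, pts)
  expect_setequal(cls2$null, which(d_brute > 0.15))
})

test_that("raising the null-point factor never grows the null set", {
  set.seed(11)
  pts <- matrix(runif(200 * 3, 0, 0.4), ncol = 3)
  axes <- list(x = seq(0, 0.4, 0.1), y = seq(0, 0.4, 0.1),
               z = seq(0, 0.4, 0.1))
  sizes <- vapply(c(1.5, 2, 3, 5),
                  function(f) length(append_null_points(pts, axes, 0.1, f)$null),
                  numeric(1))
  expect_true(all(diff(sizes) <= 0))
})

test_that("regridded series keeps null nodes at exactly zero in all frames", {
  set.seed(3)
  pts <- matrix(runif(500 * 3, 0, 0.5), ncol = 3)
  vels <- lapply(1:3, function(k) matrix(rnorm(1500, sd = 10), ncol = 3))
  fdm <- fdm_series(pts, vels, c(0, 2, 4))
  g <- regrid_fdm(fdm, spacing = 0.1)
  null_idx <- grid_node_indices(g)$null
  expect_true(all(g$v[null_idx, , ] == 0))
  expect_equal(sort(unique(c(null_idx, grid_node_indices(g)$flow))),
               seq_along(g$flow_mask))
})

test_that("flow-grid container round-trips and validates keys", {
  g <- pipe_field(radius = 0.3, length = 1)
  path <- tempfile(fileext = ".rds")
  save_flow_grid(g, path)
  g2 <- load_flow_grid(path)
  expect_identical(g2$x, g$x)
  expect_identical(g2$flow_mask, g$flow_mask)
  expect_equal(g2$v, g$v)
  expect_equal(g2$cycle_period, g$cycle_period)

  broken <- readRDS(path)
  broken$frame_times <- NULL
  path2 <- tempfile(fileext = ".rds")
  saveRDS(broken, path2)
  expect_error(load_flow_grid(path2), "frame_times")
})

test_that("degenerate inputs raise descriptive errors", {
  expect_error(fdm_series(matrix(numeric(0), 0, 3), list(), numeric(0)),
               "no flow points")
  pts <- matrix(runif(30), 10, 3)
  v <- list(matrix(0, 10, 3), matrix(0, 10, 3))
  expect_error(fdm_series(pts, v, c(2, 1)), "strictly increasing")
  fdm <- fdm_series(pts, v[1], 0)
  axes <- list(x = seq(0, 1, 0.1), y = seq(0, 1, 0.1), z = seq(0, 1, 0.1))
  expect_error(regrid_frame(fdm, 5, axes, 0.1), "frame_index")
})
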
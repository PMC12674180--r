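#' Uniform-grid velocity-field time series
#'
#' The central flow container: a node-centred uniform grid with one velocity
#' vector per node per frame, a boolean flow mask (identical across frames),
#' and a cycle period for periodic (cardiac-cycle) wrap-around. Velocity is
#' exactly zero at every masked-out ("null") node.
#'
#' Node order is x-fastest: node index = ix + nx*(iy + ny*iz) (1-based in R).
#'
#' @param x,y,z Uniform axis coordinates \[mm\]. All three must share the same
#'   spacing to within 1e-9 relative.
#' @param v Numeric array of dim (n_nodes, 3, n_frames): velocity \[mm/s\]
#'   per node, component (vx, vy, vz), frame.
#' @param frame_times Strictly increasing frame times \[ms\].
#' @param flow_mask Logical, length n_nodes; TRUE inside the flow.
#' @param cycle_period Cycle length \[ms\]. Defaults to
#'   `diff(range(frame_times)) + frame step` (periodic wrap enabled).
#' @param periodic Whether time samples wrap modulo `cycle_period`.
#' @return An object of class `flow_grid`.
#' @export
flow_grid <- function(x, y, z, v, frame_times, flow_mask,
                      cycle_period = NULL, periodic = TRUE) {
  x <- as.numeric(x); y <- as.numeric(y); z <- as.numeric(z)
  d <- axis_spacing(x, y, z)
  n_nodes <- length(x) * length(y) * length(z)
  if (is.null(dim(v)) || length(dim(v)) != 3L)
    abort("`v` must be an array of dim (n_nodes, 3, n_frames)")
  if (dim(v)[1] != n_nodes || dim(v)[2] != 3L)
    abort(sprintf("`v` first dims must be (%d, 3), got (%d, %d)",
                  n_nodes, dim(v)[1], dim(v)[2]))
  n_frames <- dim(v)[3]
  frame_times <- as.numeric(frame_times)
  if (length(frame_times) != n_frames)
    abort("length(frame_times) must equal the number of frames in `v`")
  if (n_frames > 1 && any(diff(frame_times) <= 0))
    abort("frame_times must be strictly increasing")
  flow_mask <- as.logical(flow_mask)
  if (length(flow_mask) != n_nodes)
    abort("flow_mask length must equal the number of grid nodes")
  if (!all(is.finite(v))) abort("velocities must be finite")
  # enforce the null-node invariant: zero velocity outside the flow
  if (any(!flow_mask)) v[!flow_mask, , ] <- 0
  step <- if (n_frames > 1) frame_times[2] - frame_times[1] else 1
  if (is.null(cycle_period))
    cycle_period <- frame_times[n_frames] - frame_times[1] + step
  structure(
    list(x = x, y = y, z = z, spacing = d, v = v,
         frame_times = frame_times, cycle_period = cycle_period,
         flow_mask = flow_mask, periodic = periodic),
    class = "flow_grid")
}

axis_spacing <- function(x, y, z) {
  steps <- c(diff(x), diff(y), diff(z))
  if (length(steps) == 0) abort("grid must have at least 2 nodes on one axis")
  d <- steps[1]
  if (any(abs(steps - d) > 1e-9 * d))
    abort("grid axes must be uniform with a common spacing")
  d
}

#' @export
print.flow_grid <- function(x, ...) {
  cat(sprintf(
    "<flow_grid> %d x %d x %d nodes (d = %g mm), %d frames over %g ms%s\n",
    length(x$x), length(x$y), length(x$z), x$spacing,
    length(x$frame_times), x$cycle_period,
    if (x$periodic) " (periodic)" else ""))
  cat(sprintf("  flow nodes: %d / %d; peak speed %.3g mm/s\n",
              sum(x$flow_mask), length(x$flow_mask),
              sqrt(max(rowSums(matrix(x$v, ncol = 3)^2)))))
  invisible(x)
}

#' Grid node coordinates
#'
#' @param grid A `flow_grid`.
#' @param which One of "all", "flow", "null".
#' @return Matrix (n x 3) of node coordinates \[mm\], x-fastest node order.
#' @export
grid_node_coords <- function(grid, which = c("all", "flow", "null")) {
  which <- match.arg(which)
  nx <- length(grid$x); ny <- length(grid$y); nz <- length(grid$z)
  coords <- cbind(
    rep(grid$x, times = ny * nz),
    rep(rep(grid$y, each = nx), times = nz),
    rep(grid$z, each = nx * ny))
  colnames(coords) <- c("x", "y", "z")
  switch(which,
         all  = coords,
         flow = coords[grid$flow_mask, , drop = FALSE],
         null = coords[!grid$flow_mask, , drop = FALSE])
}

#' Stored node index sets
#'
#' @inheritParams grid_node_coords
#' @return List with integer vectors `flow` and `null` (1-based node indices).
#' @export
grid_node_indices <- function(grid) {
  list(flow = which(grid$flow_mask), null = which(!grid$flow_mask))
}

#' Flow volume of a grid
#'
#' One grid cell volume (`d^3`) is attributed to each flow node.
#'
#' @param grid A `flow_grid`.
#' @param wavelength If given \[mm\], the volume is returned in units of
#'   wavelength cubed instead of mm^3.
#' @return Volume \[mm^3\] (or \[lambda^3\]).
#' @export
flow_volume <- function(grid, wavelength = NULL) {
  v <- sum(grid$flow_mask) * grid$spacing^3
  if (!is.null(wavelength)) v <- v / wavelength^3
  v
}

flow_bbox <- function(grid) {
  fc <- grid_node_coords(grid, "flow")
  if (nrow(fc) == 0) abort("flow mask is empty: zero flow volume")
  rbind(lo = apply(fc, 2, min), hi = apply(fc, 2, max))
}

grid_bbox <- function(grid) {
  rbind(lo = c(grid$x[1], grid$y[1], grid$z[1]),
        hi = c(tail(grid$x, 1), tail(grid$y, 1), tail(grid$z, 1)))
}

#' Save / load a flow grid
#'
#' The container is an RDS file holding a plain list with keys `xg`, `yg`,
#' `zg` (axes, mm), `V` (n_nodes x 3 x n_frames, mm/s, x-fastest node order),
#' `frame_times` (ms), `flow_mask`, and `cycle_period_ms`. Loading validates
#' the keys and names any missing one.
#'
#' @param grid A `flow_grid`.
#' @param path File path.
#' @return `load_flow_grid` returns a `flow_grid`; `save_flow_grid` returns
#'   `path` invisibly.
#' @export
save_flow_grid <- function(grid, path) {
  stopifnot(inherits(grid, "flow_grid"))
  saveRDS(list(xg = grid$x, yg = grid$y, zg = grid$z, V = grid$v,
               frame_times = grid$frame_times, flow_mask = grid$flow_mask,
               cycle_period_ms = grid$cycle_period,
               periodic = grid$periodic),
          path)
  invisible(path)
}

#' @rdname save_flow_grid
#' @export
load_flow_grid <- function(path) {
  obj <- readRDS(path)
  needed <- c("xg", "yg", "zg", "V", "frame_times", "flow_mask",
              "cycle_period_ms")
  missing <- setdiff(needed, names(obj))
  if (length(missing) > 0)
    abort(sprintf("flow-grid container is missing dataset(s): %s",
                  paste(missing, collapse = ", ")))
  flow_grid(obj$xg, obj$yg, obj$zg, obj$V, obj$frame_times, obj$flow_mask,
            cycle_period = obj$cycle_period_ms,
            periodic = if (is.null(obj$periodic)) TRUE else obj$periodic)
}
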
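#' Non-uniform flow-domain-model time series
#'
#' Holds the raw output of a computational flow model: scattered mesh points
#' and one velocity vector per point per frame. This is the input to
#' [regrid_fdm()], which aligns it onto a uniform grid.
#'
#' @param points Matrix (n x 3) of mesh point coordinates \[mm\].
#' @param velocities List of length n_frames; each element an (n x 3) matrix
#'   of velocities \[mm/s\] aligned with `points`.
#' @param frame_times Strictly increasing frame times \[ms\].
#' @return An object of class `fdm_series`.
#' @export
fdm_series <- function(points, velocities, frame_times) {
  points <- as.matrix(points)
  if (nrow(points) == 0) abort("no flow points")
  if (ncol(points) != 3) abort("`points` must be an n x 3 matrix")
  if (!is.list(velocities)) velocities <- list(velocities)
  frame_times <- as.numeric(frame_times)
  if (length(velocities) != length(frame_times))
    abort("one velocity frame required per frame time")
  if (length(frame_times) > 1 && any(diff(frame_times) <= 0))
    abort("frame_times must be strictly increasing")
  for (k in seq_along(velocities)) {
    velocities[[k]] <- as.matrix(velocities[[k]])
    if (!all(dim(velocities[[k]]) == c(nrow(points), 3)))
      abort(sprintf("frame %d velocities must be %d x 3", k, nrow(points)))
    if (!all(is.finite(velocities[[k]])))
      abort(sprintf("frame %d has non-finite velocities", k))
  }
  structure(list(points = points, velocities = velocities,
                 frame_times = frame_times,
                 n_frames = length(frame_times)),
            class = "fdm_series")
}

#' @export
print.fdm_series <- function(x, ...) {
  cat(sprintf("<fdm_series> %d mesh points, %d frames over [%g, %g] ms\n",
              nrow(x$points), x$n_frames, x$frame_times[1],
              tail(x$frame_times, 1)))
  invisible(x)
}

#' Default uniform axes covering an FDM point cloud
#'
#' Axes are snapped to multiples of `spacing` and extended by `margin` cells
#' beyond the point bounding box so that a shell of null nodes surrounds the
#' flow.
#'
#' @param points Matrix (n x 3) \[mm\].
#' @param spacing Grid spacing d \[mm\].
#' @param margin Extra cells beyond the bounding box on each side.
#' @return List of axes `x`, `y`, `z`.
#' @export
default_grid_axes <- function(points, spacing, margin = 2L) {
  lapply(setNames(1:3, c("x", "y", "z")), function(a) {
    lo <- floor(min(points[, a]) / spacing) * spacing - margin * spacing
    hi <- ceiling(max(points[, a]) / spacing) * spacing + margin * spacing
    seq(lo, hi, by = spacing)
  })
}

#' Classify uniform-grid nodes as flow or null
#'
#' A grid node is null iff its distance to the nearest FDM flow point
#' exceeds `factor * spacing`. The default factor 1.5 puts the threshold at
#' 3d/2. Null nodes are later appended to the interpolation source set with
#' zero velocity so that the regridded field decays to zero at the flow
#' boundary; both index sets are stored on the resulting grid for reuse by
#' the tracker.
#'
#' @param points FDM mesh points, matrix (n x 3) \[mm\].
#' @param grid_axes List with axes `x`, `y`, `z` (uniform, spacing `spacing`).
#' @param spacing Grid spacing d \[mm\].
#' @param factor Threshold multiple of d (default 1.5).
#' @return List with integer node-index vectors `null` and `flow`
#'   (1-based, x-fastest node order) and the logical `flow_mask`.
#' @export
append_null_points <- function(points, grid_axes, spacing, factor = 1.5) {
  points <- as.matrix(points)
  if (nrow(points) == 0) abort("no flow points")
  stopifnot(factor > 0)
  nodes <- axes_node_coords(grid_axes)
  d_near <- .cpp_nn_dist(nodes, points, cell = spacing)
  mask <- d_near <= factor * spacing
  list(null = which(!mask), flow = which(mask), flow_mask = mask)
}

axes_node_coords <- function(grid_axes) {
  nx <- length(grid_axes$x); ny <- length(grid_axes$y); nz <- length(grid_axes$z)
  cbind(rep(grid_axes$x, times = ny * nz),
        rep(rep(grid_axes$y, each = nx), times = nz),
        rep(grid_axes$z, each = nx * ny))
}

#' Regrid one FDM frame onto a uniform grid
#'
#' Scattered-data linear interpolation of one velocity frame onto the grid
#' nodes, after appending zero-velocity null points outside the flow (see
#' [append_null_points()]). The interpolant is a local linear least-squares
#' fit over the `k` nearest source points, which reproduces affine fields
#' exactly; nodes in the null set get exactly zero velocity.
#'
#' @inheritParams append_null_points
#' @param fdm An [fdm_series()].
#' @param frame_index Frame to interpolate (1-based).
#' @param k Neighbourhood size for the local fit.
#' @param classes Optional precomputed result of [append_null_points()].
#' @return Matrix (n_nodes x 3) of velocities \[mm/s\], x-fastest node order.
#' @export
regrid_frame <- function(fdm, frame_index, grid_axes, spacing,
                         factor = 1.5, k = 12L, classes = NULL) {
  stopifnot(inherits(fdm, "fdm_series"))
  if (frame_index < 1 || frame_index > fdm$n_frames)
    abort(sprintf("frame_index must be in 1..%d", fdm$n_frames))
  nodes <- axes_node_coords(grid_axes)
  if (is.null(classes))
    classes <- append_null_points(fdm$points, grid_axes, spacing, factor)
  null_coords <- nodes[classes$null, , drop = FALSE]
  src <- rbind(fdm$points, null_coords)
  val <- rbind(fdm$velocities[[frame_index]],
               matrix(0, nrow(null_coords), 3))
  out <- matrix(0, nrow(nodes), 3)
  flow_idx <- classes$flow
  if (length(flow_idx) > 0) {
    out[flow_idx, ] <- .cpp_regrid_lls(
      src, val, nodes[flow_idx, , drop = FALSE],
      k = as.integer(k), cell = spacing)
  }
  out
}

#' Regrid a whole FDM time series onto a uniform flow grid
#'
#' Applies [regrid_frame()] to every frame and assembles a [flow_grid()]
#' with the derived flow mask and stored node index sets.
#'
#' @inheritParams regrid_frame
#' @param cycle_period Cycle length \[ms\]; defaults to the frame span plus
#'   one frame step (periodic wrap).
#' @param periodic Whether the series wraps in time.
#' @return A [flow_grid()].
#' @export
regrid_fdm <- function(fdm, spacing = 0.1, grid_axes = NULL, factor = 1.5,
                       k = 12L, cycle_period = NULL, periodic = TRUE) {
  stopifnot(inherits(fdm, "fdm_series"))
  if (is.null(grid_axes))
    grid_axes <- default_grid_axes(fdm$points, spacing)
  classes <- append_null_points(fdm$points, grid_axes, spacing, factor)
  n_nodes <- length(grid_axes$x) * length(grid_axes$y) * length(grid_axes$z)
  v <- array(0, dim = c(n_nodes, 3, fdm$n_frames))
  for (m in seq_len(fdm$n_frames)) {
    v[, , m] <- regrid_frame(fdm, m, grid_axes, spacing, factor, k,
                             classes = classes)
  }
  flow_grid(grid_axes$x, grid_axes$y, grid_axes$z, v, fdm$frame_times,
            classes$flow_mask, cycle_period = cycle_period,
            periodic = periodic)
}
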
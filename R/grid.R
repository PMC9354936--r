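#' Define a regular N-dimensional state-space grid
#'
#' The grid discretizes the state space of an N-dimensional neuron (or other
#' ODE) model into `prod(resolution)` identical half-open boxes. By
#' convention the membrane potential is always the LAST dimension; the
#' threshold and reset values refer to that dimension. Cell `i` along
#' dimension `d` spans `[base_d + i*cw_d, base_d + (i+1)*cw_d)` where
#' `cw_d = extent_d / resolution_d`. Cell and dimension indices are 0-based
#' throughout the package, matching the on-disk file formats and the XML
#' dialect.
#'
#' @param base numeric vector; per-dimension minimum of the grid, in model
#'   units (e.g. nS/cm^2 for conductances, mV for the potential).
#' @param extent numeric vector; per-dimension span of the grid (> 0).
#' @param resolution integer vector; per-dimension cell counts (>= 1).
#' @param threshold membrane-potential threshold (mV) in the last dimension,
#'   or `NULL` for a model without a threshold-reset mechanism.
#' @param reset membrane-potential reset value (mV); required when
#'   `threshold` is given, and must satisfy `reset < threshold`.
#' @param reset_shift numeric vector; additive per-dimension shift applied to
#'   a neuron's state on reset (model units). Defaults to no shift.
#' @param timescale seconds per model time unit. The built-in models express
#'   their derivatives per millisecond, so they use `timescale = 1e-3`; a
#'   model written in seconds uses `timescale = 1`.
#' @param time_step simulation time step in seconds.
#' @return An object of class `grid_spec`.
#' @examples
#' g <- grid_spec(base = c(-0.2, -0.2, -80), extent = c(5.4, 5.4, 40),
#'                resolution = c(50, 50, 50), threshold = -50.4,
#'                reset = -70.6, timescale = 1e-3, time_step = 1e-3)
#' n_cells(g)
#' @export
grid_spec <- function(base, extent, resolution, threshold = NULL,
                      reset = NULL, reset_shift = NULL, timescale = 1,
                      time_step = 1e-3) {
  base <- as.numeric(base)
  extent <- as.numeric(extent)
  resolution <- as.integer(resolution)
  n <- length(base)
  if (n < 1L) stop("grid must have at least one dimension")
  if (length(extent) != n || length(resolution) != n)
    stop("base, extent and resolution must have equal length")
  if (any(!is.finite(base)) || any(!is.finite(extent)))
    stop("grid base/extent must be finite")
  if (any(extent <= 0)) stop("all extents must be strictly positive")
  if (any(resolution < 1L)) stop("all resolutions must be >= 1")
  if (is.null(reset_shift)) reset_shift <- numeric(n)
  reset_shift <- as.numeric(reset_shift)
  if (length(reset_shift) != n)
    stop("reset_shift must have one entry per dimension")
  if (!is.numeric(timescale) || timescale <= 0)
    stop("timescale must be a positive number (seconds per model time unit)")
  if (!is.numeric(time_step) || time_step <= 0)
    stop("time_step must be positive (seconds)")
  cw <- extent / resolution
  if (any(cw <= 0)) stop("all cell widths must be strictly positive")
  vlo <- base[n]
  vhi <- base[n] + extent[n]
  if (!is.null(threshold)) {
    if (is.null(reset)) stop("reset must be given when threshold is given")
    if (threshold < vlo || threshold > vhi)
      stop("threshold must lie inside the last-dimension range [",
           vlo, ", ", vhi, "]")
    if (reset < vlo || reset > vhi)
      stop("reset must lie inside the last-dimension range")
    if (reset >= threshold) stop("reset must be below threshold")
  }
  structure(list(n_dims = n, base = base, extent = extent,
                 resolution = resolution, cell_width = cw,
                 threshold_value = if (is.null(threshold)) NA_real_ else threshold,
                 reset_value = if (is.null(reset)) NA_real_ else reset,
                 reset_shift = reset_shift, timescale = timescale,
                 time_step = time_step),
            class = "grid_spec")
}

#' @export
print.grid_spec <- function(x, ...) {
  cat("grid_spec:", x$n_dims, "dimensions,",
      format(n_cells(x), big.mark = ","), "cells\n")
  for (d in seq_len(x$n_dims)) {
    cat(sprintf("  dim %d: [%g, %g) in %d cells of width %g\n", d - 1L,
                x$base[d], x$base[d] + x$extent[d], x$resolution[d],
                x$cell_width[d]))
  }
  if (!is.na(x$threshold_value))
    cat(sprintf("  threshold %g / reset %g (last dimension)\n",
                x$threshold_value, x$reset_value))
  cat(sprintf("  time step %g s, timescale %g s per model unit\n",
              x$time_step, x$timescale))
  invisible(x)
}

#' Number of cells in a grid
#' @param grid a [grid_spec()].
#' @return integer cell count `prod(resolution)`.
#' @export
n_cells <- function(grid) prod(grid$resolution)

stopifnot_grid <- function(grid) {
  if (!inherits(grid, "grid_spec")) stop("expected a grid_spec object")
  invisible(grid)
}

#' Convert between multi-indices and flat cell indices
#'
#' Flat indices are row-major with the last dimension varying fastest, and
#' both index forms are 0-based. `flat_index` accepts a matrix of
#' multi-indices (one row per cell); `multi_index` accepts a vector of flat
#' indices and returns a matrix.
#'
#' @param grid a [grid_spec()].
#' @param multi integer vector (one cell) or matrix (rows = cells) of
#'   0-based per-dimension indices.
#' @return `flat_index`: 0-based integer vector. `multi_index`: integer
#'   matrix with one row per flat index.
#' @export
flat_index <- function(grid, multi) {
  stopifnot_grid(grid)
  if (is.null(dim(multi))) multi <- matrix(as.integer(multi), nrow = 1L)
  storage.mode(multi) <- "integer"
  if (ncol(multi) != grid$n_dims) stop("multi-index has wrong length")
  if (any(multi < 0L) || any(sweep(multi, 2, grid$resolution, `>=`)))
    stop("cell index out of range")
  flat <- rep(0, nrow(multi))
  for (d in seq_len(grid$n_dims)) flat <- flat * grid$resolution[d] + multi[, d]
  as.integer(flat)
}

#' @rdname flat_index
#' @param flat 0-based integer vector of flat cell indices.
#' @export
multi_index <- function(grid, flat) {
  stopifnot_grid(grid)
  flat <- as.integer(flat)
  if (any(flat < 0L) || any(flat >= n_cells(grid)))
    stop("flat index out of range")
  out <- matrix(0L, nrow = length(flat), ncol = grid$n_dims)
  rem <- flat
  for (d in rev(seq_len(grid$n_dims))) {
    out[, d] <- rem %% grid$resolution[d]
    rem <- rem %/% grid$resolution[d]
  }
  out
}

#' Coordinates of cell centers
#' @param grid a [grid_spec()].
#' @param flat 0-based flat cell indices.
#' @return numeric matrix, one row of center coordinates per index.
#' @export
cell_centers <- function(grid, flat) {
  m <- multi_index(grid, flat)
  sweep(sweep(m + 0.5, 2, grid$cell_width, `*`), 2, grid$base, `+`)
}

#' Locate the cell containing a point
#'
#' Cells are half-open, so a point exactly on a shared edge belongs to the
#' cell whose lower edge it sits on. Points outside the grid raise an error
#' unless `clamp = TRUE`.
#'
#' @param grid a [grid_spec()].
#' @param point numeric state vector (or matrix, rows = points).
#' @param clamp clamp out-of-grid coordinates to the nearest boundary cell?
#' @return 0-based flat cell indices.
#' @export
locate_cell <- function(grid, point, clamp = FALSE) {
  stopifnot_grid(grid)
  if (is.null(dim(point))) point <- matrix(point, nrow = 1L)
  if (ncol(point) != grid$n_dims) stop("point has wrong dimension")
  idx <- floor(sweep(sweep(point, 2, grid$base, `-`), 2, grid$cell_width, `/`))
  if (clamp) {
    idx <- pmax(idx, 0)
    idx <- sweep(idx, 2, grid$resolution - 1L, pmin)
  } else if (any(idx < 0) || any(sweep(idx, 2, grid$resolution, `>=`))) {
    stop("point lies outside the grid")
  }
  flat_index(grid, idx)
}

#' Corner points of a grid cell
#'
#' Returns the `2^N` corners of the axis-aligned cell in binary counting
#' order over dimensions with the last dimension varying fastest: row `k`
#' (0-based) takes the upper corner along dimension `d` iff bit `N-1-d` of
#' `k` is set.
#'
#' @param grid a [grid_spec()].
#' @param index 0-based multi-index (length-N integer vector) of the cell.
#' @return a `2^N x N` numeric matrix of corner coordinates.
#' @examples
#' g <- grid_spec(c(0, 0), c(1, 2), c(1, 1))
#' cell_vertices(g, c(0, 0))
#' @export
cell_vertices <- function(grid, index) {
  stopifnot_grid(grid)
  index <- as.integer(index)
  if (length(index) != grid$n_dims) stop("cell index has wrong length")
  if (any(index < 0L) || any(index >= grid$resolution))
    stop("cell index out of range")
  n <- grid$n_dims
  corners <- unit_cube_corners(n)
  lower <- grid$base + index * grid$cell_width
  sweep(sweep(corners, 2, grid$cell_width, `*`), 2, lower, `+`)
}

#' Corners of the unit N-cube in canonical order
#' @param n_dims dimension N >= 1.
#' @return a `2^N x N` 0/1 matrix; row order is binary counting with the
#'   last dimension varying fastest.
#' @export
unit_cube_corners <- function(n_dims) {
  n <- as.integer(n_dims)
  if (n < 1L) stop("n_dims must be >= 1")
  codes <- 0:(2^n - 1L)
  out <- matrix(0, nrow = 2^n, ncol = n)
  for (d in seq_len(n)) {
    out[, d] <- bitwAnd(bitwShiftR(codes, n - d), 1L)
  }
  out
}

# deterministic FNV-1a hash of the grid geometry; guards model/matrix pairing
grid_checksum <- function(grid) {
  stopifnot_grid(grid)
  s <- paste(c(grid$n_dims, sprintf("%.12g", grid$base),
               sprintf("%.12g", grid$extent), grid$resolution,
               sprintf("%.12g", grid$threshold_value),
               sprintf("%.12g", grid$reset_value),
               sprintf("%.12g", grid$reset_shift),
               sprintf("%.12g", grid$timescale),
               sprintf("%.12g", grid$time_step)), collapse = "|")
  bytes <- utf8ToInt(s)
  h <- 2166136261
  for (b in bytes) {
    lo <- h %% 256
    h <- h - lo + bitwXor(as.integer(lo), as.integer(b))
    # 32-bit FNV prime multiply, split so all intermediates stay exact doubles
    h <- (h * 403 + (h %% 2^16) * 16777216) %% 2^32
  }
  paste0(sprintf("%04x", as.integer(h %/% 65536)),
         sprintf("%04x", as.integer(h %% 65536)))
}
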
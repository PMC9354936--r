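#' @useDynLib popgrid, .registration = TRUE
#' @importFrom Rcpp sourceCpp
#' @importFrom methods as new
#' @importFrom stats rpois runif
#' @importFrom Matrix sparseMatrix Diagonal colSums
NULL

# Accepts a derivative function written either for a single state vector or
# already vectorized over a matrix of states (rows = states), and returns the
# vectorized form. The contract: dimension order matches the grid, membrane
# potential last; output finite for every in-grid state.
as_vectorized_deriv <- function(deriv, n_dims, probe = NULL) {
  if (!is.function(deriv)) stop("deriv must be a function")
  if (is.null(probe)) probe <- matrix(0, nrow = 2L, ncol = n_dims)
  out <- tryCatch(deriv(probe), error = function(e) NULL)
  if (is.matrix(out) && all(dim(out) == dim(probe))) return(deriv)
  function(y) t(apply(y, 1L, deriv))
}

# Explicit Euler over `substeps` equal sub-intervals of dt_model; points is a
# matrix (rows = states). Coordinates are kept inside the grid range padded
# by two cell widths: model functions are then never evaluated at states
# wildly outside their intended domain (where, e.g., the Hodgkin-Huxley
# rate functions overflow), and any mass carried past the padding belongs
# to the boundary cells it is clamped to during scattering anyway.
euler_advance <- function(points, vderiv, dt_model, substeps, grid) {
  h <- dt_model / substeps
  lo <- matrix(grid$base - 2 * grid$cell_width, nrow = nrow(points),
               ncol = grid$n_dims, byrow = TRUE)
  hi <- matrix(grid$base + grid$extent + 2 * grid$cell_width,
               nrow = nrow(points), ncol = grid$n_dims, byrow = TRUE)
  for (k in seq_len(substeps)) {
    d <- vderiv(points)
    if (any(!is.finite(d)))
      stop("non-finite derivative encountered during vertex transform")
    points <- points + h * d
    points <- pmin(pmax(points, lo), hi)
  }
  points
}

#' Advance the corners of one grid cell by a single time step
#'
#' Translates the `2^N` cell corners along the model flow using explicit
#' Euler with `substeps` equal sub-intervals of the grid's time step, the
#' same integrator used during transition-matrix generation. The model time
#' step is `time_step / timescale` model units.
#'
#' @param grid a [grid_spec()].
#' @param index 0-based multi-index of the cell.
#' @param deriv derivative function: maps a length-N state vector (or a
#'   matrix with rows = states) to its time derivative in model units per
#'   model time unit.
#' @param dt time step in seconds; defaults to the grid's `time_step`.
#' @param substeps number of Euler sub-intervals (>= 1).
#' @return a `2^N x N` matrix of transformed corner points.
#' @export
transform_cell <- function(grid, index, deriv, dt = grid$time_step,
                           substeps = 10L) {
  stopifnot_grid(grid)
  if (dt <= 0) stop("dt must be positive")
  substeps <- as.integer(substeps)
  if (substeps < 1L) stop("substeps must be >= 1")
  verts <- cell_vertices(grid, index)
  vd <- as_vectorized_deriv(deriv, grid$n_dims, probe = verts)
  out <- tryCatch(
    euler_advance(verts, vd, dt / grid$timescale, substeps, grid),
    error = function(e) stop("cell [", paste(index, collapse = ","), "]: ",
                             conditionMessage(e)))
  out
}

#' Precompute the deterministic-dynamics transition matrix
#'
#' For every cell of the grid the corner points are advanced by one time
#' step of the model, the Kuhn triangulation of the unit cube is mapped onto
#' the transformed corners, and each simplex is recursively subdivided
#' against the grid hyperplanes; the per-cell volume fractions become one
#' row of the (sparse, row-stochastic) transition matrix. Because the model
#' does not change during a simulation the matrix is computed once and
#' reused every step. Mass leaving the grid is clamped to the nearest
#' boundary cell. Generation is deterministic: identical inputs give
#' identical matrices.
#'
#' Corner points shared between neighbouring cells are transformed once, so
#' the model function is evaluated on `prod(resolution + 1)` points per
#' Euler substep.
#'
#' @inheritParams transform_cell
#' @param drop_tol row entries below this proportion are dropped and the row
#'   renormalized (file size; no measurable dynamical effect).
#' @param model_name name stored in the matrix metadata.
#' @param max_pieces per-cell cap on subdivision pieces. Transformed cells
#'   in unreachable corners of the state space can be stretched across a
#'   volume-proportional number of cells (the model flow there is extreme);
#'   beyond the cap their remaining simplices are assigned whole to their
#'   centroid cell, keeping generation tractable while conserving mass
#'   exactly. Ordinary cells use a few dozen pieces and are unaffected.
#' @return an object of class `transition_matrix` with elements `grid`,
#'   `Tt` (a `dgCMatrix` holding the transpose: entry `[target, source]` is
#'   the proportion moved), `substeps`, `model_name`, `checksum`.
#' @export
generate_deterministic_matrix <- function(grid, deriv, dt = grid$time_step,
                                          substeps = 10L, drop_tol = 1e-12,
                                          model_name = "model",
                                          max_pieces = 4096L) {
  stopifnot_grid(grid)
  if (dt <= 0) stop("dt must be positive")
  substeps <- as.integer(substeps)
  if (substeps < 1L) stop("substeps must be >= 1")
  n <- grid$n_dims
  lat <- grid$resolution + 1L
  npts <- prod(lat)
  pts <- matrix(0, nrow = npts, ncol = n)
  stride <- rev(cumprod(rev(c(lat[-1L], 1L))))
  seq0 <- 0:(npts - 1L)
  for (d in seq_len(n)) {
    idx <- (seq0 %/% stride[d]) %% lat[d]
    pts[, d] <- grid$base[d] + grid$cell_width[d] * idx
  }
  vd <- as_vectorized_deriv(deriv, n, probe = pts[1:2, , drop = FALSE])
  pts <- euler_advance(pts, vd, dt / grid$timescale, substeps, grid)
  tri <- triangulate_unit_hypercube(n)
  trip <- cpp_generate_transitions(pts, grid$resolution, grid$base,
                                   grid$cell_width, tri, drop_tol,
                                   as.integer(max_pieces))
  if (trip$n_nonconvex > 0L)
    warning(trip$n_nonconvex, " transformed cell(s) had a triangulated ",
            "volume deviating >20% from the cell volume (convexity ",
            "assumption strained; consider a smaller time step)")
  nc <- n_cells(grid)
  Tt <- Matrix::sparseMatrix(i = trip$target + 1L, j = trip$source + 1L,
                             x = trip$proportion, dims = c(nc, nc))
  structure(list(grid = grid, Tt = Tt, substeps = substeps,
                 model_name = model_name, checksum = grid_checksum(grid)),
            class = "transition_matrix")
}

#' @export
print.transition_matrix <- function(x, ...) {
  cat("transition_matrix:", x$model_name, "-",
      format(length(x$Tt@x), big.mark = ","), "entries over",
      format(ncol(x$Tt), big.mark = ","), "cells (",
      sprintf("%.2f", length(x$Tt@x) / ncol(x$Tt)), "per row )\n")
  invisible(x)
}

#' Apply one deterministic step to a mass vector
#' @param tm a [generate_deterministic_matrix()] result.
#' @param mass numeric mass vector over cells.
#' @return updated mass vector.
#' @export
apply_deterministic <- function(tm, mass) {
  if (!inherits(tm, "transition_matrix")) stop("expected a transition_matrix")
  if (length(mass) != ncol(tm$Tt)) stop("mass vector has wrong length")
  as.numeric(tm$Tt %*% mass)
}

#' Precompute the threshold-to-reset cell mapping
#'
#' The threshold layer consists of every cell whose last-dimension interval
#' has its lower edge at or above the threshold value (for a 3-D grid this
#' is a two-dimensional sheet of cells, one per conductance-index pair).
#' Each such cell maps to the cell whose last-dimension index contains
#' `reset_value + reset_shift[N]`, with the remaining indices preserved and
#' shifted by the per-dimension offsets implied by `reset_shift`, clamped to
#' the grid.
#'
#' @param grid a [grid_spec()] with threshold/reset defined.
#' @return data.frame with 0-based columns `source` and `target` (flat cell
#'   indices), one row per threshold-layer cell.
#' @export
build_reset_mapping <- function(grid) {
  stopifnot_grid(grid)
  if (is.na(grid$threshold_value))
    stop("grid has no threshold/reset configured")
  n <- grid$n_dims
  cw <- grid$cell_width
  thr_lo <- ceiling((grid$threshold_value - grid$base[n]) / cw[n] - 1e-9)
  if (thr_lo >= grid$resolution[n])
    stop("threshold layer lies outside the grid")
  thr_idx <- seq.int(max(thr_lo, 0L), grid$resolution[n] - 1L)
  reset_v <- grid$reset_value + grid$reset_shift[n]
  if (reset_v < grid$base[n] || reset_v >= grid$base[n] + grid$extent[n])
    stop("reset value (plus shift) lies outside the grid")
  reset_idx <- floor((reset_v - grid$base[n]) / cw[n])
  off <- round(grid$reset_shift / cw)
  off[n] <- 0
  # enumerate all source cells: every index combination in dims 1..N-1
  # crossed with the threshold-layer indices in dim N
  other <- lapply(seq_len(n - 1L), function(d) 0:(grid$resolution[d] - 1L))
  src_multi <- as.matrix(expand.grid(c(other, list(v = thr_idx)),
                                     KEEP.OUT.ATTRS = FALSE))
  colnames(src_multi) <- NULL
  tgt_multi <- src_multi
  if (n > 1L) {
    for (d in seq_len(n - 1L)) {
      tgt_multi[, d] <- pmin(pmax(src_multi[, d] + off[d], 0L),
                             grid$resolution[d] - 1L)
    }
  }
  tgt_multi[, n] <- reset_idx
  data.frame(source = flat_index(grid, src_multi),
             target = flat_index(grid, tgt_multi))
}

# ---- model / matrix file formats -------------------------------------------
# Plain-text, deterministic, round-trip stable. The matrix file carries the
# grid checksum so a matrix can never be paired with the wrong grid.

#' Write and read grid ("model") files
#'
#' The model file is a plain-text key-value header describing the grid:
#' `n_dims`, `base`, `extent`, `resolution`, `threshold`, `reset`,
#' `reset_shift`, `timescale`, `time_step`, plus the grid checksum. The
#' round trip `read_model_file(write_model_file(g))` reproduces the grid
#' exactly.
#'
#' @param grid a [grid_spec()].
#' @param path output file path.
#' @return `write_model_file`: invisibly, `path`. `read_model_file`: a
#'   [grid_spec()].
#' @export
write_model_file <- function(grid, path) {
  stopifnot_grid(grid)
  num <- function(x) paste(sprintf("%.17g", x), collapse = " ")
  lines <- c("popgrid-model v1",
             paste("checksum", grid_checksum(grid)),
             paste("n_dims", grid$n_dims),
             paste("base", num(grid$base)),
             paste("extent", num(grid$extent)),
             paste("resolution", paste(grid$resolution, collapse = " ")),
             paste("threshold", num(grid$threshold_value)),
             paste("reset", num(grid$reset_value)),
             paste("reset_shift", num(grid$reset_shift)),
             paste("timescale", num(grid$timescale)),
             paste("time_step", num(grid$time_step)))
  writeLines(lines, path)
  invisible(path)
}

#' @rdname write_model_file
#' @export
read_model_file <- function(path) {
  lines <- readLines(path)
  if (length(lines) < 2L || lines[1L] != "popgrid-model v1")
    stop("not a popgrid model file: ", path)
  kv <- strsplit(lines[-1L], " +")
  keys <- vapply(kv, `[`, "", 1L)
  val <- function(key) {
    i <- match(key, keys)
    if (is.na(i)) stop("model file is missing field '", key, "'")
    as.numeric(kv[[i]][-1L])
  }
  thr <- val("threshold")
  rst <- val("reset")
  g <- grid_spec(base = val("base"), extent = val("extent"),
                 resolution = val("resolution"),
                 threshold = if (is.na(thr)) NULL else thr,
                 reset = if (is.na(rst)) NULL else rst,
                 reset_shift = val("reset_shift"),
                 timescale = val("timescale"), time_step = val("time_step"))
  stored <- kv[[match("checksum", keys)]][2L]
  if (!identical(stored, grid_checksum(g)))
    stop("model file checksum mismatch (corrupted file?): ", path)
  g
}

#' Write and read transition-matrix files
#'
#' Text format: a header `popgrid-tmat v1 checksum <hex> cells <count>`
#' followed by one line per source cell, `flat_index n (target proportion)`
#' repeated `n` times. Writing is deterministic (17 significant digits), so
#' regenerating a matrix from identical inputs reproduces the file byte for
#' byte. On read the checksum must match the supplied grid.
#'
#' @param tm a `transition_matrix`.
#' @param path file path.
#' @param grid the [grid_spec()] the matrix is expected to pair with.
#' @return `write_matrix_file`: invisibly `path`; `read_matrix_file`: a
#'   `transition_matrix`.
#' @export
write_matrix_file <- function(tm, path) {
  if (!inherits(tm, "transition_matrix")) stop("expected a transition_matrix")
  Tt <- tm$Tt
  nc <- ncol(Tt)
  p <- Tt@p
  con <- file(path, open = "wt")
  on.exit(close(con))
  writeLines(sprintf("popgrid-tmat v1 checksum %s cells %d substeps %d name %s",
                     tm$checksum, nc, tm$substeps, tm$model_name), con)
  out <- character(nc)
  for (j in seq_len(nc)) {
    k <- (p[j] + 1L):p[j + 1L]
    if (p[j + 1L] == p[j]) {
      out[j] <- sprintf("%d 0", j - 1L)
    } else {
      out[j] <- paste(j - 1L, length(k),
                      paste(Tt@i[k], sprintf("%.17g", Tt@x[k]),
                            collapse = " "))
    }
  }
  writeLines(out, con)
  invisible(path)
}

#' @rdname write_matrix_file
#' @export
read_matrix_file <- function(path, grid) {
  stopifnot_grid(grid)
  con <- file(path, open = "rt")
  on.exit(close(con))
  header <- readLines(con, n = 1L)
  hdr <- strsplit(header, " +")[[1L]]
  if (length(hdr) < 6L || hdr[1L] != "popgrid-tmat")
    stop("not a popgrid matrix file: ", path)
  checksum <- hdr[4L]
  nc <- as.integer(hdr[6L])
  if (!identical(checksum, grid_checksum(grid)))
    stop("matrix file was generated for a different grid ",
         "(checksum mismatch): ", path)
  if (nc != n_cells(grid)) stop("matrix cell count does not match grid")
  substeps <- as.integer(hdr[8L])
  model_name <- hdr[10L]
  lines <- readLines(con)
  if (length(lines) != nc) stop("truncated matrix file: ", path)
  toks <- strsplit(lines, " ", fixed = TRUE)
  counts <- vapply(toks, function(t) as.integer(t[2L]), 0L)
  srcs <- vapply(toks, function(t) as.integer(t[1L]), 0L)
  total <- sum(counts)
  i <- integer(total)
  j <- integer(total)
  x <- numeric(total)
  pos <- 1L
  for (r in seq_len(nc)) {
    nk <- counts[r]
    if (nk == 0L) next
    t <- toks[[r]]
    sel <- seq.int(3L, by = 2L, length.out = nk)
    i[pos:(pos + nk - 1L)] <- as.integer(t[sel])
    x[pos:(pos + nk - 1L)] <- as.numeric(t[sel + 1L])
    j[pos:(pos + nk - 1L)] <- srcs[r]
    pos <- pos + nk
  }
  Tt <- Matrix::sparseMatrix(i = i + 1L, j = j + 1L, x = x, dims = c(nc, nc))
  structure(list(grid = grid, Tt = Tt, substeps = substeps,
                 model_name = model_name, checksum = checksum),
            class = "transition_matrix")
}

#' Generate the support files for a population grid
#'
#' Mirror of the usual one-call workflow: given a model function and the
#' grid geometry, computes the deterministic transition matrix and writes
#' `<name>.model` and `<name>.tmat` into `dir`.
#'
#' @param deriv model derivative function (see [transform_cell()]).
#' @param name base name for the generated files.
#' @param base,extent,resolution grid geometry, per dimension (membrane
#'   potential last).
#' @param threshold,reset threshold and reset potentials (mV).
#' @param reset_shift per-dimension additive state change applied on reset.
#' @param timescale seconds per model time unit (1e-3 for ms-based models).
#' @param time_step simulation time step in seconds.
#' @param dir output directory.
#' @param substeps Euler sub-intervals per time step.
#' @return invisibly, a list with the `grid`, the `transition_matrix` and
#'   the two file paths.
#' @export
generate_nd_grid <- function(deriv, name, base, extent, resolution,
                             threshold, reset, reset_shift = NULL,
                             timescale = 1e-3, time_step = 1e-3,
                             dir = ".", substeps = 10L) {
  grid <- grid_spec(base, extent, resolution, threshold = threshold,
                    reset = reset, reset_shift = reset_shift,
                    timescale = timescale, time_step = time_step)
  tm <- generate_deterministic_matrix(grid, deriv, substeps = substeps,
                                      model_name = name)
  model_path <- file.path(dir, paste0(name, ".model"))
  tmat_path <- file.path(dir, paste0(name, ".tmat"))
  write_model_file(grid, model_path)
  write_matrix_file(tm, tmat_path)
  invisible(list(grid = grid, matrix = tm, model_file = model_path,
                 matrix_file = tmat_path))
}
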
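# Shared fixtures and oracles, all built in code at test time.

# cache for expensive artifacts shared between test files (transition
# matrices are deterministic, so reuse is safe)
.popgrid_cache <- new.env(parent = emptyenv())

cached <- function(key, expr) {
  if (!exists(key, envir = .popgrid_cache)) {
    assign(key, force(expr), envir = .popgrid_cache)
  }
  get(key, envir = .popgrid_cache)
}

cond3d_inputs_5050 <- function() {
  data.frame(rate = c(50, 50), num_connections = 1, efficacy = 1.5,
             dimension = c(1, 0))
}

# conductance-LIF transition matrix at a given cubic resolution
cached_cond3d_tm <- function(r) {
  cached(paste0("cond3d_tm_", r), {
    generate_deterministic_matrix(cond3d_grid(c(r, r, r)), cond3d_derivative)
  })
}

# simplices of a (possibly sheared) cell image, from its 2^N corner points
cell_image_simplices <- function(corners) {
  n <- ncol(corners)
  tri <- triangulate_unit_hypercube(n)
  lapply(seq_len(nrow(tri)), function(r) corners[tri[r, ] + 1L, , drop = FALSE])
}

# Monte Carlo scatter oracle: sample points uniformly in the unit cube, map
# them through the same affine map that produced the transformed corners,
# and histogram the (boundary-clamped) cells they land in. Independent of
# the simplex-subdivision path.
scatter_sampling_oracle <- function(grid, affine_map, n_points = 1e6) {
  n <- grid$n_dims
  u <- matrix(runif(n_points * n), ncol = n)
  pts <- affine_map(u)
  idx <- floor(sweep(sweep(pts, 2, grid$base, `-`), 2, grid$cell_width, `/`))
  idx <- pmax(idx, 0)
  idx <- sweep(idx, 2, grid$resolution - 1L, pmin)
  flat <- rep(0, nrow(idx))
  for (d in seq_len(n)) flat <- flat * grid$resolution[d] + idx[, d]
  counts <- table(flat)
  data.frame(flat_index = as.integer(names(counts)),
             fraction = as.numeric(counts) / n_points)
}

# an affine cell image: unit cube corners mapped by x -> A x + b
affine_cell_corners <- function(n, A, b) {
  corners <- unit_cube_corners(n)
  sweep(corners %*% t(A), 2, b, `+`)
}

expect_fractions_match <- function(scatter_df, oracle_df, tol) {
  all_idx <- sort(union(scatter_df$flat_index, oracle_df$flat_index))
  a <- numeric(length(all_idx))
  b <- numeric(length(all_idx))
  a[match(scatter_df$flat_index, all_idx)] <- scatter_df$fraction
  b[match(oracle_df$flat_index, all_idx)] <- oracle_df$fraction
  expect_lt(max(abs(a - b)), tol)
}
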
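#' Per-spike jump transition for a grid
#'
#' A single incoming spike shifts a neuron's state instantaneously by the
#' constant vector `J`. Because all cells are identical boxes, the mass of
#' any cell lands in at most two adjacent cells per dimension: the nearer
#' cell at offset `floor(J_d / cw_d)` (`ceiling` for negative `J_d`)
#' receives `1 - frac(|J_d| / cw_d)` of the mass and the cell one further
#' along receives the remainder. Dimensions combine as a cross product, so
#' an N-dimensional jump touches at most `2^N` cells. The same relative
#' offsets apply to every cell, so this is computed once per efficacy.
#'
#' @param grid a [grid_spec()].
#' @param jump numeric length-N vector `J`: per-dimension instantaneous
#'   state change caused by one spike (model units). A scalar is treated as
#'   a jump in the given `dimension`.
#' @param dimension when `jump` is scalar, the 0-based dimension it acts on.
#' @return an object of class `jump_transition`: list with `offsets`
#'   (integer matrix, rows = entries) and `fractions` (positive, sum to 1).
#' @examples
#' g <- grid_spec(c(0, 0), c(10, 10), c(10, 10))
#' jump_transition(g, c(1.5, 0)) # offsets 1 and 2 in dim 0, 0.5 each
#' @export
jump_transition <- function(grid, jump, dimension = NULL) {
  stopifnot_grid(grid)
  n <- grid$n_dims
  if (length(jump) == 1L && !is.null(dimension)) {
    dimension <- as.integer(dimension)
    if (dimension < 0L || dimension >= n) stop("dimension out of range")
    J <- numeric(n)
    J[dimension + 1L] <- jump
  } else {
    J <- as.numeric(jump)
    if (length(J) != n) stop("jump vector must have one entry per dimension")
  }
  if (any(!is.finite(J))) stop("jump vector must be finite")
  offsets <- matrix(0L, nrow = 1L, ncol = n)
  fractions <- 1
  for (d in seq_len(n)) {
    r <- J[d] / grid$cell_width[d]
    k <- if (r >= 0) floor(r) else ceiling(r)
    fr <- abs(r) %% 1
    if (fr < 1e-12 || fr > 1 - 1e-12) {
      # jump is an exact multiple of the cell width: single target
      dim_off <- as.integer(round(r))
      dim_frac <- 1
    } else {
      step <- if (r >= 0) 1L else -1L
      dim_off <- c(as.integer(k), as.integer(k) + step)
      dim_frac <- c(1 - fr, fr)
    }
    reps <- nrow(offsets)
    offsets <- offsets[rep(seq_len(reps), times = length(dim_off)), ,
                       drop = FALSE]
    offsets[, d] <- rep(dim_off, each = reps)
    fractions <- rep(fractions, times = length(dim_off)) *
      rep(dim_frac, each = reps)
  }
  structure(list(offsets = offsets, fractions = fractions, jump = J),
            class = "jump_transition")
}

#' Sparse one-spike redistribution matrix
#'
#' Expands a [jump_transition()] into a column-stochastic sparse matrix
#' `M[target, source]` over all grid cells; targets beyond the grid edge are
#' clamped to the nearest boundary cell, so every column still sums to 1 and
#' mass is conserved exactly.
#'
#' @param grid a [grid_spec()].
#' @param jt a [jump_transition()].
#' @return a `dgCMatrix`.
#' @export
jump_matrix <- function(grid, jt) {
  stopifnot_grid(grid)
  if (!inherits(jt, "jump_transition")) stop("expected a jump_transition")
  nc <- n_cells(grid)
  src_multi <- multi_index(grid, 0:(nc - 1L))
  i <- integer(0)
  j <- integer(0)
  x <- numeric(0)
  for (k in seq_len(nrow(jt$offsets))) {
    tgt <- src_multi
    for (d in seq_len(grid$n_dims)) {
      tgt[, d] <- pmin(pmax(src_multi[, d] + jt$offsets[k, d], 0L),
                       grid$resolution[d] - 1L)
    }
    i <- c(i, flat_index(grid, tgt) + 1L)
    j <- c(j, seq_len(nc))
    x <- c(x, rep(jt$fractions[k], nc))
  }
  Matrix::sparseMatrix(i = i, j = j, x = x, dims = c(nc, nc))
}

#' Apply one spike's worth of redistribution to a mass vector
#'
#' @param mass numeric mass vector over cells (sums to at most 1).
#' @param grid a [grid_spec()].
#' @param jt a [jump_transition()], or a prebuilt [jump_matrix()].
#' @return redistributed mass vector; total mass is conserved exactly.
#' @export
apply_jump <- function(mass, grid, jt) {
  stopifnot_grid(grid)
  if (length(mass) != n_cells(grid)) stop("mass vector has wrong length")
  M <- if (inherits(jt, "jump_transition")) jump_matrix(grid, jt) else jt
  as.numeric(M %*% mass)
}

#' Solve the Poisson master equation over one time step
#'
#' Advances `dp/dt = sum_k R_k (M_k p - p)` over `dt` seconds with
#' `n_substeps` explicit Euler iterations, where `M_k` is the one-spike
#' redistribution matrix of input `k` and `R_k` its Poisson rate. All
#' simultaneous inputs are combined into a single generator (the operator
#' sum is the exact master-equation generator; applying inputs sequentially
#' would introduce O(dt^2) splitting error). Mass is conserved to machine
#' precision. A warning is raised when `sum(R_k) * dt / n_substeps > 1`,
#' the explicit-Euler stability bound; raise `n_substeps` in that regime.
#'
#' @param mass numeric mass vector over cells.
#' @param grid a [grid_spec()].
#' @param inputs list of inputs, each a list with elements `rate` (Hz, >= 0)
#'   and `jt` (a [jump_transition()]) or `M` (a prebuilt [jump_matrix()]).
#' @param dt time step in seconds.
#' @param n_substeps Euler iterations (>= 1); the `master_steps` run
#'   parameter.
#' @return updated mass vector.
#' @export
solve_master_equation <- function(mass, grid, inputs, dt, n_substeps = 10L) {
  stopifnot_grid(grid)
  if (length(mass) != n_cells(grid)) stop("mass vector has wrong length")
  n_substeps <- as.integer(n_substeps)
  if (n_substeps < 1L) stop("n_substeps must be >= 1")
  rates <- vapply(inputs, function(inp) as.numeric(inp$rate), 0)
  if (any(rates < 0)) stop("rates must be >= 0")
  keep <- rates > 0
  if (!any(keep)) return(mass)
  Ms <- lapply(inputs[keep], function(inp) {
    M <- if (!is.null(inp$M)) inp$M else jump_matrix(grid, inp$jt)
    methods::as(M, "CsparseMatrix")
  })
  total_rate <- sum(rates[keep])
  if (total_rate * dt / n_substeps > 1)
    warning("master-equation substep R*dt/n = ",
            signif(total_rate * dt / n_substeps, 4),
            " > 1: explicit Euler may be unstable; increase n_substeps")
  cpp_master_equation(mass,
                      lapply(Ms, function(M) M@i),
                      lapply(Ms, function(M) M@p),
                      lapply(Ms, function(M) M@x),
                      rates[keep], dt / n_substeps, n_substeps)
}
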
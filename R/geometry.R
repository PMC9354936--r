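#' Triangulate the unit N-cube into N! simplices
#'
#' Uses the Kuhn (standard simplicial) decomposition: for every permutation
#' of the dimensions there is one simplex walking from the all-zero corner to
#' the all-one corner, adding one dimension at a time. The decomposition is
#' deterministic, partitions the cube exactly (volumes sum to 1, interiors
#' disjoint), and yields 2 triangles for N = 2 and 6 tetrahedra for N = 3.
#' Because every grid cell is an affine image of the unit cube, the same
#' corner-index tuples triangulate every (convex) transformed cell.
#'
#' @param n_dims dimension N >= 1.
#' @return an `N! x (N+1)` integer matrix; each row lists the corner codes
#'   (0-based, see [unit_cube_corners()]) of one simplex. The corner
#'   coordinate matrix is attached as attribute `"corners"`.
#' @examples
#' nrow(triangulate_unit_hypercube(2)) # 2 triangles
#' nrow(triangulate_unit_hypercube(3)) # 6 tetrahedra
#' @export
triangulate_unit_hypercube <- function(n_dims) {
  n <- as.integer(n_dims)
  if (is.na(n) || n < 1L) stop("n_dims must be >= 1")
  perms <- permutations_lex(n)
  out <- matrix(0L, nrow = nrow(perms), ncol = n + 1L)
  for (r in seq_len(nrow(perms))) {
    code <- 0L
    for (k in seq_len(n)) {
      code <- code + bitwShiftL(1L, n - perms[r, k])
      out[r, k + 1L] <- code
    }
  }
  attr(out, "corners") <- unit_cube_corners(n)
  out
}

# all permutations of 1..n in lexicographic order (deterministic)
permutations_lex <- function(n) {
  if (n == 1L) return(matrix(1L, 1L, 1L))
  sub <- permutations_lex(n - 1L)
  out <- matrix(0L, nrow = n * nrow(sub), ncol = n)
  row <- 1L
  for (first in seq_len(n)) {
    rest <- setdiff(seq_len(n), first)
    for (r in seq_len(nrow(sub))) {
      out[row, ] <- c(first, rest[sub[r, ]])
      row <- row + 1L
    }
  }
  out
}

#' Volume of an N-simplex
#'
#' The N-volume `|det(E)| / N!` where the rows of `E` are the edge vectors
#' from the first vertex. Zero iff the vertices are affinely dependent.
#'
#' @param vertices an `(N+1) x N` numeric matrix, one vertex per row.
#' @return non-negative volume.
#' @examples
#' simplex_volume(rbind(c(0, 0), c(1, 0), c(0, 1))) # 0.5
#' @export
simplex_volume <- function(vertices) {
  vertices <- as.matrix(vertices)
  if (nrow(vertices) != ncol(vertices) + 1L)
    stop("a simplex in N dimensions needs N+1 vertices")
  cpp_simplex_volume(vertices)
}

#' Cut a simplex with an axis-aligned hyperplane
#'
#' Splits a simplex along the hyperplane `x[axis] == offset` by recursively
#' bisecting crossing edges at their exact linear-interpolation points.
#' Vertices within `tol` of the plane are classified as lying on it and
#' create no new vertices. The returned pieces partition the input: their
#' volumes sum to the input volume to relative tolerance 1e-9.
#'
#' @param vertices an `(N+1) x N` numeric matrix (must be non-degenerate).
#' @param axis 0-based dimension index of the cutting plane's normal.
#' @param offset plane coordinate along `axis`.
#' @param tol absolute coplanarity tolerance (>= 0).
#' @return list with elements `above` and `below`, each a list of simplex
#'   vertex matrices (either may be empty when there is no crossing).
#' @export
bisect_simplex <- function(vertices, axis, offset, tol = 0) {
  vertices <- as.matrix(vertices)
  if (nrow(vertices) != ncol(vertices) + 1L)
    stop("a simplex in N dimensions needs N+1 vertices")
  axis <- as.integer(axis)
  if (axis < 0L || axis >= ncol(vertices)) stop("axis out of range")
  if (tol < 0) stop("tol must be >= 0")
  cpp_bisect_simplex(vertices, axis, offset, tol)
}

#' Enumerate the combinatorial cases of a simplex-hyperplane cut
#'
#' Each way a hyperplane can meet an N-simplex is classified by the counts
#' of vertices above, below, and on the plane (`n_above + n_below + n_on =
#' N+1`, with at least one vertex strictly on each side and between 0 and
#' N-1 coplanar vertices). For each case a reference simplex is built whose
#' vertices realize the configuration, the crossing edges are bisected at
#' their midpoints exactly as during matrix generation, and the resulting
#' triangulations of the above- and below-side polytopes are recorded as
#' templates. The number of intersection vertices equals
#' `n_above * n_below` (the number of crossing edges).
#'
#' @param n_dims dimension N >= 1.
#' @return a named list keyed `"a/b/c"` for `(n_above, n_below, n_on)`.
#'   Each entry contains `n_above`, `n_below`, `n_on`, `n_new` (intersection
#'   vertex count), `vertices` (reference configuration, original vertices
#'   then intersection vertices), and `above`/`below`: lists of integer
#'   tuples (1-based rows of `vertices`) triangulating each side.
#' @examples
#' cases <- enumerate_bisection_cases(3)
#' cases[["1/3/0"]]$n_new # 3
#' @export
enumerate_bisection_cases <- function(n_dims) {
  n <- as.integer(n_dims)
  if (is.na(n) || n < 1L) stop("n_dims must be >= 1")
  out <- list()
  for (n_on in 0:(n - 1L)) {
    for (n_above in seq_len(n + 1L - n_on - 1L)) {
      n_below <- n + 1L - n_on - n_above
      if (n_below < 1L) next
      key <- paste(n_above, n_below, n_on, sep = "/")
      out[[key]] <- bisection_case_template(n, n_above, n_below, n_on)
    }
  }
  out
}

# Build one reference configuration and its side triangulations.
# The reference simplex has its first coordinate fixed by the prescribed
# side (+0.4 above, -0.3 below, 0 on the plane x[0] == 0); the remaining
# coordinates are deterministic quasi-random values that keep the simplex
# non-degenerate (checked, with a fallback offset).
bisection_case_template <- function(n, n_above, n_below, n_on) {
  nv <- n + 1L
  s <- c(rep(0.4, n_above), rep(-0.3, n_below), rep(0, n_on))
  qrand <- function(k) (sin(k * 12.9898) * 43758.5453) %% 1
  verts <- NULL
  for (try_off in 0:9) {
    verts <- matrix(0, nrow = nv, ncol = n)
    verts[, 1L] <- s
    if (n > 1L) {
      k <- seq_len(nv * (n - 1L)) + 1000L * try_off
      verts[, -1L] <- matrix(qrand(k), nrow = nv)
    }
    if (cpp_simplex_volume(verts) > 1e-6) break
  }
  stopifnot(cpp_simplex_volume(verts) > 0)
  # analytic intersection points on crossing edges, lexicographic (i, j)
  newpts <- NULL
  for (i in which(s > 0)) {
    for (j in which(s < 0)) {
      t <- s[i] / (s[i] - s[j])
      newpts <- rbind(newpts, verts[i, ] + t * (verts[j, ] - verts[i, ]))
    }
  }
  pieces <- cpp_bisect_simplex(verts, 0L, 0, 1e-12)
  allpts <- rbind(verts, newpts)
  label <- function(simp) {
    apply(simp, 1L, function(pt) {
      d <- sqrt(colSums((t(allpts) - pt)^2))
      k <- which.min(d)
      if (d[k] > 1e-9) stop("template vertex does not match any known point")
      k
    })
  }
  list(n_above = n_above, n_below = n_below, n_on = n_on,
       n_new = n_above * n_below, vertices = allpts,
       above = lapply(pieces$above, label),
       below = lapply(pieces$below, label))
}

#' Distribute simplex volumes over grid cells
#'
#' Recursively bisects each simplex against every interior grid hyperplane
#' it straddles until each terminal piece lies in exactly one cell, then
#' accumulates the piece volumes per cell. Volume falling outside the grid
#' is assigned to the nearest boundary cell (coordinate clamping), so the
#' returned fractions always sum to `sum(volumes) / total_volume`.
#'
#' @param simplices list of `(N+1) x N` vertex matrices.
#' @param grid a [grid_spec()].
#' @param total_volume reference volume the fractions are expressed
#'   against (> 0); typically the summed volume of `simplices`.
#' @return data.frame with 0-based `flat_index` and `fraction`, sorted by
#'   index.
#' @export
scatter_simplices_to_grid <- function(simplices, grid, total_volume) {
  stopifnot_grid(grid)
  if (!is.numeric(total_volume) || total_volume <= 0)
    stop("total_volume must be strictly positive")
  idx_all <- integer(0)
  vol_all <- numeric(0)
  for (s in simplices) {
    s <- as.matrix(s)
    if (nrow(s) != grid$n_dims + 1L || ncol(s) != grid$n_dims)
      stop("each simplex must be an (N+1) x N vertex matrix")
    r <- cpp_scatter_simplex(s, grid$base, grid$cell_width, grid$resolution)
    idx_all <- c(idx_all, r$flat)
    vol_all <- c(vol_all, r$volume)
  }
  if (length(idx_all) == 0L)
    return(data.frame(flat_index = integer(0), fraction = numeric(0)))
  agg <- rowsum(vol_all, group = idx_all)
  data.frame(flat_index = as.integer(rownames(agg)),
             fraction = as.numeric(agg) / total_volume)
}
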
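test_that("cell_vertices enumerates the 2^N corners in binary order", {
  g1 <- grid_spec(0, 1, 1)
  expect_equal(cell_vertices(g1, 0L), matrix(c(0, 1), ncol = 1))

  g2 <- grid_spec(c(0, 0), c(1, 2), c(1, 1))
  expect_equal(cell_vertices(g2, c(0L, 0L)),
               rbind(c(0, 0), c(0, 2), c(1, 0), c(1, 2)))

  g3 <- grid_spec(c(-1, -1, -1), c(2, 2, 2), c(4, 4, 4))
  v <- cell_vertices(g3, c(1L, 2L, 3L))
  expect_equal(dim(v), c(8L, 3L))
  expect_error(cell_vertices(g3, c(4L, 0L, 0L)), "out of range")
})

test_that("the Kuhn triangulation partitions the unit N-cube", {
  counts <- c(1L, 2L, 6L, 24L) # N! simplices; 2 triangles, 6 tetrahedra
  for (n in 1:4) {
    tri <- triangulate_unit_hypercube(n)
    expect_identical(nrow(tri), counts[n])
    corners <- attr(tri, "corners")
    vols <- apply(tri, 1L, function(ix)
      simplex_volume(corners[ix + 1L, , drop = FALSE]))
    expect_lt(abs(sum(vols) - 1), 1e-12)
    expect_identical(tri, triangulate_unit_hypercube(n)) # deterministic
  }
  expect_error(triangulate_unit_hypercube(0), ">= 1")
})

test_that("triangulation simplices have disjoint interiors", {
  # every interior point of the cube lies in exactly one simplex
  in_simplex <- function(verts, p) {
    n <- ncol(verts)
    lam <- solve(rbind(t(verts), 1), c(p, 1))
    all(lam > 1e-10)
  }
  set.seed(42)
  for (n in 2:3) {
    tri <- triangulate_unit_hypercube(n)
    corners <- attr(tri, "corners")
    in_closed <- function(verts, p) {
      lam <- solve(rbind(t(verts), 1), c(p, 1))
      all(lam > -1e-10)
    }
    for (k in 1:40) {
      p <- runif(n)
      open_hits <- sum(apply(tri, 1L, function(ix)
        in_simplex(corners[ix + 1L, , drop = FALSE], p)))
      closed_hits <- sum(apply(tri, 1L, function(ix)
        in_closed(corners[ix + 1L, , drop = FALSE], p)))
      expect_lte(open_hits, 1L)  # interiors disjoint
      expect_gte(closed_hits, 1L) # closures cover the cube
    }
  }
})

test_that("simplex_volume matches closed forms and invariances", {
  expect_equal(simplex_volume(rbind(c(0, 0), c(1, 0), c(0, 1))), 0.5)
  tet <- rbind(c(0, 0, 0), c(1, 0, 0), c(0, 1, 0), c(0, 0, 1))
  expect_equal(simplex_volume(tet), 1 / 6)
  coplanar <- rbind(c(0, 0, 0), c(1, 0, 0), c(0, 1, 0), c(1, 1, 0))
  expect_equal(simplex_volume(coplanar), 0)
  # permutation invariance
  expect_equal(simplex_volume(tet[c(3, 1, 4, 2), ]), 1 / 6)
  # rigid motion invariance
  th <- 0.7
  R <- rbind(c(cos(th), -sin(th), 0), c(sin(th), cos(th), 0), c(0, 0, 1))
  moved <- sweep(tet %*% t(R), 2, c(3, -2, 5), `+`)
  expect_equal(simplex_volume(moved), 1 / 6, tolerance = 1e-12)
  expect_error(simplex_volume(rbind(c(0, 0), c(1, 0))), "vertices")
})

test_that("bisection-case table matches the 3-simplex enumeration", {
  cases <- enumerate_bisection_cases(3)
  # four canonical rows (up to above/below exchange), with the published
  # intersection-vertex counts 3, 4, 2, 1
  expect_equal(cases[["1/3/0"]]$n_new, 3L)
  expect_equal(cases[["2/2/0"]]$n_new, 4L)
  expect_equal(cases[["1/2/1"]]$n_new, 2L)
  expect_equal(cases[["1/1/2"]]$n_new, 1L)
  canon <- unique(lapply(cases, function(cs)
    c(sort(c(cs$n_above, cs$n_below)), cs$n_on)))
  expect_length(canon, 4L)
  # 2-D: brute-force edge-crossing enumeration of a triangle gives cases
  # (1,2,0), (2,1,0), (1,1,1) with 2, 2, 1 intersection vertices
  cases2 <- enumerate_bisection_cases(2)
  expect_setequal(names(cases2), c("1/2/0", "2/1/0", "1/1/1"))
  expect_equal(cases2[["1/2/0"]]$n_new, 2L)
  expect_equal(cases2[["2/1/0"]]$n_new, 2L)
  expect_equal(cases2[["1/1/1"]]$n_new, 1L)
  # template triangulations conserve the reference simplex volume, and the
  # vertex budget per case is (N+1) originals plus n_above*n_below cuts
  for (n in 2:4) {
    for (cs in enumerate_bisection_cases(n)) {
      total <- simplex_volume(cs$vertices[seq_len(n + 1L), , drop = FALSE])
      piece <- sum(vapply(c(cs$above, cs$below), function(ix)
        simplex_volume(cs$vertices[ix, , drop = FALSE]), 0))
      expect_lt(abs(piece - total), 1e-12 + 1e-9 * total)
      expect_identical(nrow(cs$vertices), n + 1L + cs$n_above * cs$n_below)
    }
  }
  # mirror symmetry: case (a,b,c) pairs with case (b,a,c)
  for (key in names(cases)) {
    cs <- cases[[key]]
    mirror <- cases[[paste(cs$n_below, cs$n_above, cs$n_on, sep = "/")]]
    expect_equal(cs$n_new, mirror$n_new)
    expect_length(mirror$above, length(cs$below))
    expect_length(mirror$below, length(cs$above))
  }
})

test_that("bisect_simplex conserves volume and classifies contacts", {
  tet <- rbind(c(0, 0, 0), c(1, 0, 0), c(0, 1, 0), c(0, 0, 1))
  # plane entirely left of the simplex: no crossing
  r <- bisect_simplex(tet, 0, -1, 1e-12)
  expect_length(r$below, 0L)
  expect_length(r$above, 1L)
  expect_equal(r$above[[1L]], tet)
  # corner cut at x = 0.5: above side is the sub-tetrahedron scaled by 1/2,
  # volume (1/6) * (1/2)^3 = 1/48
  r <- bisect_simplex(tet, 0, 0.5, 1e-12)
  va <- sum(vapply(r$above, simplex_volume, 0))
  vb <- sum(vapply(r$below, simplex_volume, 0))
  expect_equal(va, 1 / 48, tolerance = 1e-12)
  expect_equal(va + vb, 1 / 6, tolerance = 1e-12)
  # a vertex within tol of the plane counts as "on": no new vertex from
  # its edges, so the cut creates only the crossing-edge points
  tet2 <- rbind(c(0.5, 0, 0), c(0, 0, 1), c(0, 1, 0), c(1, 0.5, 0.5))
  r <- bisect_simplex(tet2, 0, 0.5, 1e-9)
  pts <- do.call(rbind, c(r$above, r$below))
  onplane <- unique(round(pts[abs(pts[, 1] - 0.5) < 1e-9, ], 9))
  expect_identical(nrow(onplane), 3L) # the on-vertex + 2 edge cuts
  expect_error(bisect_simplex(rbind(c(0, 0, 0), c(1, 0, 0), c(2, 0, 0),
                                    c(3, 0, 0)), 0, 0.5, 0),
               "degenerate")
})

test_that("random bisections conserve volume (property)", {
  set.seed(7)
  for (k in 1:60) {
    n <- sample(2:4, 1)
    verts <- matrix(rnorm((n + 1) * n), ncol = n)
    v0 <- simplex_volume(verts)
    if (v0 < 1e-6) next
    axis <- sample(0:(n - 1), 1)
    offset <- runif(1, min(verts[, axis + 1]), max(verts[, axis + 1]))
    r <- bisect_simplex(verts, axis, offset, 1e-12)
    vsum <- sum(vapply(c(r$above, r$below), simplex_volume, 0))
    expect_lt(abs(vsum - v0), 1e-9 * v0)
  }
})

test_that("scatter resolves cell overlaps analytically", {
  g <- grid_spec(c(0, 0), c(4, 4), c(4, 4))
  # cell image strictly inside one grid cell
  small <- affine_cell_corners(2, diag(2) * 0.5, c(1.2, 2.1))
  out <- scatter_simplices_to_grid(cell_image_simplices(small), g, 0.25)
  expect_equal(out$flat_index, flat_index(g, c(1L, 2L)))
  expect_equal(out$fraction, 1)
  # unit cell translated +0.5 cell widths along dim 0
  shifted <- affine_cell_corners(2, diag(2), c(0.5, 0))
  out <- scatter_simplices_to_grid(cell_image_simplices(shifted), g, 1)
  expect_equal(out$flat_index, c(0L, 4L))
  expect_equal(out$fraction, c(0.5, 0.5))
  # mass pushed past the boundary is clamped: fractions still sum to 1
  outside <- affine_cell_corners(2, diag(2), c(3.6, -0.4))
  out <- scatter_simplices_to_grid(cell_image_simplices(outside), g, 1)
  expect_lt(abs(sum(out$fraction) - 1), 1e-9)
  expect_error(scatter_simplices_to_grid(cell_image_simplices(small), g, 0),
               "positive")
})

test_that("scatter fractions match a uniform point-sampling oracle", {
  set.seed(101)
  for (n in 2:3) {
    g <- grid_spec(rep(0, n), rep(6, n), rep(6L, n))
    for (k in 1:6) {
      A <- diag(n) + matrix(runif(n * n, -0.3, 0.3), n)
      b <- runif(n, 0.5, 4.5)
      corners <- affine_cell_corners(n, A, b)
      vol <- abs(det(A))
      out <- scatter_simplices_to_grid(cell_image_simplices(corners), g, vol)
      expect_lt(abs(sum(out$fraction) - 1), 1e-9)
      oracle <- scatter_sampling_oracle(
        g, function(u) sweep(u %*% t(A), 2, b, `+`), 2e5)
      expect_fractions_match(out, oracle, 5e-3)
    }
  }
})
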
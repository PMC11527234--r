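# Synthetic cavity generator, mesh primitives, refinement and quality.

test_that("cavity generator hits a 2.5 L target volume within 2%", {
  spec <- cavity_spec(target_volume = 2.5e-3, mesh_size = 0.02, dim = 3)
  mesh <- build_cavity_mesh(spec)
  V <- compute_volume(mesh)
  expect_gt(V, 2.45e-3)
  expect_lt(V, 2.55e-3)
  expect_setequal(unique(mesh$facet_patch),
                  c("diaphragm", "lateral", "floor", "ovary_left",
                    "ovary_right"))
})

test_that("generator is deterministic and the jitter seed is reproducible", {
  spec <- tiny_cavity_spec(jitter_frac = 0.2, seed = 7L)
  a <- build_cavity_mesh(spec)
  b <- build_cavity_mesh(spec)
  expect_identical(a$points, b$points)
  expect_identical(a$cells, b$cells)
  other <- build_cavity_mesh(tiny_cavity_spec(jitter_frac = 0.2, seed = 8L))
  expect_false(identical(a$points, other$points))
})

test_that("refinement_level regenerates with strictly more, smaller cells", {
  m0 <- build_cavity_mesh(tiny_cavity_spec(refinement_level = 0L))
  m1 <- build_cavity_mesh(tiny_cavity_spec(refinement_level = 1L))
  expect_gt(nrow(m1$cells), nrow(m0$cells))
  dia <- function(m) {
    ed <- asciflow:::mesh_edges(m)
    min(sqrt(rowSums((m$points[ed$edges[, 1], ] -
                      m$points[ed$edges[, 2], ])^2)))
  }
  expect_lt(dia(m1), dia(m0))
})

test_that("ovary protrusion invariants are enforced", {
  expect_error(cavity_spec(ovary_centers = rbind(c(0.05, 0.04, 0.01),
                                                 c(0.1, 0.04, -0.005))),
               "intersect the floor")
  expect_error(cavity_spec(ovary_centers = rbind(c(0.05, 0.04, -0.02),
                                                 c(0.1, 0.04, -0.02)),
                           ovary_radius = 0.015), "intersect the floor")
  expect_error(cavity_spec(z_ov = 0.5), "cavity_height")
  expect_error(cavity_spec(cavity_width = -1), "cavity_width")
})

test_that("compute_volume: closed forms, isometry and scaling law", {
  cube <- mesh_box(3, 3, 3)
  expect_equal(compute_volume(cube), 1, tolerance = 1e-12)
  moved <- cube
  moved$points <- sweep(moved$points, 2, c(5, -3, 2), "+")
  expect_equal(compute_volume(moved), 1, tolerance = 1e-12)
  scaled <- cube
  scaled$points <- 2 * scaled$points
  expect_equal(compute_volume(scaled), 8, tolerance = 1e-10)
})

test_that("inverted cells are rejected with the offending indices", {
  m <- mesh_rectangle(2, 2)
  bad <- m
  # collapse cell 1 through its apex
  v <- bad$cells[1, ]
  bad$points[v[1], ] <- colMeans(bad$points[v[2:3], ])
  expect_error(compute_volume(bad), "inverted cells|non-positive")
  expect_error(quality_report(bad), "non-positive")
})

test_that("uniform refinement conserves volume, patch areas and counts", {
  for (mesh in list(build_cavity_mesh(tiny_cavity_spec()),
                    mesh_box(2, 2, 2, 0.3, 0.2, 0.4))) {
    expect_identical(refine(mesh, 0L), mesh)
    r <- refine(mesh, 1L)
    fac <- if (mesh$dim == 2L) 4L else 8L
    expect_equal(nrow(r$cells), fac * nrow(mesh$cells))
    expect_equal(compute_volume(r), compute_volume(mesh), tolerance = 1e-10)
    q0 <- quality_report(mesh); q1 <- quality_report(r)
    for (p in names(q0$boundary_area_by_patch))
      expect_equal(q1$boundary_area_by_patch[[p]],
                   q0$boundary_area_by_patch[[p]], tolerance = 1e-10)
  }
})

test_that("quality report partitions the boundary area exactly", {
  L <- 0.3
  cube <- mesh_box(2, 3, 2, L, L, L)
  q <- quality_report(cube)
  expect_equal(Reduce(`+`, q$boundary_area_by_patch), 6 * L^2,
               tolerance = 1e-10 * 6 * L^2)
  expect_gt(q$min_cell_volume, 0)
  m <- build_cavity_mesh(tiny_cavity_spec(dim = 3))
  q2 <- quality_report(m)
  expect_equal(Reduce(`+`, q2$boundary_area_by_patch),
               q2$total_boundary_area,
               tolerance = 1e-10 * q2$total_boundary_area)
})

test_that("2D cross-section mode carries the same patch taxonomy", {
  m <- build_cavity_mesh(tiny_cavity_spec(dim = 2))
  expect_setequal(unique(m$facet_patch),
                  c("diaphragm", "lateral", "floor", "ovary_left",
                    "ovary_right"))
  expect_equal(m$dim, 2L)
  # enclosed volume from the oriented boundary agrees with the cell sum
  expect_equal(asciflow:::enclosed_volume(m), compute_volume(m),
               tolerance = 1e-12)
})
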
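# Breathing presets, isovolumetric boundary forcing, mesh motion.

test_that("breathing presets carry the study parameters", {
  reg <- preset("regular")
  expect_equal(reg$amplitude, 0.060)
  expect_equal(reg$frequency, 0.37)
  expect_equal(reg$n_cycles, 3L)
  act <- preset("active")
  expect_equal(act$amplitude, 0.080)
  expect_equal(act$frequency, 1.0)
  expect_equal(act$n_cycles, 3L)
  expect_error(preset("vigorous"), "valid presets")
})

test_that("vertical decay profile is the clamped linear ramp", {
  expect_equal(vertical_profile(0.2, 0.05, 0.2), 1)
  expect_equal(vertical_profile(0.05, 0.05, 0.2), 0)
  expect_equal(vertical_profile(0.125, 0.05, 0.2), 0.5)
  expect_equal(vertical_profile(c(-1, 0.04), 0.05, 0.2), c(0, 0))
  expect_equal(vertical_profile(5, 0.05, 0.2), 1)
  expect_error(vertical_profile(0.1, 0.3, 0.2), "z_top")
})

test_that("prescribed displacement: smooth start, amplitude, stationarity, periodicity", {
  spec <- tiny_cavity_spec()
  mesh <- build_cavity_mesh(spec)
  pre <- preset("regular")
  d0 <- boundary_displacement(mesh, pre, spec$z_ov, 0)
  expect_equal(max(abs(d0$values)), 0)
  dh <- boundary_displacement(mesh, pre, spec$z_ov, 1 / (2 * pre$frequency))
  expect_equal(max(abs(dh$values[, 2])), 0.060, tolerance = 1e-12)
  # nodes at or below the ovary height never move
  z <- mesh$points[dh$nodes, 2]
  expect_equal(max(abs(dh$values[z <= spec$z_ov + 1e-12, ])), 0)
  dp <- boundary_displacement(mesh, pre, spec$z_ov,
                              0.8 + 1 / pre$frequency)
  db <- boundary_displacement(mesh, pre, spec$z_ov, 0.8)
  expect_equal(dp$values, db$values, tolerance = 1e-12)
  # amplitude linearity of the prescribed forcing
  pre2 <- breathing_preset(2 * pre$amplitude, pre$frequency)
  d2 <- boundary_displacement(mesh, pre2, spec$z_ov, 0.8)
  expect_equal(d2$values, 2 * db$values, tolerance = 1e-12)
})

test_that("lateral compensation restores the enclosed volume", {
  spec <- tiny_cavity_spec()
  mesh <- build_cavity_mesh(spec)
  pre <- preset("regular")
  V0 <- asciflow:::enclosed_volume(mesh)
  basis <- asciflow:::lateral_compensation_basis(mesh, spec$z_ov)
  # zero vertical field -> zero compensation
  v0 <- boundary_displacement(mesh, pre, spec$z_ov, 0)
  attr(v0, "z_ov") <- spec$z_ov
  c0 <- volume_compensation(mesh, v0, basis = basis, V0 = V0)
  expect_equal(attr(c0, "magnitude"), 0)
  for (t in seq(0.2, 2.5, by = 0.6)) {
    mo <- cavity_boundary_motion(mesh, pre, spec$z_ov, t, basis = basis,
                                 V0 = V0)
    p <- mesh$points
    p[mo$nodes, ] <- p[mo$nodes, ] + mo$values
    expect_lt(abs(asciflow:::enclosed_volume(mesh, p) - V0) / V0, 1e-3)
  }
})

test_that("piston compensation matches the first-order area bookkeeping", {
  w <- 0.2; d <- 0.15; h <- 0.25
  mesh <- box_cavity_3d(3, 3, 3, w, d, h)
  bn <- asciflow:::boundary_nodes(mesh)
  delta <- 1e-4                        # small piston displacement of the top
  vals <- matrix(0, length(bn), 3)
  top <- abs(mesh$points[bn, 3] - h) < 1e-12
  vals[top, 3] <- -delta
  vf <- asciflow:::displacement_field(bn, vals, 0)
  z_ov <- 1e-9                          # whole wall participates
  basis <- asciflow:::lateral_compensation_basis(mesh, z_ov)
  attr(vf, "z_ov") <- z_ov
  comp <- volume_compensation(mesh, vf, basis = basis)
  m <- attr(comp, "magnitude")
  A_top <- w * d
  A_lat <- 2 * (w + d) * h
  expect_equal(m, delta * A_top / A_lat, tolerance = 0.05)
})

test_that("3D cavity stays isovolumetric over a forcing cycle", {
  spec <- cavity_spec(target_volume = 2.5e-3, mesh_size = 0.025, dim = 3)
  mesh <- build_cavity_mesh(spec)
  pre <- preset("active")
  V0 <- asciflow:::enclosed_volume(mesh)
  basis <- asciflow:::lateral_compensation_basis(mesh, spec$z_ov)
  for (t in seq(0, 1 / pre$frequency, length.out = 9L)) {
    mo <- cavity_boundary_motion(mesh, pre, spec$z_ov, t, basis = basis,
                                 V0 = V0)
    p <- mesh$points
    p[mo$nodes, ] <- p[mo$nodes, ] + mo$values
    expect_lt(abs(asciflow:::enclosed_volume(mesh, p) - V0) / V0, 1e-3)
  }
})

test_that("mesh velocity differencing is exact on its design order", {
  nn <- 10L
  base <- matrix(stats::rnorm(nn * 2), nn, 2)
  dt <- 0.05
  # constant history -> zero velocity
  expect_equal(mesh_velocity(list(base, base), dt), 0 * base)
  # linear d(t) = c t: BDF1 exact
  cmat <- matrix(stats::rnorm(nn * 2), nn, 2)
  hist <- lapply(0:2, function(k) cmat * k * dt)
  expect_equal(mesh_velocity(hist, dt, "backward_difference_1"), cmat,
               tolerance = 1e-12)
  # quadratic d(t) = c t^2: BDF2 exact at the evaluation time (oracle:
  # d'(t) = 2 c t)
  t2 <- (0:2) * dt
  hist2 <- lapply(t2, function(t) cmat * t^2)
  expect_equal(mesh_velocity(hist2, dt, "backward_difference_2"),
               2 * cmat * t2[3], tolerance = 1e-12)
  expect_error(mesh_velocity(list(base), dt), "insufficient")
  expect_error(mesh_velocity(list(base, base), dt,
                             "backward_difference_2"), "insufficient")
})

test_that("pseudo-solid mesh motion reproduces rigid and linear fields", {
  for (mesh in list(build_cavity_mesh(tiny_cavity_spec()),
                    mesh_box(3, 3, 3, 0.2, 0.2, 0.2))) {
    d <- mesh$dim
    bn <- asciflow:::boundary_nodes(mesh)
    # zero boundary data -> zero interior
    z <- solve_mesh_motion(mesh,
      asciflow:::displacement_field(bn, matrix(0, length(bn), d), 0))
    expect_equal(max(abs(z)), 0, tolerance = 1e-12)
    # uniform translation passes through exactly
    tr <- matrix(rep(seq_len(d) * 1e-3, each = length(bn)), ncol = d)
    dt <- solve_mesh_motion(mesh, asciflow:::displacement_field(bn, tr, 0))
    expect_equal(dt, matrix(rep(seq_len(d) * 1e-3, each = nrow(mesh$points)),
                            ncol = d), tolerance = 1e-9)
    # linear boundary data -> the same linear field (homogeneous material)
    A <- matrix(0.01 * seq_len(d * d), d, d)
    lin <- solve_mesh_motion(mesh,
      asciflow:::displacement_field(bn, mesh$points[bn, ] %*% t(A), 0),
      settings = mesh_motion_settings(stiffening_exponent = 0))
    expect_equal(lin, mesh$points %*% t(A), tolerance = 1e-9)
  }
})

test_that("mesh motion demands full boundary coverage", {
  mesh <- build_cavity_mesh(tiny_cavity_spec())
  bn <- asciflow:::boundary_nodes(mesh)
  part <- bn[-1]
  expect_error(solve_mesh_motion(mesh,
    asciflow:::displacement_field(part, matrix(0, length(part), 2), 0)),
    "every boundary node")
})
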
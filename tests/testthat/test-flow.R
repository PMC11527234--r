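# ALE Navier-Stokes solver: exact solutions, conservation and contracts.

props <- fluid_properties()

test_that("fluid defaults are the ascitic values and are validated", {
  expect_equal(props$density, 1017.5)
  expect_equal(props$dynamic_viscosity, 0.0012)
  expect_error(fluid_properties(density = -1))
})

test_that("a quiescent fluid on a fixed mesh stays exactly at rest", {
  mesh <- build_cavity_mesh(tiny_cavity_spec())
  st <- solver_settings(dt = 0.1)
  state <- flow_state_rest(mesh, st)
  motion <- list(points = mesh$points, w = matrix(0, nrow(mesh$points), 2))
  for (k in 1:3) {
    state <- advance_flow(state, mesh, motion, props, st)
    expect_equal(max(abs(state$u)), 0)
    expect_equal(diff(range(state$p)), 0, tolerance = 1e-9)
  }
})

test_that("uniform flow is preserved exactly on a rigidly translating mesh", {
  rep <- verify("gcl_uniform_translation")
  expect_lt(rep$spurious_velocity, 1e-8)
})

test_that("Taylor-Hood reproduces plane Poiseuille exactly (solution in the space)", {
  h <- 0.004; G <- 0.5
  ch <- poiseuille_state(8)
  U <- G * h^2 / (12 * props$dynamic_viscosity)
  expect_equal(max(ch$state$u[, 1]), 1.5 * U, tolerance = 1e-8)
  expect_lt(divergence_norm(ch$state, ch$mesh), 1e-6)
  # exact parabola across the section at mid-channel
  vsp <- ch$state$opr$vsp
  mid <- abs(vsp$dof_coords[, 1] - h) < 1e-9
  y <- vsp$dof_coords[mid, 2]
  expect_equal(ch$state$u[mid, 1], 6 * U * y * (h - y) / h^2,
               tolerance = 1e-8)
})

test_that("divergence norm: zero field and rigid rotation are divergence-free", {
  mesh <- mesh_rectangle(4, 4, 1, 1)
  q <- manual_state(mesh, function(x) matrix(0, nrow(x), 2))
  expect_equal(divergence_norm(q, mesh), 0)
  rot <- manual_state(mesh, function(x)
    cbind(-(x[, 2] - 0.5), x[, 1] - 0.5))
  expect_lt(divergence_norm(rot, mesh), 1e-12)
})

test_that("identical configurations give identical histories", {
  spec <- tiny_cavity_spec()
  mesh <- build_cavity_mesh(spec)
  st <- cavity_run_settings(steps_per_cycle = 8L, snapshot_stride = 2L)
  pre <- preset("regular")
  pre$n_cycles <- 1L
  h1 <- run_cycles(mesh, pre, spec, settings = st)
  h2 <- run_cycles(mesh, pre, spec, settings = st)
  expect_identical(lapply(h1$snapshots, `[[`, "u"),
                   lapply(h2$snapshots, `[[`, "u"))
  expect_identical(h1$volume_drift, h2$volume_drift)
})

test_that("zero forcing amplitude leaves every snapshot quiescent", {
  spec <- tiny_cavity_spec()
  mesh <- build_cavity_mesh(spec)
  pre <- breathing_preset(1e-30, 0.37, n_cycles = 1L)
  st <- cavity_run_settings(steps_per_cycle = 8L, snapshot_stride = 2L)
  h <- run_cycles(mesh, pre, spec, settings = st)
  for (s in h$snapshots) expect_lt(max(abs(s$u)), 1e-20)
})

test_that("Stokes-regime response is linear in the forcing amplitude", {
  spec <- tiny_cavity_spec()
  mesh <- build_cavity_mesh(spec)
  st <- cavity_run_settings(steps_per_cycle = 16L, snapshot_stride = 4L,
                            include_convection = FALSE)
  maxu <- vapply(c(0.01, 0.005), function(A) {
    pre <- breathing_preset(A, 0.37, n_cycles = 1L)
    h <- run_cycles(mesh, pre, spec, settings = st)
    max(vapply(h$snapshots, function(s) max(abs(s$u)), numeric(1)))
  }, numeric(1))
  expect_equal(maxu[1] / maxu[2], 2, tolerance = 0.005)
})

test_that("wall flux balances the volume rate at every step (compatibility)", {
  spec <- tiny_cavity_spec()
  mesh <- build_cavity_mesh(spec)
  pre <- preset("regular"); pre$n_cycles <- 1L
  st <- cavity_run_settings(steps_per_cycle = 10L, snapshot_stride = 10L)
  h <- run_cycles(mesh, pre, spec, settings = st)
  V0 <- asciflow:::enclosed_volume(mesh)
  expect_lt(max(h$volume_drift) * V0 * pre$frequency,
            1e-3 * V0 * pre$frequency)   # drift within the stated budget
})

test_that("periodicity residual: exact cases and error path", {
  spec <- tiny_cavity_spec()
  mesh <- build_cavity_mesh(spec)
  pre <- breathing_preset(1e-30, 0.37, n_cycles = 2L)
  st <- cavity_run_settings(steps_per_cycle = 8L, snapshot_stride = 2L)
  h <- run_cycles(mesh, pre, spec, settings = st)
  h0 <- h
  for (k in seq_along(h0$snapshots)) h0$snapshots[[k]]$u[] <- 0
  expect_equal(periodicity_residual(h0), 0)    # quiescent
  h1 <- h
  h1$snapshots <- h1$snapshots[seq_len(4)]     # single recorded cycle
  expect_error(periodicity_residual(h1), "two recorded cycles")
  # copied-cycle fixture: exactly periodic by construction
  h2 <- h
  spc <- 4L
  for (k in seq_len(spc)) {
    h2$snapshots[[k]]$u[] <- stats::rnorm(length(h2$snapshots[[k]]$u))
    h2$snapshots[[k + spc]]$u <- h2$snapshots[[k]]$u
  }
  expect_equal(periodicity_residual(h2), 0)
})

test_that("settings constructors validate their arguments", {
  expect_error(solver_settings(dt = -1))
  expect_error(solver_settings(element_pair = "p0"))
  expect_error(solver_settings(n_cycles = 0))
  expect_error(mesh_motion_settings(poisson_ratio = 0.6))
  expect_error(breathing_preset(0.06, -1))
})
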
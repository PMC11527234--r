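# Wall traction, shear projection, and cycle metrics.

props <- fluid_properties()

test_that("hydrostatic state gives purely normal traction and zero WSS", {
  # traction of a discontinuous-at-corners exact field projected onto the
  # continuous trace space has corner ripples decaying exponentially with
  # facet distance: measure well inside the patch of a long-enough wall
  mesh <- mesh_rectangle(24, 6, 0.04, 0.01)
  p0 <- 37
  st <- manual_state(mesh, function(x) matrix(0, nrow(x), 2), p = p0)
  tr <- wall_traction(st, mesh, props, patch = "bottom")
  interior <- abs(tr$coords[, 1] - 0.02) < 0.004
  expect_equal(tr$traction[interior, 2], rep(p0, sum(interior)),
               tolerance = 1e-6)                    # n = (0,-1): t = -p0 n
  expect_lt(max(abs(tr$traction[interior, 1])), p0 * 1e-6)
  ws <- wall_shear(tr$traction, tr$normals)
  expect_lt(max(ws$mag_pa[interior]), p0 * 1e-6)
})

test_that("uniform shear recovers mu * gamma_dot (1.2 dynes/cm2 at 100/s)", {
  mesh <- mesh_rectangle(24, 4, 0.06, 0.005)
  gd <- 100
  st <- manual_state(mesh, function(x) cbind(gd * x[, 2], 0))
  tr <- wall_traction(st, mesh, props, patch = "bottom")
  ws <- wall_shear(tr$traction, tr$normals)
  interior <- abs(tr$coords[, 1] - 0.03) < 0.006
  expect_equal(ws$mag_pa[interior],
               rep(props$dynamic_viscosity * gd, sum(interior)),
               tolerance = 1e-6)
  expect_equal(ws$mag_dyn_cm2[interior], rep(1.2, sum(interior)),
               tolerance = 1e-6)
  # unit discipline holds everywhere, exactly
  expect_equal(ws$mag_dyn_cm2, 10 * ws$mag_pa)
})

test_that("tangential projection kills purely normal tractions, demands unit normals", {
  n <- cbind(c(0, 0, 1), c(1, 0, 0), c(0, 1, 0))
  tr <- 3 * n
  ws <- wall_shear(tr, n)
  expect_equal(max(ws$mag_pa), 0, tolerance = 1e-14)
  expect_equal(max(abs(rowSums(ws$tau * n))), 0, tolerance = 1e-12)
  expect_error(wall_shear(tr, 2 * n), "unit")
})

test_that("consistent-flux Poiseuille wall shear matches 6 mu U / h", {
  h <- 0.004; G <- 0.5
  ch <- poiseuille_state(8)
  wssv <- asciflow:::channel_bottom_wss(ch, props)
  expect_equal(wssv, G * h / 2, tolerance = 0.02)
  # WSS is invariant under a constant pressure shift
  st2 <- ch$state
  st2$p <- st2$p + 123.4
  tr1 <- wall_traction(ch$state, ch$mesh, props, patch = "bottom")
  tr2 <- wall_traction(st2, ch$mesh, props, patch = "bottom")
  w1 <- wall_shear(tr1$traction, tr1$normals)
  w2 <- wall_shear(tr2$traction, tr2$normals)
  # invariant under the shift: change bounded by 1e-12 of the added constant
  expect_lt(max(abs(w2$mag_pa - w1$mag_pa)), 1e-12 * 123.4)
  # tangency at every node
  expect_lt(max(abs(rowSums(w1$tau * tr1$normals))), 1e-8 * max(w1$mag_pa))
})

test_that("wall_traction rejects unknown patches", {
  mesh <- mesh_rectangle(3, 3)
  st <- manual_state(mesh, function(x) matrix(0, nrow(x), 2))
  expect_error(wall_traction(st, mesh, props, patch = "ovary_left"),
               "not present")
})

test_that("patch metrics: constant and sin^2 closed forms", {
  spec <- tiny_cavity_spec()
  mesh <- build_cavity_mesh(spec)
  vsp <- asciflow:::fem_space(mesh, 2L)
  bd <- asciflow:::boundary_dofs(vsp)
  lab <- asciflow:::dof_patch_labels(vsp)[bd]
  f0 <- 0.37
  times <- seq(0, 1 / f0, length.out = 65L)[-1]
  cval <- 2.5
  mk <- function(valfun) lapply(times, function(t)
    list(time = t, dofs = bd, patch = lab,
         mag_dyn_cm2 = rep(valfun(t), length(bd)),
         mag_pa = rep(valfun(t) / 10, length(bd))))
  hist_const <- mk(function(t) cval)
  pm <- patch_metrics(hist_const, mesh, "ovary_left")
  expect_equal(pm$mean_fss, cval, tolerance = 1e-12)
  expect_equal(pm$peak_fss, cval, tolerance = 1e-12)
  hist_sin <- mk(function(t) cval * sin(2 * pi * f0 * t)^2)
  pm2 <- patch_metrics(hist_sin, mesh, "ovary_right")
  expect_equal(pm2$mean_fss, cval / 2, tolerance = 1e-3)
  expect_equal(pm2$peak_fss, cval, tolerance = 1e-3)
  expect_gte(pm2$peak_fss, pm2$mean_fss)
  expect_error(patch_metrics(hist_const, mesh, "nonexistent"), "empty patch")
})

test_that("velocity metrics: quiescent and uniform closed forms", {
  spec <- tiny_cavity_spec()
  mesh <- build_cavity_mesh(spec)
  pre <- breathing_preset(1e-30, 0.37, n_cycles = 1L)
  st <- cavity_run_settings(steps_per_cycle = 8L, snapshot_stride = 2L)
  h <- run_cycles(mesh, pre, spec, settings = st)
  vm <- velocity_metrics(h, mesh)
  expect_equal(vm$mean_speed, 0)
  expect_equal(vm$peak_speed, 0)
  # uniform |u| = 1 cm/s fixture
  for (k in seq_along(h$snapshots)) h$snapshots[[k]]$u[, 1] <- 0.01
  vm2 <- velocity_metrics(h, mesh)
  expect_equal(vm2$mean_speed, 1, tolerance = 1e-10)
  expect_equal(vm2$peak_speed, 1, tolerance = 1e-10)
})

test_that("cycle summary composes its parts and round-trips through JSON", {
  spec <- tiny_cavity_spec()
  mesh <- build_cavity_mesh(spec)
  pre <- preset("regular"); pre$n_cycles <- 1L
  st <- cavity_run_settings(steps_per_cycle = 8L, snapshot_stride = 2L)
  h <- run_cycles(mesh, pre, spec, settings = st)
  s <- summarize(h, mesh)
  vm <- velocity_metrics(h, mesh)
  expect_equal(s$mean_speed_cm_s, vm$mean_speed)
  expect_equal(s$peak_speed_cm_s, vm$peak_speed)
  pm <- patch_metrics(h, mesh, "ovary_left")
  expect_equal(s$patch_metrics$ovary_left$mean_fss, pm$mean_fss)
  expect_gte(s$peak_speed_cm_s, s$mean_speed_cm_s)
  for (p in s$patch_metrics) expect_gte(p$peak_fss, p$mean_fss)
  tf <- tempfile(fileext = ".json")
  summary_to_json(s, tf)
  back <- jsonlite::read_json(tf, simplifyVector = TRUE)
  expect_equal(back$mean_speed_cm_s, s$mean_speed_cm_s, tolerance = 1e-12)
  expect_equal(back$patch_metrics$ovary_right$peak_fss,
               s$patch_metrics$ovary_right$peak_fss, tolerance = 1e-12)
  expect_equal(back$config_digest, s$config_digest)
})
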
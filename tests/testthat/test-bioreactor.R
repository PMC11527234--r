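# Brinkman plug flow, idealized-cell channel FSS, inverse design.

props <- fluid_properties()

# one coarse shared channel solver for the whole file (fresh factorization
# per solve; the mesh is reused)
coarse_solver <- function() {
  cache_get("cell_solver_coarse", function() {
    asciflow:::cell_channel_solver(cell_model(quiet = TRUE), props,
                                   resolution_scale = 0.6)
  })
}

test_that("chamber flow: rest state, Darcy limit and pump-rate linearity", {
  gel <- hydrogel_spec(quiet = TRUE)
  expect_equal(chamber_flow(chamber_spec(pump_rate = 0), gel, props)$U_gel, 0)
  # Darcy limit: volume-averaged speed equals the superficial speed
  ch <- chamber_spec(pump_rate = 2e-8)
  cf <- chamber_flow(ch, gel, props)
  sup <- ch$pump_rate / ch$n_chambers / gel$plug_cross_section_area
  expect_equal(cf$U_gel, sup, tolerance = 0.01)
  # doubling the pump rate doubles the averaged speed exactly
  cf2 <- chamber_flow(chamber_spec(pump_rate = 4e-8), gel, props)
  expect_equal(cf2$U_gel / cf$U_gel, 2, tolerance = 1e-10)
})

test_that("slab Brinkman profile matches the closed-form cosh solution", {
  gel <- hydrogel_spec(permeability = 1e-8, quiet = TRUE)
  ch <- chamber_spec(pump_rate = 1e-8, cross_section = "slab")
  cf <- chamber_flow(ch, gel, props, n = 160L)
  W <- sqrt(gel$plug_cross_section_area)
  mu <- props$dynamic_viscosity
  delta <- sqrt(gel$permeability / gel$porosity)
  uex <- cf$G * gel$permeability / mu *
    (1 - cosh((cf$profile$y_m - W / 2) / delta) / cosh(W / 2 / delta))
  expect_lt(max(abs(cf$profile$u_m_s - uex)) / max(uex), 0.01)
})

test_that("hydrogel and chamber specs validate and warn on placeholders", {
  expect_warning(hydrogel_spec(), "placeholder")
  expect_error(hydrogel_spec(porosity = 1.2, quiet = TRUE))
  expect_error(chamber_spec(n_chambers = 0))
  expect_equal(chamber_spec()$n_chambers, 8L)
  expect_warning(cell_model(), "placeholder")
  expect_error(cell_model(cell_radius = 60e-6, channel_height = 100e-6,
                          quiet = TRUE), "channel_height")
})

test_that("cell-surface FSS: rest state, flat-wall oracle and Stokes scaling", {
  solver <- coarse_solver()
  cell <- cell_model(quiet = TRUE)
  p0 <- cell_fss_profile(cell_model(inlet_speed = 0, quiet = TRUE), props,
                         solver = solver)
  expect_equal(max(p0$fss_dyn_cm2), 0)
  U <- 1e-4
  pf <- solver$profile(U)
  flat <- 10 * 6 * props$dynamic_viscosity * U / cell$channel_height
  expect_equal(pf$upstream_fss_dyn_cm2, flat, tolerance = 0.02)
  # linearity: scaling the inlet speed scales the whole profile
  pf3 <- solver$profile(3 * U)
  expect_lt(max(abs(pf3$fss_dyn_cm2 - 3 * pf$fss_dyn_cm2)) /
              max(pf3$fss_dyn_cm2), 0.005)
  # the bump amplifies the local shear above the flat-wall value
  expect_gt(peak_cell_fss(pf)$peak, flat)
})

test_that("peak extraction: monotone fixture, zero profile, empty profile", {
  expect_equal(peak_cell_fss(c(0.1, 0.5, 2, 3))$peak, 3)
  expect_equal(peak_cell_fss(numeric(3))$peak, 0)
  expect_error(peak_cell_fss(numeric(0)), "empty")
})

test_that("inverse design round-trips and returns 1:5:11 speed ratios", {
  solver <- coarse_solver()
  cell <- cell_model(quiet = TRUE)
  gel <- hydrogel_spec(quiet = TRUE)
  chamber <- chamber_spec()
  # definitional round trip: target the FSS achieved at a known speed
  Ustar <- 2e-4
  tgt <- peak_cell_fss(solver$profile(Ustar))$peak
  op <- inverse_design(tgt, cell, chamber, gel, props, solver = solver)
  expect_equal(op$inlet_speed, Ustar, tolerance = 0.01)
  ops <- lapply(c(1, 5, 11), inverse_design, cell = cell,
                chamber = chamber, gel = gel, props = props,
                solver = solver)
  for (i in seq_along(ops)) {
    expect_lt(ops[[i]]$residual, 0.01)
    expect_equal(ops[[i]]$achieved_fss, c(1, 5, 11)[i], tolerance = 0.01)
  }
  Us <- vapply(ops, `[[`, numeric(1), "inlet_speed")
  expect_equal(Us / Us[1], c(1, 5, 11), tolerance = 0.01)
  # monotone: pump rate increases with the target
  Qs <- vapply(ops, `[[`, numeric(1), "pump_rate")
  expect_true(all(diff(Qs) > 0))
  expect_error(inverse_design(0, cell, chamber, gel, props), "positive")
})
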
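# Shared fixtures: small meshes, hand-built flow states, and a cache for
# expensive end-to-end runs shared by several tests.

.af_cache <- new.env(parent = emptyenv())

cache_get <- function(key, builder) {
  if (!exists(key, envir = .af_cache)) assign(key, builder(), envir = .af_cache)
  get(key, envir = .af_cache)
}

tiny_cavity_spec <- function(...) cavity_spec(mesh_size = 0.02, ...)

# rectangular "cavity" (flat floor) with the cavity patch taxonomy, for
# piston-compensation bookkeeping tests
box_cavity_3d <- function(nx = 4, ny = 4, nz = 4, w = 0.2, d = 0.15,
                          h = 0.25) {
  m <- mesh_box(nx, ny, nz, w, d, h)
  relab <- c(xmin = "lateral", xmax = "lateral", ymin = "lateral",
             ymax = "lateral", zmin = "floor", zmax = "diaphragm")
  m$facet_patch <- unname(relab[m$facet_patch])
  m
}

# hand-built flow state (no assembled operator: wall_traction treats it as
# steady Stokes with no body force)
manual_state <- function(mesh, u_fun, p = 0, order = 2L) {
  vsp <- asciflow:::fem_space(mesh, order)
  u <- u_fun(vsp$dof_coords)
  structure(list(u = u, p = rep(p, nrow(mesh$points))[seq_len(nrow(mesh$points))],
                 time = 0, points = mesh$points),
            class = "af_flow_state")
}

# steady Taylor-Hood Poiseuille channel solution with operator attached
poiseuille_state <- function(ny = 8, h = 0.004, G = 0.5) {
  cache_get(sprintf("poiseuille_%d", ny), function() {
    asciflow:::channel_steady(3L * ny, ny, 2 * h, h, G, fluid_properties())
  })
}

# the acceptance-resolution regular/active cavity pair (expensive; shared
# by the monotonicity, symmetry and periodicity tests)
acceptance_pair <- function() {
  cache_get("acceptance_pair", function() {
    spec <- cavity_spec()
    mesh <- build_cavity_mesh(spec)
    st <- cavity_run_settings()
    out <- list(spec = spec, mesh = mesh)
    for (nm in c("regular", "active")) {
      hist <- run_cycles(mesh, preset(nm), spec, settings = st)
      out[[nm]] <- list(history = hist, summary = summarize(hist, mesh))
    }
    out
  })
}
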
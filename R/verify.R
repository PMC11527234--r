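# Analytic verification suite: classical closed-form flows exercised
# end-to-end through the same assembly, solver and wall-shear extraction
# paths as the cavity pipeline.

#' Analytic Womersley (oscillatory channel) solution
#'
#' Velocity profile of plane channel flow driven by a uniform oscillatory
#' body force `G cos(omega t)` with no-slip walls at `y = 0, h`:
#' the real part of
#' `G/(i rho omega) * (1 - cosh(L(y - h/2))/cosh(L h/2)) e^{i omega t}`
#' with `L = sqrt(i omega rho / mu)`.
#'
#' @param y heights (m); `t` time (s); `h` channel height (m); `G` forcing
#'   amplitude (Pa/m); `omega` angular frequency (rad/s); `props`
#'   [fluid_properties()].
#' @return velocity (m/s).
#' @export
womersley_velocity <- function(y, t, h, G, omega, props) {
  rho <- props$density; mu <- props$dynamic_viscosity
  lam <- sqrt(1i * omega * rho / mu)
  up <- G / (1i * rho * omega)
  Re(up * (1 - cosh(lam * (y - h / 2)) / cosh(lam * h / 2)) *
       exp(1i * omega * t))
}

#' @rdname womersley_velocity
#' @export
womersley_wall_shear <- function(t, h, G, omega, props) {
  rho <- props$density; mu <- props$dynamic_viscosity
  lam <- sqrt(1i * omega * rho / mu)
  up <- G / (1i * rho * omega)
  Re(mu * up * lam * tanh(lam * h / 2) * exp(1i * omega * t))
}

#' @rdname womersley_velocity
#' @export
womersley_wall_shear_amplitude <- function(h, G, omega, props) {
  rho <- props$density; mu <- props$dynamic_viscosity
  lam <- sqrt(1i * omega * rho / mu)
  abs(mu * G / (1i * rho * omega) * lam * tanh(lam * h / 2))
}

# Steady channel flow driven by a body force, on a fixed straight channel:
# no-slip walls, symmetry-type conditions (u_y = 0) at the ends so the
# exact x-independent solution satisfies the discrete problem's boundary
# conditions. Returns the flow state with assembled operator.
channel_steady <- function(nx, ny, L, h, G, props,
                           element_pair = "taylor_hood") {
  mesh <- mesh_rectangle(nx, ny, width = L, height = h)
  st <- solver_settings(element_pair = element_pair,
                        include_convection = FALSE,
                        pressure_constraint = "none")
  opctx <- flow_operator(mesh, mesh$points, props, st, dtc = NULL)
  vsp <- opctx$vsp
  bc <- merge_bc(
    bc_patch(vsp, c("bottom", "top"),
             function(xx) matrix(0, nrow(xx), 2), 1:2),
    bc_patch(vsp, c("left", "right"),
             function(xx) matrix(0, nrow(xx), 1), 2))
  sol <- flow_solve(opctx, bc, body_force = c(G, 0))
  state <- structure(list(u = sol$u, p = sol$p, time = 0,
                          points = mesh$points,
                          opr = list(A = sol$A, F = sol$F, vsp = vsp,
                                     psp = opctx$psp, nV = opctx$nV, d = 2L)),
                     class = "af_flow_state")
  list(mesh = mesh, state = state, settings = st)
}

# area-weighted mean WSS over the mid-span of the bottom wall (away from
# the end-corner projection bleed)
channel_bottom_wss <- function(ch, props, span = 1 / 3) {
  tr <- wall_traction(ch$state, ch$mesh, props, patch = "bottom")
  ws <- wall_shear(tr$traction, tr$normals)
  L <- max(ch$mesh$points[, 1])
  mid <- abs(tr$coords[, 1] - L / 2) <= span * L / 2
  mean(ws$mag_pa[mid])
}

# Transient channel run with oscillatory body force; mesh fixed. Returns
# final-cycle snapshots (states with operators stripped except the last).
channel_womersley_run <- function(nx, ny, L, h, G, omega, props,
                                  n_cycles = 4, steps_per_cycle = 96,
                                  time_scheme = "backward_difference_2") {
  mesh <- mesh_rectangle(nx, ny, width = L, height = h)
  Tper <- 2 * pi / omega
  dt <- Tper / steps_per_cycle
  st <- solver_settings(dt = dt, time_scheme = time_scheme,
                        include_convection = FALSE,
                        pressure_constraint = "none")
  opctx <- flow_operator(mesh, mesh$points, props, st,
                         bdf_coeffs(st$time_scheme, dt, FALSE))
  vsp <- opctx$vsp
  bc <- merge_bc(
    bc_patch(vsp, c("bottom", "top"),
             function(xx) matrix(0, nrow(xx), 2), 1:2),
    bc_patch(vsp, c("left", "right"),
             function(xx) matrix(0, nrow(xx), 1), 2))
  state <- flow_state_rest(mesh, st)
  motion <- list(points = mesh$points, w = matrix(0, nrow(mesh$points), 2))
  n_steps <- n_cycles * steps_per_cycle
  keep_from <- (n_cycles - 1) * steps_per_cycle
  snaps <- list(); times <- c(); wss_num <- c()
  for (n in seq_len(n_steps)) {
    t_new <- n * dt
    state <- advance_flow(state, mesh, motion, props, st, bc = bc,
                          body_force = c(G * cos(omega * t_new), 0))
    if (n > keep_from) {
      tr <- wall_traction(state, mesh, props, patch = "bottom")
      ws <- wall_shear(tr$traction, tr$normals)
      Lx <- max(mesh$points[, 1])
      mid <- abs(tr$coords[, 1] - Lx / 2) <= Lx / 6
      wss_num <- c(wss_num, mean(ws$mag_pa[mid]))
      s <- state; s$opr <- NULL
      snaps[[length(snaps) + 1L]] <- s
      times <- c(times, t_new)
    }
  }
  list(mesh = mesh, snapshots = snaps, times = times, wss_series = wss_num,
       settings = st)
}

# relative L2 (space-time, mid-span profile) error of a Womersley run
womersley_profile_error <- function(run, h, G, omega, props) {
  mesh <- run$mesh
  L <- max(mesh$points[, 1])
  vsp <- fem_space(mesh, 2L)
  mid <- abs(vsp$dof_coords[, 1] - L / 2) <= L / 6
  y <- vsp$dof_coords[mid, 2]
  num <- 0; den <- 0
  for (k in seq_along(run$snapshots)) {
    uex <- womersley_velocity(y, run$times[k], h, G, omega, props)
    uh <- run$snapshots[[k]]$u[mid, 1]
    num <- num + sum((uh - uex)^2)
    den <- den + sum(uex^2)
  }
  sqrt(num / den)
}

# ---- Stokes flow past a sphere (axisymmetric meridian solver) ----------

# Exact Stokes solution around a fixed sphere of radius a in a uniform
# far-field stream U along +z; cylindrical components (u_r, u_z) and
# pressure, as functions of meridian coordinates (r, z).
stokes_sphere_exact <- function(r, z, a, U, props) {
  s <- sqrt(r^2 + z^2)
  ct <- z / s; st <- r / s
  us <- U * ct * (1 - 3 * a / (2 * s) + a^3 / (2 * s^3))
  ut <- -U * st * (1 - 3 * a / (4 * s) - a^3 / (4 * s^3))
  list(u_r = us * st + ut * ct, u_z = us * ct - ut * st,
       p = -1.5 * props$dynamic_viscosity * U * a * ct / s^2)
}

# Meridian (r, z) mesh of the spherical shell a <= |x| <= R, theta in
# [0, pi], geometrically graded toward the sphere surface.
sphere_shell_mesh <- function(n_theta, n_s, a, R, grade_strength = 2.5) {
  th <- seq(0, pi, length.out = n_theta + 1L)
  xi <- grade_wall(grade_strength)(seq(0, 1, length.out = n_s + 1L))
  s <- a * (R / a)^xi
  nid <- function(i, j) (j - 1L) * (n_s + 1L) + i   # i: radial, j: angular
  pts <- matrix(0, (n_s + 1L) * (n_theta + 1L), 2L)
  for (j in seq_len(n_theta + 1L)) for (i in seq_len(n_s + 1L))
    pts[nid(i, j), ] <- c(s[i] * sin(th[j]), s[i] * cos(th[j]))
  cells <- matrix(0L, 2L * n_s * n_theta, 3L)
  r <- 1L
  for (j in seq_len(n_theta)) for (i in seq_len(n_s)) {
    v00 <- nid(i, j); v10 <- nid(i + 1L, j)
    v01 <- nid(i, j + 1L); v11 <- nid(i + 1L, j + 1L)
    cells[r, ] <- c(v00, v10, v11); cells[r + 1L, ] <- c(v00, v11, v01)
    r <- r + 2L
  }
  m0 <- af_mesh(pts, cells, validate = FALSE)
  ctr <- facet_centroids(m0)
  ss <- sqrt(rowSums(ctr^2))
  pat <- ifelse(ctr[, 1] < 1e-9 * R, "axis",
                ifelse(ss < sqrt(a * R), "sphere", "outer"))
  af_mesh(pts, cells, m0$facets, pat)
}

# Axisymmetric Stokes solve (swirl-free, P2/P1) on a meridian mesh; no-slip
# sphere, exact solution on the outer rim, u_r = 0 on the axis. Returns
# peak WSS magnitude on the sphere via consistent flux with r-weighted
# boundary mass.
stokes_sphere_solve <- function(mesh, a, U, props) {
  d <- 2L
  vsp <- fem_space(mesh, 2L); psp <- fem_space(mesh, 1L)
  geom <- fem_geom(mesh, mesh$points)
  rule <- default_volume_rule(2L)
  bV <- fem_basis_at_quad(geom, 2L, rule)
  bP <- fem_basis_at_quad(geom, 1L, rule)
  nV <- vsp$ndof; nP <- psp$nn
  mu <- props$dynamic_viscosity
  nsys <- 2L * nV + nP + 1L
  # quadrature-point radius (coordinates are affine per element)
  rq <- field_at_quad(vsp, bV, vsp$dof_coords[, 1, drop = FALSE])
  rq <- lapply(rq, function(m) pmax(m[, 1], 1e-30))
  nb <- bV$nb; np1 <- 3L
  ii <- jj <- xx <- list(); k <- 1L
  push <- function(i, j, x) {
    ii[[k]] <<- i; jj[[k]] <<- j; xx[[k]] <<- x; k <<- k + 1L
  }
  for (i in seq_len(nb)) for (j in seq_len(nb)) {
    arr <- azz <- arz <- azr <- 0
    for (q in seq_len(bV$nq)) {
      G <- bV$G[[q]]; w <- bV$w[q] * rq[[q]]
      Ni <- bV$N[[q]][i]; Nj <- bV$N[[q]][j]
      arr <- arr + w * (2 * G[[1]][, j] * G[[1]][, i] +
                        G[[2]][, j] * G[[2]][, i] +
                        2 * Ni * Nj / rq[[q]]^2)
      azz <- azz + w * (2 * G[[2]][, j] * G[[2]][, i] +
                        G[[1]][, j] * G[[1]][, i])
      arz <- arz + w * (G[[1]][, j] * G[[2]][, i])   # dr(u_z) dz(v_r)
      azr <- azr + w * (G[[2]][, j] * G[[1]][, i])
    }
    push(vsp$cell_dofs[, i], vsp$cell_dofs[, j], mu * geom$vol * arr)
    push(nV + vsp$cell_dofs[, i], nV + vsp$cell_dofs[, j],
         mu * geom$vol * azz)
    push(vsp$cell_dofs[, i], nV + vsp$cell_dofs[, j], mu * geom$vol * arz)
    push(nV + vsp$cell_dofs[, i], vsp$cell_dofs[, j], mu * geom$vol * azr)
  }
  # pressure coupling: -int p (r dr(v_r) + v_r + r dz(v_z)) dOmega
  for (i in seq_len(nb)) for (l in seq_len(np1)) {
    br <- bz <- 0
    for (q in seq_len(bV$nq)) {
      G <- bV$G[[q]]; pl <- bP$N[[q]][l]
      br <- br + bV$w[q] * pl * (rq[[q]] * G[[1]][, i] + bV$N[[q]][i])
      bz <- bz + bV$w[q] * pl * rq[[q]] * G[[2]][, i]
    }
    push(vsp$cell_dofs[, i], 2L * nV + psp$cell_dofs[, l], -geom$vol * br)
    push(2L * nV + psp$cell_dofs[, l], vsp$cell_dofs[, i], -geom$vol * br)
    push(nV + vsp$cell_dofs[, i], 2L * nV + psp$cell_dofs[, l],
         -geom$vol * bz)
    push(2L * nV + psp$cell_dofs[, l], nV + vsp$cell_dofs[, i],
         -geom$vol * bz)
  }
  # zero-mean pressure multiplier with r-weighted measure
  mv <- numeric(nP)
  for (q in seq_len(bP$nq)) for (l in seq_len(np1))
    mv <- mv + tabulate_add(psp$cell_dofs[, l],
                            bP$w[q] * geom$vol * rq[[q]] * bP$N[[q]][l], nP)
  push(2L * nV + seq_len(nP), rep(nsys, nP), mv)
  push(rep(nsys, nP), 2L * nV + seq_len(nP), mv)
  A <- Matrix::sparseMatrix(i = unlist(ii), j = unlist(jj), x = unlist(xx),
                            dims = c(nsys, nsys))
  # Dirichlet data
  sph <- boundary_dofs(vsp, "sphere")
  outer <- boundary_dofs(vsp, "outer")
  axis <- boundary_dofs(vsp, "axis")
  exo <- stokes_sphere_exact(vsp$dof_coords[outer, 1],
                             vsp$dof_coords[outer, 2], a, U, props)
  cdofs <- c(sph, nV + sph, outer, nV + outer, setdiff(axis, c(sph, outer)))
  cvals <- c(rep(0, 2 * length(sph)), exo$u_r, exo$u_z,
             rep(0, length(setdiff(axis, c(sph, outer)))))
  F <- numeric(nsys)
  x <- solve_constrained(A, F, cdofs, cvals)
  u <- cbind(x[seq_len(nV)], x[nV + seq_len(nV)])
  p <- x[2L * nV + seq_len(nP)]
  # traction on the sphere by direct stress evaluation at facet midpoints
  # from the adjacent element (the strongly graded near-wall mesh makes the
  # P2 boundary gradient accurate and node-wise smooth here)
  sel <- which(mesh$facet_patch == "sphere")
  af <- all_cell_facets(mesh$cells, 2L)
  keys <- facet_key(af)
  cellof <- rep(seq_len(nrow(mesh$cells)), 3L)
  adj <- cellof[match(facet_key(mesh$facets[sel, , drop = FALSE]), keys)]
  mag <- theta <- numeric(length(sel))
  for (kf in seq_along(sel)) {
    fi <- mesh$facets[sel[kf], ]
    xm <- colMeans(mesh$points[fi, , drop = FALSE])
    c0 <- adj[kf]
    verts <- mesh$points[mesh$cells[c0, ], ]
    Amat <- rbind(1, t(verts))
    lam <- solve(Amat, c(1, xm))
    se <- shape_eval(2L, lam)
    gl <- geom$gradlam[c0, , ]               # (d+1) x 2
    gradN <- se$C %*% gl                     # nb x 2
    dofs <- vsp$cell_dofs[c0, ]
    gradu <- t(u[dofs, , drop = FALSE]) %*% gradN   # 2x2: du_a/dx_b
    pm <- sum(lam * p[mesh$cells[c0, ]])
    sig <- -pm * diag(2) + mu * (gradu + t(gradu))
    nrm <- -xm / sqrt(sum(xm^2))
    tvec <- as.vector(sig %*% nrm)
    tau <- tvec - sum(tvec * nrm) * nrm
    mag[kf] <- sqrt(sum(tau^2))
    theta[kf] <- atan2(xm[1], xm[2])
  }
  list(u = u, p = p, wss = mag, theta = theta, peak_wss = max(mag))
}


#' Run one analytic verification case
#'
#' Each case runs at two or more resolutions, compares the computed
#' quantity with its closed-form oracle, and reports relative errors and
#' the observed convergence behaviour.
#'
#' Cases: `poiseuille_wss` (steady channel, stabilized equal-order pair,
#' consistent-flux WSS vs `6 mu U / h`), `womersley_wss` (oscillatory
#' channel at the regular-breathing frequency vs the analytic series),
#' `stokes_sphere_wss` (axisymmetric creeping flow past a sphere vs
#' `1.5 mu U / a`), `isovolumetry` (cavity volume drift over a forcing
#' cycle), `gcl_uniform_translation` (uniform flow preserved on a rigidly
#' translating mesh), `bioreactor_linearity` (FSS-vs-inlet-speed slope
#' constancy across a decade).
#'
#' @param case case name.
#' @param resolution_scale multiplies the baseline mesh resolutions.
#' @return list of class `af_verification_report`.
#' @export
verify <- function(case = c("poiseuille_wss", "womersley_wss",
                            "stokes_sphere_wss", "isovolumetry",
                            "gcl_uniform_translation",
                            "bioreactor_linearity"),
                   resolution_scale = 1) {
  if (length(case) > 1 || !case[1] %in% c("poiseuille_wss", "womersley_wss",
      "stokes_sphere_wss", "isovolumetry", "gcl_uniform_translation",
      "bioreactor_linearity"))
    case <- match.arg(case)
  fn <- switch(case,
    poiseuille_wss = verify_poiseuille,
    womersley_wss = verify_womersley,
    stokes_sphere_wss = verify_stokes_sphere,
    isovolumetry = verify_isovolumetry,
    gcl_uniform_translation = verify_gcl,
    bioreactor_linearity = verify_bioreactor_linearity)
  fn(resolution_scale)
}

vreport <- function(case, resolutions, computed, oracle, tol,
                    extra = list()) {
  err <- abs(computed - oracle) / abs(oracle)
  # observed order under successive (factor-2) refinement
  ord <- if (length(err) >= 2 && all(err > 0))
    log2(err[length(err) - 1] / err[length(err)]) else NA_real_
  structure(c(list(case = case, resolutions = resolutions,
                   computed = computed, oracle = oracle,
                   rel_errors = err, tolerance = tol,
                   observed_order = ord,
                   pass = err[length(err)] <= tol,
                   monotone = all(diff(err) < 0)), extra),
            class = "af_verification_report")
}

#' @export
print.af_verification_report <- function(x, ...) {
  cat(sprintf("<verify:%s> oracle %.6g, tol %.3g, %s\n", x$case,
              x$oracle[1], x$tolerance, if (x$pass) "PASS" else "FAIL"))
  for (i in seq_along(x$rel_errors))
    cat(sprintf("  res %-8s computed %.6g  rel err %.3e\n",
                paste(x$resolutions[[i]], collapse = "x"),
                x$computed[i], x$rel_errors[i]))
  invisible(x)
}

verify_poiseuille <- function(scale = 1) {
  props <- fluid_properties()
  h <- 0.004; L <- 2 * h; G <- 0.5
  U <- G * h^2 / (12 * props$dynamic_viscosity)
  oracle <- 6 * props$dynamic_viscosity * U / h   # = G h / 2
  nys <- pmax(4L, as.integer(round(c(6, 12, 24) * scale)))
  computed <- vapply(nys, function(ny) {
    ch <- channel_steady(2L * ny, ny, L, h, G, props,
                         element_pair = "equal_order_stabilized")
    channel_bottom_wss(ch, props)
  }, numeric(1))
  vreport("poiseuille_wss", as.list(nys), computed, oracle, tol = 0.02)
}

verify_womersley <- function(scale = 1) {
  props <- fluid_properties()
  f <- 0.37; omega <- 2 * pi * f
  h <- 0.0043; L <- h; G <- 0.2
  nys <- pmax(6L, as.integer(round(c(10, 20) * scale)))
  nxs <- pmax(4L, as.integer(round(c(5, 10) * scale)))
  prof_err <- wss_err <- numeric(length(nys))
  for (k in seq_along(nys)) {
    run <- channel_womersley_run(nxs[k], nys[k], L, h, G, omega, props)
    prof_err[k] <- womersley_profile_error(run, h, G, omega, props)
    amp <- womersley_wall_shear_amplitude(h, G, omega, props)
    wss_err[k] <- abs(max(run$wss_series) - amp) / amp
  }
  amp <- womersley_wall_shear_amplitude(h, G, omega, props)
  rep <- vreport("womersley_wss", as.list(nys),
                 computed = amp * (1 + wss_err), oracle = amp, tol = 0.05,
                 extra = list(profile_l2_errors = prof_err,
                              profile_tolerance = 0.05,
                              profile_pass = prof_err[length(prof_err)] <= 0.05))
  rep$pass <- rep$pass && rep$profile_pass
  rep
}

verify_stokes_sphere <- function(scale = 1) {
  props <- fluid_properties()
  a <- 1e-3; R <- 4e-3; U <- 1e-4
  oracle <- 1.5 * props$dynamic_viscosity * U / a
  res <- list(c(24L, 12L), c(48L, 24L))
  res <- lapply(res, function(r) pmax(8L, as.integer(round(r * scale))))
  computed <- vapply(res, function(r) {
    mesh <- sphere_shell_mesh(r[1], r[2], a, R)
    stokes_sphere_solve(mesh, a, U, props)$peak_wss
  }, numeric(1))
  vreport("stokes_sphere_wss", res, computed, oracle, tol = 0.05)
}

verify_isovolumetry <- function(scale = 1) {
  spec <- cavity_spec(mesh_size = 0.005 / max(scale, 0.25))
  mesh <- build_cavity_mesh(spec)
  pre <- preset("regular")
  V0 <- enclosed_volume(mesh)
  basis <- lateral_compensation_basis(mesh, spec$z_ov)
  ts <- seq(0, 1 / pre$frequency, length.out = 41L)
  drift <- vapply(ts, function(t) {
    mo <- cavity_boundary_motion(mesh, pre, spec$z_ov, t, basis = basis,
                                 V0 = V0)
    p <- mesh$points
    p[mo$nodes, ] <- p[mo$nodes, , drop = FALSE] + mo$values
    abs(enclosed_volume(mesh, p) - V0) / V0
  }, numeric(1))
  vreport("isovolumetry", list(length(ts)), computed = max(drift) + 1,
          oracle = 1, tol = 1e-3,
          extra = list(max_drift = max(drift)))
}

verify_gcl <- function(scale = 1) {
  props <- fluid_properties()
  mesh <- build_cavity_mesh(cavity_spec(mesh_size = 0.02 / max(scale, 0.5)))
  cvec <- c(0.05, -0.02); dt <- 0.05
  st <- solver_settings(dt = dt)
  state <- flow_state_rest(mesh, st)
  state$u <- matrix(rep(cvec, each = nrow(state$u)), ncol = 2)
  X <- mesh$points
  nn <- nrow(X)
  for (n in 1:4) {
    pts <- X + n * dt * matrix(rep(cvec, each = nn), ncol = 2)
    w <- matrix(rep(cvec, each = nn), ncol = 2)
    state <- advance_flow(state, mesh, list(points = pts, w = w), props, st)
  }
  spur <- max(abs(sweep(state$u, 2, cvec))) / sqrt(sum(cvec^2))
  vreport("gcl_uniform_translation", list(nrow(mesh$cells)),
          computed = spur + 1, oracle = 1, tol = 1e-8,
          extra = list(spurious_velocity = spur))
}

verify_bioreactor_linearity <- function(scale = 1) {
  props <- fluid_properties()
  cell <- cell_model()
  solver <- cell_channel_solver(cell, props,
                                resolution_scale = max(scale, 0.5))
  Us <- cell$inlet_speed * c(0.3, 1, 3)
  slopes <- vapply(Us, function(U) {
    pk <- peak_cell_fss(solver$profile(U))$peak
    pk / U
  }, numeric(1))
  dev <- max(abs(slopes - mean(slopes))) / mean(slopes)
  vreport("bioreactor_linearity", as.list(Us),
          computed = slopes, oracle = mean(slopes), tol = 0.005,
          extra = list(slope_deviation = dev))
}
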
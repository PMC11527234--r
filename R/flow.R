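#' Fluid properties
#'
#' Ascites is modelled as an incompressible Newtonian fluid; the defaults
#' are the ascitic-fluid density 1017.5 kg/m^3 and viscosity 0.0012 Pa s.
#'
#' @param density kg/m^3, > 0.
#' @param dynamic_viscosity Pa s, > 0.
#' @export
fluid_properties <- function(density = 1017.5, dynamic_viscosity = 0.0012) {
  stopifnot(density > 0, dynamic_viscosity > 0)
  structure(list(density = density, dynamic_viscosity = dynamic_viscosity),
            class = "af_fluid_properties")
}

#' Flow solver settings
#'
#' Discretization choices for the incompressible (ALE) Navier-Stokes
#' solver.
#'
#' @param dt time step (s); if `NULL`, derived as `1 / (frequency *
#'   steps_per_cycle)` by [run_cycles()].
#' @param n_cycles forcing cycles to run (default 3).
#' @param steps_per_cycle time steps per forcing cycle when `dt` is
#'   derived.
#' @param element_pair `"taylor_hood"` (P2/P1, inf-sup stable) or
#'   `"equal_order_stabilized"` (P1/P1 with a Brezzi-Pitkaranta pressure
#'   Laplacian).
#' @param time_scheme backward differencing order 1 (robust default) or 2.
#' @param linearization `"picard"` or `"newton"` treatment of convection.
#' @param nonlinear_tolerance relative increment tolerance of the
#'   nonlinear loop.
#' @param max_nonlinear_iterations cap on nonlinear iterations per step; a
#'   step that still exceeds the tolerance at the cap proceeds
#'   (semi-implicit first-order linearization) with the achieved residual
#'   recorded; growth of the increment errors out as divergence.
#' @param linear_tolerance residual tolerance of the sparse direct solve
#'   (diagnostic).
#' @param pressure_constraint `"zero_mean"` (Lagrange multiplier),
#'   `"pin_node"`, or `"none"` (valid with a natural outflow boundary).
#' @param include_convection `FALSE` drops the convective term (Stokes
#'   test mode).
#' @param sd_constant streamline-diffusion stabilization constant for the
#'   convective term (0 disables; used for the under-resolved cavity runs).
#' @param pressure_stab_constant Brezzi-Pitkaranta constant for the
#'   equal-order pair.
#' @param snapshot_stride record every k-th step in [run_cycles()].
#' @export
solver_settings <- function(dt = NULL, n_cycles = 3L, steps_per_cycle = 100L,
                            element_pair = c("taylor_hood",
                                             "equal_order_stabilized"),
                            time_scheme = c("backward_difference_1",
                                            "backward_difference_2"),
                            linearization = c("picard", "newton"),
                            nonlinear_tolerance = 1e-6,
                            max_nonlinear_iterations = 15L,
                            linear_tolerance = 1e-8,
                            pressure_constraint = c("zero_mean", "pin_node",
                                                    "none"),
                            include_convection = TRUE, sd_constant = 0,
                            pressure_stab_constant = 0.05,
                            snapshot_stride = 5L) {
  element_pair <- match.arg(element_pair)
  time_scheme <- match.arg(time_scheme)
  linearization <- match.arg(linearization)
  pressure_constraint <- match.arg(pressure_constraint)
  stopifnot(is.null(dt) || dt > 0, n_cycles >= 1, nonlinear_tolerance > 0,
            linear_tolerance > 0, max_nonlinear_iterations >= 1,
            steps_per_cycle >= 4, snapshot_stride >= 1)
  structure(list(dt = dt, n_cycles = as.integer(n_cycles),
                 steps_per_cycle = as.integer(steps_per_cycle),
                 element_pair = element_pair, time_scheme = time_scheme,
                 linearization = linearization,
                 nonlinear_tolerance = nonlinear_tolerance,
                 max_nonlinear_iterations = as.integer(max_nonlinear_iterations),
                 linear_tolerance = linear_tolerance,
                 pressure_constraint = pressure_constraint,
                 include_convection = include_convection,
                 sd_constant = sd_constant,
                 pressure_stab_constant = pressure_stab_constant,
                 snapshot_stride = as.integer(snapshot_stride)),
            class = "af_solver_settings")
}

velocity_order <- function(settings)
  if (settings$element_pair == "taylor_hood") 2L else 1L

#' Solver settings tuned for the desk-scale cavity runs
#'
#' The breathing-driven cavity at ascitic fluid properties is strongly
#' convection-dominated at desk resolution; these defaults resolve the
#' forcing cycle (80 implicit steps per cycle, CFL about 0.5), apply
#' streamline diffusion along the convective direction, and cap the
#' Picard loop at two iterations per step (a first-order-consistent
#' semi-implicit linearization matching the BDF1 order; the achieved
#' increment is recorded on every state).
#'
#' @param ... overrides passed to [solver_settings()].
#' @export
cavity_run_settings <- function(...) {
  args <- list(steps_per_cycle = 80L, max_nonlinear_iterations = 2L,
               nonlinear_tolerance = 1e-4, sd_constant = 0.5,
               snapshot_stride = 4L)
  override <- list(...)
  args[names(override)] <- override
  do.call(solver_settings, args)
}

# Interpolate per-node (P1) data into the velocity space (midpoint dofs get
# edge averages, exact for P1 data).
nodal_to_space <- function(vsp, X) {
  X <- as.matrix(X)
  if (vsp$order == 1L) return(X)
  ed <- vsp$edges
  rbind(X, (X[ed$edges[, 1], , drop = FALSE] +
            X[ed$edges[, 2], , drop = FALSE]) / 2)
}

# Dirichlet data on all boundary velocity dofs from nodal wall velocity.
bc_wall_velocity <- function(vsp, w_nodes) {
  bd <- boundary_dofs(vsp)
  wv <- nodal_to_space(vsp, w_nodes)
  d <- ncol(wv)
  dofs <- as.vector(outer(bd, (seq_len(d) - 1L) * vsp$ndof, `+`))
  vals <- as.vector(wv[bd, ])
  list(dofs = dofs, vals = vals)
}

# Dirichlet data on selected patches from a function of dof coordinates.
# components: integer vector of constrained components.
bc_patch <- function(vsp, patches, fun, components = seq_len(ncol(vsp$points))) {
  bd <- boundary_dofs(vsp, patches)
  vals <- fun(vsp$dof_coords[bd, , drop = FALSE])
  vals <- as.matrix(vals)
  dofs <- NULL; vv <- NULL
  for (k in seq_along(components)) {
    a <- components[k]
    dofs <- c(dofs, (a - 1L) * vsp$ndof + bd)
    vv <- c(vv, vals[, k])
  }
  list(dofs = dofs, vals = vv)
}

merge_bc <- function(...) {
  parts <- list(...)
  dofs <- unlist(lapply(parts, `[[`, "dofs"))
  vals <- unlist(lapply(parts, `[[`, "vals"))
  keep <- !duplicated(dofs)       # first specification wins
  list(dofs = dofs[keep], vals = vals[keep])
}

# Assemble the time-invariant-per-step part of the (Navier-)Stokes system
# on the current coordinates. Returns the operator context reused by the
# nonlinear loop and the traction extraction.
flow_operator <- function(mesh, points, props, settings, dtc = NULL) {
  d <- mesh$dim
  vorder <- velocity_order(settings)
  vsp <- fem_space(mesh, vorder, points)
  psp <- fem_space(mesh, 1L, points)
  geom <- fem_geom(mesh, points)
  rule <- default_volume_rule(d)
  bV <- fem_basis_at_quad(geom, vorder, rule)
  bP <- fem_basis_at_quad(geom, 1L, rule)
  nV <- vsp$ndof; nP <- psp$nn
  mu <- props$dynamic_viscosity
  has_mult <- settings$pressure_constraint == "zero_mean"
  nsys <- d * nV + nP + as.integer(has_mult)

  M <- asm_mass(vsp, geom, bV)           # scalar velocity mass
  ii <- jj <- xx <- list(); k <- 1L
  push <- function(i, j, x) {
    ii[[k]] <<- i; jj[[k]] <<- j; xx[[k]] <<- x; k <<- k + 1L
  }
  # viscous blocks mu * (delta_ab grad.grad + dNj/da dNi/db)
  nb <- bV$nb
  for (a in seq_len(d)) for (b in seq_len(d)) {
    for (i in seq_len(nb)) for (j in seq_len(nb)) {
      acc <- 0
      for (q in seq_len(bV$nq)) {
        G <- bV$G[[q]]
        s <- G[[a]][, j] * G[[b]][, i]
        if (a == b) {
          for (kk in seq_len(d)) s <- s + G[[kk]][, i] * G[[kk]][, j]
        }
        acc <- acc + bV$w[q] * s
      }
      push((a - 1L) * nV + vsp$cell_dofs[, i],
           (b - 1L) * nV + vsp$cell_dofs[, j], mu * geom$vol * acc)
    }
  }
  # time term on the diagonal blocks
  if (!is.null(dtc)) {
    Mt <- props$density * dtc$c0 / dtc$dt * M
    trip <- Matrix::mat2triplet(Mt)
    for (a in seq_len(d))
      push((a - 1L) * nV + trip$i, (a - 1L) * nV + trip$j, trip$x)
  }
  # pressure gradient and continuity blocks
  np1 <- d + 1L
  for (a in seq_len(d)) for (i in seq_len(nb)) for (l in seq_len(np1)) {
    acc <- 0
    for (q in seq_len(bV$nq))
      acc <- acc + bV$w[q] * bP$N[[q]][l] * bV$G[[q]][[a]][, i]
    val <- -geom$vol * acc
    push((a - 1L) * nV + vsp$cell_dofs[, i],
         d * nV + psp$cell_dofs[, l], val)
    push(d * nV + psp$cell_dofs[, l],
         (a - 1L) * nV + vsp$cell_dofs[, i], val)
  }
  # equal-order pressure stabilization (Brezzi-Pitkaranta)
  if (settings$element_pair == "equal_order_stabilized") {
    he2 <- (factorial(d) * geom$vol)^(2 / d)
    gam <- settings$pressure_stab_constant
    for (i in seq_len(np1)) for (j in seq_len(np1)) {
      acc <- 0
      for (q in seq_len(bP$nq)) {
        G <- bP$G[[q]]
        s <- 0
        for (kk in seq_len(d)) s <- s + G[[kk]][, i] * G[[kk]][, j]
        acc <- acc + bP$w[q] * s
      }
      push(d * nV + psp$cell_dofs[, i], d * nV + psp$cell_dofs[, j],
           -gam * he2 / mu * geom$vol * acc)
    }
  }
  if (has_mult) {
    mvec <- asm_load(psp, geom, bP, 1)
    push(d * nV + seq_len(nP), rep(nsys, nP), mvec)
    push(rep(nsys, nP), d * nV + seq_len(nP), mvec)
  }
  A0 <- Matrix::sparseMatrix(i = unlist(ii), j = unlist(jj), x = unlist(xx),
                             dims = c(nsys, nsys))
  list(mesh = mesh, points = points, vsp = vsp, psp = psp, geom = geom,
       bV = bV, bP = bP, M = M, A0 = A0, nV = nV, nP = nP, d = d,
       nsys = nsys, has_mult = has_mult, props = props, settings = settings,
       dtc = dtc)
}

# Convective (+ streamline-diffusion, + optional Newton) contribution for a
# given convective velocity field beta (nV x d dof values) and state u_star.
convection_matrix <- function(opctx, beta, newton_u = NULL) {
  vsp <- opctx$vsp; geom <- opctx$geom; bV <- opctx$bV
  d <- opctx$d; nV <- opctx$nV
  rho <- opctx$props$density
  betaq <- field_at_quad(vsp, bV, beta)
  sd_c <- opctx$settings$sd_constant
  tau <- NULL
  if (sd_c > 0) {
    speed <- 0
    for (q in seq_len(bV$nq)) speed <- speed + sqrt(rowSums(betaq[[q]]^2))
    speed <- speed / bV$nq
    he <- (factorial(d) * geom$vol)^(1 / d)
    tau <- sd_c * he / (2 * pmax(speed, 1e-12))
  }
  nb <- bV$nb
  ii <- jj <- xx <- list(); k <- 1L
  for (i in seq_len(nb)) for (j in seq_len(nb)) {
    acc <- 0; accsd <- 0
    for (q in seq_len(bV$nq)) {
      G <- bV$G[[q]]
      bgradj <- 0
      for (kk in seq_len(d)) bgradj <- bgradj + betaq[[q]][, kk] * G[[kk]][, j]
      acc <- acc + bV$w[q] * bV$N[[q]][i] * bgradj
      if (!is.null(tau)) {
        bgradi <- 0
        for (kk in seq_len(d)) bgradi <- bgradi + betaq[[q]][, kk] * G[[kk]][, i]
        accsd <- accsd + bV$w[q] * bgradi * bgradj
      }
    }
    val <- rho * geom$vol * acc
    if (!is.null(tau)) val <- val + rho * geom$vol * tau * accsd
    for (a in seq_len(d)) {
      ii[[k]] <- (a - 1L) * nV + vsp$cell_dofs[, i]
      jj[[k]] <- (a - 1L) * nV + vsp$cell_dofs[, j]
      xx[[k]] <- val
      k <- k + 1L
    }
  }
  if (!is.null(newton_u)) {
    # cross-coupling rho * int N_i N_j d(u*_a)/d(x_b)
    gradu <- grad_at_quad(opctx, newton_u)   # list[q][[a]][[b]] ne-vectors
    for (a in seq_len(d)) for (b in seq_len(d)) {
      for (i in seq_len(nb)) for (j in seq_len(nb)) {
        acc <- 0
        for (q in seq_len(bV$nq))
          acc <- acc + bV$w[q] * bV$N[[q]][i] * bV$N[[q]][j] *
            gradu[[q]][[a]][[b]]
        ii[[k]] <- (a - 1L) * nV + vsp$cell_dofs[, i]
        jj[[k]] <- (b - 1L) * nV + vsp$cell_dofs[, j]
        xx[[k]] <- rho * geom$vol * acc
        k <- k + 1L
      }
    }
  }
  Matrix::sparseMatrix(i = unlist(ii), j = unlist(jj), x = unlist(xx),
                       dims = c(opctx$nsys, opctx$nsys))
}

# gradient of a velocity-space field at quadrature points
grad_at_quad <- function(opctx, U) {
  vsp <- opctx$vsp; bV <- opctx$bV; d <- opctx$d
  lapply(seq_len(bV$nq), function(q) {
    G <- bV$G[[q]]
    lapply(seq_len(d), function(a) {
      Ua <- U[, a]
      lapply(seq_len(d), function(b) {
        out <- 0
        for (i in seq_len(bV$nb))
          out <- out + G[[b]][, i] * Ua[vsp$cell_dofs[, i]]
        out
      })
    })
  })
}

# RHS for one step: time history + body force. body_force: NULL, length-d
# vector, or function(coords) -> n x d.
flow_rhs <- function(opctx, u_old = NULL, u_older = NULL, body_force = NULL) {
  d <- opctx$d; nV <- opctx$nV
  F <- numeric(opctx$nsys)
  dtc <- opctx$dtc
  if (!is.null(dtc)) {
    rho <- opctx$props$density
    hist <- dtc$c1 * u_old
    if (dtc$c2 != 0) hist <- hist + dtc$c2 * u_older
    for (a in seq_len(d))
      F[(a - 1L) * nV + seq_len(nV)] <-
        rho / dtc$dt * as.vector(opctx$M %*% hist[, a])
  }
  if (!is.null(body_force)) {
    if (is.function(body_force)) {
      xq <- field_at_quad(opctx$vsp, opctx$bV,
                          opctx$vsp$dof_coords)   # coords at quad pts
      for (a in seq_len(d)) {
        fq <- vapply(seq_len(opctx$bV$nq),
                     function(q) body_force(xq[[q]])[, a],
                     numeric(length(opctx$geom$vol)))
        F[(a - 1L) * nV + seq_len(nV)] <-
          F[(a - 1L) * nV + seq_len(nV)] +
          asm_load(opctx$vsp, opctx$geom, opctx$bV, fq)
      }
    } else {
      for (a in seq_len(d)) {
        if (body_force[a] != 0)
          F[(a - 1L) * nV + seq_len(nV)] <-
            F[(a - 1L) * nV + seq_len(nV)] +
            asm_load(opctx$vsp, opctx$geom, opctx$bV, body_force[a])
      }
    }
  }
  F
}

bdf_coeffs <- function(scheme, dt, have_older) {
  if (scheme == "backward_difference_2" && have_older)
    list(dt = dt, c0 = 1.5, c1 = 2, c2 = -0.5)
  else list(dt = dt, c0 = 1, c1 = 1, c2 = 0)
}

# One nonlinear flow solve on the given operator context.
flow_solve <- function(opctx, bc, u_old = NULL, u_older = NULL,
                       body_force = NULL, w_space = NULL, u_init = NULL) {
  st <- opctx$settings
  d <- opctx$d; nV <- opctx$nV
  F <- flow_rhs(opctx, u_old, u_older, body_force)
  cdofs <- bc$dofs; cvals <- bc$vals
  if (st$pressure_constraint == "pin_node") {
    cdofs <- c(cdofs, d * nV + 1L); cvals <- c(cvals, 0)
  }
  uk <- if (!is.null(u_init)) u_init else if (!is.null(u_old)) u_old
        else matrix(0, nV, d)
  err <- NA_real_; niter <- 0L
  x <- NULL; Alast <- opctx$A0; Flast <- F
  if (!st$include_convection) {
    x <- solve_constrained(opctx$A0, F, cdofs, cvals)
    niter <- 1L; err <- 0
  } else {
    prev_err <- Inf
    for (it in seq_len(st$max_nonlinear_iterations)) {
      beta <- if (is.null(w_space)) uk else uk - w_space
      Cn <- convection_matrix(opctx, beta,
        newton_u = if (st$linearization == "newton") uk else NULL)
      Fi <- F
      if (st$linearization == "newton") {
        uf <- c(as.vector(uk), numeric(opctx$nsys - d * nV))
        # restore the rhs counterpart of the Newton cross term
        Nw <- convection_matrix(opctx, 0 * uk, newton_u = uk)
        Fi <- F + as.vector(Nw %*% uf)
      }
      Alast <- opctx$A0 + Cn; Flast <- Fi
      x <- solve_constrained(Alast, Fi, cdofs, cvals)
      un <- matrix(x[seq_len(d * nV)], nV, d)
      scale <- max(sqrt(mean(un^2)), 1e-14)
      err <- sqrt(mean((un - uk)^2)) / scale
      uk <- un
      niter <- it
      if (!is.finite(err) || err > 100 * prev_err + 1e-12)
        stop(sprintf("nonlinear divergence at iteration %d (increment %.3g)",
                     it, err))
      if (err < st$nonlinear_tolerance) break
      prev_err <- max(err, 1e-300)
    }
  }
  u <- matrix(x[seq_len(d * nV)], nV, d)
  p <- x[d * nV + seq_len(opctx$nP)]
  # consistent-flux ingredients: the PDE operator and rhs actually solved
  list(u = u, p = p, x = x, A = Alast, F = Flast,
       nonlinear_error = err, iterations = niter)
}

#' Advance the ALE Navier-Stokes state by one time step
#'
#' Solves the incompressible Newtonian momentum/continuity system on the
#' displaced mesh configuration at the new time level, with the ALE
#' convective velocity `u - w` and `u = w` on all walls (no-slip on the
#' moving boundary) unless a custom `bc` is supplied.
#'
#' @param state flow state: list with `u` (velocity dofs x d), `p`, `time`,
#'   `points` (node coordinates at the state time), optional `u_prev`.
#'   Use [flow_state_rest()] to create the initial state.
#' @param mesh reference [af_mesh].
#' @param motion list with `points` (node coordinates at `t + dt`) and `w`
#'   (nodal mesh velocity at `t + dt`, m/s).
#' @param props [fluid_properties()].
#' @param settings [solver_settings()]; `settings$dt` must be set.
#' @param bc optional Dirichlet spec `list(dofs, vals)` overriding the
#'   moving-wall no-slip condition.
#' @param body_force optional constant vector or `function(coords)`.
#' @return the new flow state (class `af_flow_state`), carrying the
#'   assembled operator in `$opr` for wall-traction extraction.
#' @export
advance_flow <- function(state, mesh, motion, props, settings, bc = NULL,
                         body_force = NULL) {
  dt <- settings$dt
  if (is.null(dt)) stop("settings$dt must be set for advance_flow")
  dtc <- bdf_coeffs(settings$time_scheme, dt, !is.null(state$u_prev))
  opctx <- flow_operator(mesh, motion$points, props, settings, dtc)
  w_space <- nodal_to_space(opctx$vsp, motion$w)
  if (is.null(bc)) bc <- bc_wall_velocity(opctx$vsp, motion$w)
  sol <- flow_solve(opctx, bc, u_old = state$u, u_older = state$u_prev,
                    body_force = body_force, w_space = w_space,
                    u_init = state$u)
  structure(list(u = sol$u, p = sol$p, u_prev = state$u,
                 time = state$time + dt, points = motion$points,
                 w = motion$w,
                 nonlinear_error = sol$nonlinear_error,
                 iterations = sol$iterations,
                 opr = list(A = sol$A, F = sol$F, vsp = opctx$vsp,
                            psp = opctx$psp, nV = opctx$nV, d = opctx$d)),
            class = "af_flow_state")
}

#' Initial quiescent flow state
#'
#' @param mesh reference [af_mesh].
#' @param settings [solver_settings()] (fixes the velocity space order).
#' @return an `af_flow_state` at rest at `t = 0`.
#' @export
flow_state_rest <- function(mesh, settings = solver_settings()) {
  vsp <- fem_space(mesh, velocity_order(settings))
  structure(list(u = matrix(0, vsp$ndof, mesh$dim),
                 p = numeric(nrow(mesh$points)), u_prev = NULL,
                 time = 0, points = mesh$points,
                 w = matrix(0, nrow(mesh$points), mesh$dim)),
            class = "af_flow_state")
}

#' Run the breathing-driven cavity simulation
#'
#' Orchestrates the isovolumetric boundary kinematics, pseudo-solid mesh
#' motion and ALE flow solves over `preset$n_cycles` forcing cycles,
#' starting from rest, recording strided snapshots with wall shear stress
#' fields on every patch.
#'
#' @param mesh cavity [af_mesh] from [build_cavity_mesh()].
#' @param preset an `af_breathing_preset`.
#' @param spec the [cavity_spec()] used to build the mesh (provides the
#'   ovary reference height); alternatively pass `z_ov`.
#' @param props [fluid_properties()].
#' @param settings [solver_settings()].
#' @param z_ov ovary reference height (m), overrides `spec`.
#' @return `af_flow_history`: snapshots, per-patch WSS fields, volume
#'   drift, periodicity diagnostics.
#' @export
run_cycles <- function(mesh, preset, spec = NULL,
                       props = fluid_properties(),
                       settings = solver_settings(), z_ov = NULL) {
  if (is.null(z_ov)) {
    if (!is.null(spec)) z_ov <- spec$z_ov else z_ov <- guess_z_ov(mesh)
  }
  dt <- settings$dt %||% (1 / (preset$frequency * settings$steps_per_cycle))
  spc <- as.integer(round(1 / (preset$frequency * dt)))
  settings$dt <- dt
  n_steps <- spc * preset$n_cycles
  V0 <- enclosed_volume(mesh)
  basis <- lateral_compensation_basis(mesh, z_ov)
  mop <- mesh_motion_operator(mesh)
  state <- flow_state_rest(mesh, settings)
  d_prev <- matrix(0, nrow(mesh$points), mesh$dim)
  snapshots <- list(); wss <- list(); times <- c()
  vol_drift <- numeric(n_steps)
  for (n in seq_len(n_steps)) {
    t_new <- n * dt
    bd <- cavity_boundary_motion(mesh, preset, z_ov, t_new, basis = basis,
                                 V0 = V0)
    disp <- solve_mesh_motion(mesh, bd, op = mop)
    w <- (disp - d_prev) / dt
    pts <- mesh$points + disp
    vol_drift[n] <- abs(enclosed_volume(mesh, pts) - V0) / V0
    state <- tryCatch(
      advance_flow(state, mesh, list(points = pts, w = w), props, settings),
      error = function(e) stop("flow step failed at t = ", signif(t_new, 6),
                               " s: ", conditionMessage(e)))
    d_prev <- disp
    if (n %% settings$snapshot_stride == 0L) {
      wssf <- wss_fields(state, mesh, props)
      snap <- state; snap$opr <- NULL
      snapshots[[length(snapshots) + 1L]] <- snap
      wss[[length(wss) + 1L]] <- wssf
      times <- c(times, t_new)
    }
  }
  structure(list(snapshots = snapshots, wss = wss, times = times,
                 stride = settings$snapshot_stride,
                 steps_per_cycle = spc, n_cycles = preset$n_cycles,
                 preset = preset, mesh = mesh, settings = settings,
                 props = props, z_ov = z_ov,
                 volume_drift = vol_drift, V0 = V0),
            class = "af_flow_history")
}

#' @export
print.af_flow_history <- function(x, ...) {
  cat(sprintf("<af_flow_history> %d cycles, %d snapshots, dt = %.4g s\n",
              x$n_cycles, length(x$snapshots), x$settings$dt))
  cat(sprintf("  max |V(t) - V0|/V0 = %.3g\n", max(x$volume_drift)))
  invisible(x)
}

#' Relative incompressibility defect of a flow state
#'
#' `||div u||_L2 / ||grad u||_L2` over the domain (0 for a quiescent
#' state by convention).
#'
#' @param state an `af_flow_state`.
#' @param mesh the [af_mesh] (reference topology).
#' @param settings solver settings fixing the element order.
#' @return dimensionless defect.
#' @export
divergence_norm <- function(state, mesh, settings = solver_settings()) {
  vorder <- if (!is.null(state$opr)) state$opr$vsp$order
            else velocity_order(settings)
  vsp <- fem_space(mesh, vorder, state$points)
  geom <- fem_geom(mesh, state$points)
  bV <- fem_basis_at_quad(geom, vorder, default_volume_rule(mesh$dim))
  d <- mesh$dim
  div2 <- 0; grad2 <- 0
  for (q in seq_len(bV$nq)) {
    G <- bV$G[[q]]
    dv <- 0
    for (a in seq_len(d)) {
      ga <- 0
      for (i in seq_len(bV$nb))
        ga <- ga + G[[a]][, i] * state$u[vsp$cell_dofs[, i], a]
      dv <- dv + ga
      for (b in seq_len(d)) {
        gb <- 0
        for (i in seq_len(bV$nb))
          gb <- gb + G[[b]][, i] * state$u[vsp$cell_dofs[, i], a]
        grad2 <- grad2 + sum(bV$w[q] * geom$vol * gb^2)
      }
    }
    div2 <- div2 + sum(bV$w[q] * geom$vol * dv^2)
  }
  # Grundmann-Moeller weights are partly negative: clamp the tiny
  # round-off-negative sums of squares
  div2 <- max(div2, 0); grad2 <- max(grad2, 0)
  if (grad2 == 0) return(0)
  sqrt(div2 / grad2)
}

#' Cycle-to-cycle periodicity residual
#'
#' Relative L2 difference of the velocity snapshots between matching
#' phases of two consecutive forcing cycles (default: the last two),
#' quantifying how close the run is to a periodic state.
#'
#' @param history `af_flow_history` with at least two full cycles of
#'   snapshots.
#' @param cycle index of the later cycle to compare (default last).
#' @return dimensionless relative residual.
#' @export
periodicity_residual <- function(history, cycle = NULL) {
  sp_per_cycle <- history$steps_per_cycle %/% history$stride
  ncyc <- length(history$snapshots) %/% sp_per_cycle
  if (ncyc < 2) stop("need at least two recorded cycles")
  if (is.null(cycle)) cycle <- ncyc
  stopifnot(cycle >= 2, cycle <= ncyc)
  i2 <- (cycle - 1L) * sp_per_cycle + seq_len(sp_per_cycle)
  i1 <- i2 - sp_per_cycle
  num <- 0; den <- 0
  for (s in seq_len(sp_per_cycle)) {
    u2 <- history$snapshots[[i2[s]]]$u
    u1 <- history$snapshots[[i1[s]]]$u
    num <- num + sum((u2 - u1)^2)
    den <- den + sum(u2^2)
  }
  if (den == 0) return(0)
  sqrt(num / den)
}
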
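# Two-stage perfusion-bioreactor shear model: Brinkman flow through the
# cell-laden hydrogel plug sets a volume-averaged speed, which drives an
# idealized-cell open-channel submodel whose peak surface FSS is the
# operating quantity. Inverse design finds the pump setting realizing a
# target FSS (the in vitro levels are 1, 5 and 11 dynes/cm^2).

#' Hydrogel plug specification
#'
#' Material and geometric parameters of the agarose/collagen IPN hydrogel
#' plug in one radial chamber. The permeability and porosity defaults are
#' documented placeholders at the order of magnitude of dense hydrogels
#' (the characterization lives in prior rheometry/porosimetry work and is
#' configured per rig); a warning notes when they are used.
#'
#' @param permeability Darcy permeability k (m^2), > 0.
#' @param porosity fluid volume fraction in (0, 1); the effective Brinkman
#'   viscosity is `mu / porosity`.
#' @param plug_length m.
#' @param plug_cross_section_area m^2.
#' @param quiet suppress the default-parameter warning.
#' @export
hydrogel_spec <- function(permeability = 1e-14, porosity = 0.9,
                          plug_length = 0.01,
                          plug_cross_section_area = 2.83e-5,
                          quiet = FALSE) {
  stopifnot(permeability > 0, porosity > 0, porosity < 1,
            plug_length > 0, plug_cross_section_area > 0)
  if (!quiet && missing(permeability))
    warning("using placeholder hydrogel permeability 1e-14 m^2; ",
            "set the measured value for your gel", call. = FALSE)
  structure(list(permeability = permeability, porosity = porosity,
                 plug_length = plug_length,
                 plug_cross_section_area = plug_cross_section_area),
            class = "af_hydrogel_spec")
}

#' Bioreactor chamber specification
#'
#' @param n_chambers radial hydrogel chambers fed in parallel (default 8).
#' @param pump_rate total pump volumetric rate Q (m^3/s), >= 0.
#' @param cross_section `"square"` (2D cross-section solve) or `"slab"`
#'   (1D between parallel walls; has a closed-form Brinkman profile).
#' @export
chamber_spec <- function(n_chambers = 8L, pump_rate = 1e-8,
                         cross_section = c("square", "slab")) {
  cross_section <- match.arg(cross_section)
  stopifnot(n_chambers >= 1, pump_rate >= 0)
  structure(list(n_chambers = as.integer(n_chambers),
                 pump_rate = pump_rate, cross_section = cross_section),
            class = "af_chamber_spec")
}

#' Idealized-cell channel model
#'
#' An idealized cell attached to the floor of an open flow channel: a
#' circular-cap bump (2D cross-section mode) of radius `cell_radius`,
#' protruding `protrusion_frac * cell_radius` into the channel, in fully
#' developed inflow of mean speed `inlet_speed`. The default dimensions
#' are documented placeholders (warn on use); both are rig configuration.
#'
#' @param cell_radius m (default 7.5 um).
#' @param channel_height m; must exceed `2 * cell_radius`.
#' @param shape `"semicircular_bump"` (2D; default) or
#'   `"hemisphere_on_wall"` (reserved for 3D rigs).
#' @param inlet_speed mean inflow speed U (m/s), >= 0.
#' @param protrusion_frac protruding fraction of the radius in (0, 1); the
#'   cap meets the wall at a finite angle so the mesh stays shape-regular.
#' @param channel_length m; default 10 channel heights.
#' @param quiet suppress the default-dimension warning.
#' @export
cell_model <- function(cell_radius = 7.5e-6, channel_height = 100e-6,
                       shape = c("semicircular_bump", "hemisphere_on_wall"),
                       inlet_speed = 1e-4, protrusion_frac = 0.7,
                       channel_length = 10 * channel_height,
                       quiet = FALSE) {
  shape <- match.arg(shape)
  stopifnot(cell_radius > 0, channel_height > 2 * cell_radius,
            inlet_speed >= 0, protrusion_frac > 0, protrusion_frac < 1)
  if (!quiet && (missing(cell_radius) || missing(channel_height)))
    warning("using placeholder idealized-cell dimensions ",
            "(radius 7.5 um, channel height 100 um)", call. = FALSE)
  structure(list(cell_radius = cell_radius,
                 channel_height = channel_height, shape = shape,
                 inlet_speed = inlet_speed,
                 protrusion_frac = protrusion_frac,
                 channel_length = channel_length), class = "af_cell_model")
}

#' Brinkman flow through the hydrogel plug
#'
#' Solves unidirectional Brinkman flow `mu_eff lap(u) - (mu/k) u = -G`
#' over the plug cross-section with no-slip lateral walls, with the
#' uniform axial gradient `G` scaled so each chamber passes
#' `pump_rate / n_chambers`. When the Brinkman screening length
#' `sqrt(k mu_eff / mu)` is far below the mesh size, the uniform Darcy
#' (superficial) profile is returned directly.
#'
#' @param chamber [chamber_spec()].
#' @param gel [hydrogel_spec()].
#' @param props [fluid_properties()].
#' @param n resolution of the cross-section solve.
#' @return list with `U_gel` (volume-averaged superficial speed, m/s),
#'   `profile` (data.frame of the section), `G` (Pa/m), `darcy_path`.
#' @export
chamber_flow <- function(chamber, gel, props, n = 40L) {
  Qc <- chamber$pump_rate / chamber$n_chambers
  A <- gel$plug_cross_section_area
  if (Qc == 0) {
    return(list(U_gel = 0, G = 0,
                profile = data.frame(y_m = numeric(0), u_m_s = numeric(0)),
                darcy_path = TRUE))
  }
  mu <- props$dynamic_viscosity
  mu_eff <- mu / gel$porosity
  delta <- sqrt(gel$permeability * mu_eff / mu)
  W <- sqrt(A)
  if (delta < W / (50 * n)) {
    # screening skin unresolvable and dynamically negligible: Darcy limit
    u <- Qc / A
    return(list(U_gel = u, G = mu / gel$permeability * u,
                profile = data.frame(y_m = c(0, W), u_m_s = c(u, u)),
                darcy_path = TRUE))
  }
  if (chamber$cross_section == "slab") {
    y <- seq(0, W, length.out = n + 1L)
    h <- diff(y)
    nv <- n + 1L
    # P1 FEM on the interval: mu_eff u'' - (mu/k) u = -G
    iK <- c(seq_len(n), seq_len(n) + 1L, seq_len(n), seq_len(n) + 1L)
    jK <- c(seq_len(n), seq_len(n) + 1L, seq_len(n) + 1L, seq_len(n))
    xK <- c(mu_eff / h + mu / gel$permeability * h / 3,
            mu_eff / h + mu / gel$permeability * h / 3,
            -mu_eff / h + mu / gel$permeability * h / 6,
            -mu_eff / h + mu / gel$permeability * h / 6)
    K <- Matrix::sparseMatrix(i = iK, j = jK, x = xK, dims = c(nv, nv))
    b <- numeric(nv)
    b[seq_len(n)] <- b[seq_len(n)] + h / 2
    b[seq_len(n) + 1L] <- b[seq_len(n) + 1L] + h / 2
    u1 <- solve_constrained(K, b, c(1L, nv), c(0, 0))   # unit G
    flux1 <- sum((u1[-nv] + u1[-1]) / 2 * h) * W        # per unit depth x W
    G <- Qc / flux1
    u <- G * u1
    list(U_gel = Qc / A, G = G,
         profile = data.frame(y_m = y, u_m_s = u), darcy_path = FALSE)
  } else {
    mesh <- mesh_rectangle(n, n, width = W, height = W)
    sp <- fem_space(mesh, 1L)
    geom <- fem_geom(mesh, mesh$points)
    basis <- fem_basis_at_quad(geom, 1L, default_volume_rule(2L))
    K <- mu_eff * asm_stiffness(sp, geom, basis) +
      mu / gel$permeability * asm_mass(sp, geom, basis)
    b <- asm_load(sp, geom, basis, 1)
    bd <- boundary_dofs(sp)
    u1 <- solve_constrained(K, b, bd, rep(0, length(bd)))
    G <- Qc / sum(b * u1)               # b is the load of 1: sum(b u) = int u dA
    u <- G * u1
    mid <- abs(sp$points[, 1] - W / 2) < 1e-12
    list(U_gel = Qc / A, G = G,
         profile = data.frame(y_m = sp$points[mid, 2],
                              u_m_s = u[mid])[order(sp$points[mid, 2]), ],
         darcy_path = FALSE)
  }
}

# Build the idealized-cell channel mesh and return a solver closure giving
# the full Stokes (or Navier-Stokes at cell Reynolds > 0.1) solution and
# the FSS profile for any inlet speed.
cell_channel_solver <- function(cell, props, resolution_scale = 1) {
  h <- cell$channel_height
  L <- cell$channel_length
  a <- cell$cell_radius
  cfrac <- sqrt(1 - (1 - cell$protrusion_frac)^2)  # half-width / radius
  halfw <- cfrac * a
  csub <- (1 - cell$protrusion_frac) * a           # cap center depth
  bump <- function(x) {
    r2 <- (x - L / 2)^2
    out <- numeric(length(x))
    inside <- r2 < a^2
    out[inside] <- pmax(sqrt(a^2 - r2[inside]) - csub, 0)
    out
  }
  nx <- max(40L, as.integer(round(96 * resolution_scale)))
  ny <- max(12L, as.integer(round(26 * resolution_scale)))
  mesh <- mesh_rectangle(
    nx, ny, width = L, height = h,
    grade_x = grade_cluster(0.5, 8),
    grade_y = grade_wall(3),
    bottom_profile = bump,
    bottom_patch_fun = function(xm) if (bump(xm) > 0) "cell" else "floor")
  st <- solver_settings(include_convection = FALSE,
                        pressure_constraint = "none")
  props_ <- props
  solve_at <- function(U) {
    Re_cell <- props_$density * U * h / props_$dynamic_viscosity
    sti <- st
    sti$include_convection <- Re_cell > 0.1
    opctx <- flow_operator(mesh, mesh$points, props_, sti, dtc = NULL)
    vsp <- opctx$vsp
    bc <- merge_bc(
      bc_patch(vsp, c("floor", "cell", "top"),
               function(xx) matrix(0, nrow(xx), 2), 1:2),
      bc_patch(vsp, "left", function(xx)
        cbind(6 * U * xx[, 2] * (h - xx[, 2]) / h^2, 0), 1:2))
    sol <- flow_solve(opctx, bc)
    structure(list(u = sol$u, p = sol$p, time = 0, points = mesh$points,
                   opr = list(A = sol$A, F = sol$F, vsp = vsp,
                              psp = opctx$psp, nV = opctx$nV, d = 2L)),
              class = "af_flow_state")
  }
  profile <- function(U) {
    if (U == 0) {
      pd <- boundary_dofs(fem_space(mesh, 2L), "cell")
      return(structure(list(arclength_m = seq_along(pd) * 0,
                            fss_dyn_cm2 = numeric(length(pd)),
                            upstream_fss_dyn_cm2 = 0, U = 0,
                            cell = cell), class = "af_fss_profile"))
    }
    state <- solve_at(U)
    tr <- wall_traction(state, mesh, props_, patch = "cell")
    ws <- wall_shear(tr$traction, tr$normals)
    o <- order(tr$coords[, 1])
    xy <- tr$coords[o, , drop = FALSE]
    s <- c(0, cumsum(sqrt(rowSums(diff(xy)^2))))
    trf <- wall_traction(state, mesh, props_, patch = "floor")
    wsf <- wall_shear(trf$traction, trf$normals)
    up <- trf$coords[, 1] > 0.1 * L & trf$coords[, 1] < 0.3 * L
    structure(list(arclength_m = s, fss_dyn_cm2 = ws$mag_dyn_cm2[o],
                   upstream_fss_dyn_cm2 = mean(wsf$mag_dyn_cm2[up]),
                   U = U, cell = cell), class = "af_fss_profile")
  }
  list(mesh = mesh, solve_at = solve_at, profile = profile)
}

#' FSS along the idealized-cell surface
#'
#' Solves steady viscous flow (Stokes by default; the convective term is
#' enabled when the cell-scale Reynolds number exceeds 0.1) in the open
#' channel with the cell bump on the floor, no-slip everywhere and fully
#' developed inflow, and samples the wall shear stress magnitude along the
#' cell surface arclength from the upstream to the downstream base.
#'
#' @param cell [cell_model()] (its `inlet_speed` is used, typically set to
#'   the averaged hydrogel speed `U_gel`).
#' @param props [fluid_properties()].
#' @param resolution_scale mesh refinement multiplier.
#' @param solver optional prebuilt `cell_channel_solver` (reused across
#'   calls).
#' @return `af_fss_profile`: arclength (m), FSS (dynes/cm^2), the
#'   upstream flat-wall FSS, and the inlet speed.
#' @export
cell_fss_profile <- function(cell, props = fluid_properties(),
                             resolution_scale = 1, solver = NULL) {
  if (cell$channel_height <= 2 * cell$cell_radius)
    stop("cell too large for the channel")
  if (is.null(solver))
    solver <- cell_channel_solver(cell, props, resolution_scale)
  solver$profile(cell$inlet_speed)
}

#' Peak FSS of a cell profile
#'
#' @param profile an `af_fss_profile` (or numeric vector).
#' @return list with `peak` (dynes/cm^2) and `arclength_m` of the peak.
#' @export
peak_cell_fss <- function(profile) {
  if (is.numeric(profile)) {
    if (!length(profile)) stop("empty profile")
    return(list(peak = max(profile), arclength_m = NA_real_))
  }
  if (!length(profile$fss_dyn_cm2)) stop("empty profile")
  i <- which.max(profile$fss_dyn_cm2)
  list(peak = profile$fss_dyn_cm2[i], arclength_m = profile$arclength_m[i])
}

#' Inverse design of a bioreactor operating point
#'
#' Finds the inlet speed and pump rate whose forward model realizes a
#' target peak cell-surface FSS. In the Stokes regime one forward solve
#' fixes the FSS-per-unit-speed slope and the target is hit by linearity;
#' the returned achieved value is recomputed by a fresh forward solve at
#' the designed speed. With convective effects enabled the design falls
#' back to bracketed root-finding.
#'
#' @param target_fss dynes/cm^2, > 0.
#' @param cell [cell_model()].
#' @param chamber [chamber_spec()].
#' @param gel [hydrogel_spec()].
#' @param props [fluid_properties()].
#' @param resolution_scale mesh refinement multiplier.
#' @param solver optional prebuilt solver (reused across targets).
#' @return `af_operating_point`: `target_fss`, `inlet_speed` (m/s),
#'   `pump_rate` (m^3/s), `achieved_fss`, `residual`.
#' @export
inverse_design <- function(target_fss, cell, chamber, gel,
                           props = fluid_properties(),
                           resolution_scale = 1, solver = NULL) {
  if (target_fss <= 0) stop("target_fss must be positive")
  if (is.null(solver))
    solver <- cell_channel_solver(cell, props, resolution_scale)
  U0 <- if (cell$inlet_speed > 0) cell$inlet_speed else 1e-4
  pk0 <- peak_cell_fss(solver$profile(U0))$peak
  Re0 <- props$density * U0 * cell$channel_height / props$dynamic_viscosity
  if (Re0 <= 0.1) {
    U <- target_fss / (pk0 / U0)
  } else {
    g <- function(U) peak_cell_fss(solver$profile(U))$peak - target_fss
    lo <- U0 * target_fss / pk0 / 4; hi <- U0 * target_fss / pk0 * 4
    U <- stats::uniroot(g, c(lo, hi), tol = 1e-3 * U0)$root
  }
  achieved <- peak_cell_fss(solver$profile(U))$peak
  residual <- abs(achieved - target_fss) / target_fss
  if (residual > 0.01)
    warning(sprintf("operating point residual %.3g exceeds 1%%", residual))
  # pump rate realizing U_gel = U through the chamber/plug model
  ref <- chamber_flow(chamber_spec(chamber$n_chambers, pump_rate = 1e-9,
                                   cross_section = chamber$cross_section),
                      gel, props)
  Q <- U / ref$U_gel * 1e-9
  structure(list(target_fss = target_fss, inlet_speed = U, pump_rate = Q,
                 achieved_fss = achieved, residual = residual),
            class = "af_operating_point")
}

#' @export
print.af_operating_point <- function(x, ...) {
  cat(sprintf(
    "<operating point> target %.3g dyn/cm2: U = %.4g m/s, Q = %.4g m^3/s, achieved %.4g (residual %.2e)\n",
    x$target_fss, x$inlet_speed, x$pump_rate, x$achieved_fss, x$residual))
  invisible(x)
}
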
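#' Breathing presets
#'
#' Diaphragm forcing parameters. The `regular` preset uses a maximum
#' excursion of 6.0 cm at 0.37 Hz; the `active` (energetic breathing)
#' preset uses 8.0 cm at 1.0 Hz. Runs default to three forcing cycles.
#'
#' @param name `"regular"` or `"active"`.
#' @return an `af_breathing_preset`: amplitude (m), frequency (Hz),
#'   `n_cycles`, waveform.
#' @export
preset <- function(name) {
  tbl <- list(regular = c(A = 0.060, f = 0.37),
              active  = c(A = 0.080, f = 1.00))
  if (!name %in% names(tbl))
    stop("unknown preset '", name, "'; valid presets: ",
         paste(names(tbl), collapse = ", "))
  v <- tbl[[name]]
  breathing_preset(amplitude = v[["A"]], frequency = v[["f"]])
}

#' @param amplitude maximum diaphragm excursion (m), > 0.
#' @param frequency breathing frequency (Hz), > 0.
#' @param n_cycles number of forcing cycles (default 3).
#' @param waveform `"raised_cosine"` (smooth start, s(0) = 0) or `"sine"`.
#' @param direction -1 for caudal (downward, compressing) excursion.
#' @rdname preset
#' @export
breathing_preset <- function(amplitude, frequency, n_cycles = 3L,
                             waveform = c("raised_cosine", "sine"),
                             direction = -1) {
  waveform <- match.arg(waveform)
  stopifnot(amplitude > 0, frequency > 0, n_cycles >= 1,
            direction %in% c(-1, 1))
  structure(list(amplitude = amplitude, frequency = frequency,
                 n_cycles = as.integer(n_cycles), waveform = waveform,
                 direction = direction), class = "af_breathing_preset")
}

# dimensionless waveform s(t) in [0, 1] (raised cosine) or [-1, 1] (sine)
waveform_value <- function(preset, t) {
  ph <- 2 * pi * preset$frequency * t
  switch(preset$waveform,
         raised_cosine = (1 - cos(ph)) / 2,
         sine = sin(ph))
}

#' Vertical decay profile of the prescribed deformation
#'
#' Deformation decreases linearly from the top of the ascites (full
#' amplitude at `z = z_top`) to the ovary reference height (`z = z_ov`,
#' no deformation); the region at and below the ovaries stays stationary.
#'
#' @param z heights to evaluate (m).
#' @param z_ov ovary reference height (m).
#' @param z_top top of the ascites (m), must exceed `z_ov`.
#' @return weights in `[0, 1]`.
#' @export
vertical_profile <- function(z, z_ov, z_top) {
  if (z_top <= z_ov) stop("z_top must exceed z_ov")
  pmin(pmax((z - z_ov) / (z_top - z_ov), 0), 1)
}

# boundary-only displacement field container
displacement_field <- function(nodes, values, time) {
  structure(list(nodes = as.integer(nodes), values = values, time = time),
            class = "af_displacement")
}

#' Prescribed vertical boundary displacement
#'
#' The diaphragm-driven deformation at time `t`: vertical displacement
#' `direction * A * phi(z) * s(t)` on every boundary node, with `phi` the
#' linear decay [vertical_profile()] and `s` the preset waveform. Lateral
#' volume compensation is added separately by [volume_compensation()].
#'
#' @param mesh an [af_mesh] (last coordinate is the vertical axis).
#' @param preset an `af_breathing_preset`.
#' @param z_ov ovary reference height (m).
#' @param t time (s), >= 0.
#' @return boundary `af_displacement` (nodes, values `n_bnd x d`, time).
#' @export
boundary_displacement <- function(mesh, preset, z_ov, t) {
  stopifnot(t >= 0)
  bn <- boundary_nodes(mesh)
  d <- mesh$dim
  z <- mesh$points[bn, d]
  z_top <- max(mesh$points[, d])
  phi <- vertical_profile(z, z_ov, z_top)
  vals <- matrix(0, length(bn), d)
  vals[, d] <- preset$direction * preset$amplitude * phi *
    waveform_value(preset, t)
  displacement_field(bn, vals, t)
}

# Horizontal outward unit directions on lateral-patch boundary nodes,
# weighted by the vertical decay profile (precomputable).
lateral_compensation_basis <- function(mesh, z_ov) {
  d <- mesh$dim
  nrm <- node_normals_patch(mesh, "lateral")
  nrm[, d] <- 0                               # horizontal only
  len <- sqrt(rowSums(nrm^2))
  keep <- len > 1e-12
  nrm[keep, ] <- nrm[keep, , drop = FALSE] / len[keep]
  nrm[!keep, ] <- 0
  z_top <- max(mesh$points[, d])
  phi <- vertical_profile(mesh$points[, d], z_ov, z_top)
  nrm * phi                                    # nn x d, zero off-lateral
}

# area-weighted outward normal accumulated over one patch only (per node)
node_normals_patch <- function(mesh, patch) {
  fn <- facet_normals(mesh)
  sel <- mesh$facet_patch == patch
  nn <- nrow(mesh$points)
  acc <- matrix(0, nn, mesh$dim)
  f <- mesh$facets[sel, , drop = FALSE]
  for (j in seq_len(ncol(f))) for (k in seq_len(mesh$dim)) {
    acc[, k] <- acc[, k] +
      tabulate_add(f[, j], fn$normal[sel, k] * fn$area[sel] / ncol(f), nn)
  }
  acc
}

#' Isovolumetric lateral compensation
#'
#' Solves for the uniform normal-displacement magnitude on the lateral
#' patch (weighted by the same vertical decay profile as the forcing) that
#' restores the enclosed cavity volume to its undeformed value: a
#' first-order volume-bookkeeping estimate refined by 1D root-finding on
#' the exactly computed enclosed volume of the displaced boundary.
#'
#' @param mesh an [af_mesh] with a `lateral` patch.
#' @param vertical_field boundary `af_displacement` from
#'   [boundary_displacement()].
#' @param t time (s), recorded in the result.
#' @param basis optional precomputed [lateral_compensation_basis()].
#' @param V0 optional undeformed volume (recomputed if missing).
#' @param rel_tol relative volume tolerance of the root solve.
#' @return boundary `af_displacement` holding only the lateral
#'   compensation, with the solved magnitude as attribute `magnitude`.
#' @export
volume_compensation <- function(mesh, vertical_field, t = vertical_field$time,
                                basis = NULL, V0 = NULL, rel_tol = 1e-10) {
  if (!"lateral" %in% mesh$facet_patch) stop("mesh has no lateral patch")
  if (is.null(basis)) basis <- lateral_compensation_basis(mesh, attr(vertical_field, "z_ov") %||% guess_z_ov(mesh))
  if (is.null(V0)) V0 <- enclosed_volume(mesh)
  bn <- vertical_field$nodes
  disp_pts <- mesh$points
  disp_pts[bn, ] <- disp_pts[bn, , drop = FALSE] + vertical_field$values
  vol_at <- function(m) {
    p <- disp_pts + m * basis
    enclosed_volume(mesh, p)
  }
  defect <- vol_at(0) - V0
  if (abs(defect) <= rel_tol * V0) {
    comp <- displacement_field(bn, 0 * vertical_field$values, t)
    attr(comp, "magnitude") <- 0
    return(comp)
  }
  # first-order estimate: dV/dm = effective weighted lateral area
  eps <- 1e-6 * max(abs(defect) / V0, 1) * mesh_scale(mesh)
  dVdm <- (vol_at(eps) - vol_at(-eps)) / (2 * eps)
  m0 <- -defect / dVdm
  lo <- m0 - 2 * abs(m0) - eps; hi <- m0 + 2 * abs(m0) + eps
  g <- function(m) vol_at(m) - V0
  for (k in 1:8) {
    if (g(lo) * g(hi) <= 0) break
    lo <- lo - 2 * abs(m0); hi <- hi + 2 * abs(m0)
  }
  if (g(lo) * g(hi) > 0)
    stop(sprintf("lateral compensation failed to bracket: residual volume defect %.3g m^3", defect))
  m <- stats::uniroot(g, c(lo, hi), tol = rel_tol * mesh_scale(mesh))$root
  comp <- displacement_field(bn, m * basis[bn, , drop = FALSE], t)
  attr(comp, "magnitude") <- m
  comp
}

`%||%` <- function(a, b) if (is.null(a)) b else a

guess_z_ov <- function(mesh) {
  ov <- mesh$facet_patch %in% c("ovary_left", "ovary_right")
  if (!any(ov)) stop("cannot infer z_ov: no ovary patches")
  max(mesh$points[unique(as.vector(mesh$facets[ov, , drop = FALSE])),
                  mesh$dim])
}

mesh_scale <- function(mesh) max(apply(mesh$points, 2, function(x) diff(range(x))))

#' Combined isovolumetric cavity boundary motion
#'
#' Vertical diaphragm forcing plus solved lateral compensation, as a full
#' boundary displacement field.
#'
#' @inheritParams boundary_displacement
#' @param basis,V0 optional precomputed quantities (see
#'   [volume_compensation()]).
#' @return boundary `af_displacement`; attribute `magnitude` carries the
#'   lateral compensation magnitude.
#' @export
cavity_boundary_motion <- function(mesh, preset, z_ov, t, basis = NULL,
                                   V0 = NULL) {
  if (is.null(basis)) basis <- lateral_compensation_basis(mesh, z_ov)
  vert <- boundary_displacement(mesh, preset, z_ov, t)
  attr(vert, "z_ov") <- z_ov
  comp <- volume_compensation(mesh, vert, t, basis = basis, V0 = V0)
  out <- displacement_field(vert$nodes, vert$values + comp$values, t)
  attr(out, "magnitude") <- attr(comp, "magnitude")
  out
}

#' Mesh velocity by backward differencing
#'
#' Finite-difference nodal velocity from a displacement history, consistent
#' with the flow time-integrator order.
#'
#' @param disp_history list of displacement matrices (most recent last).
#' @param dt time step (s).
#' @param scheme `"backward_difference_1"` (needs 2 levels) or
#'   `"backward_difference_2"` (needs 3).
#' @return nodal velocity matrix (m/s).
#' @export
mesh_velocity <- function(disp_history, dt,
                          scheme = c("backward_difference_1",
                                     "backward_difference_2")) {
  scheme <- match.arg(scheme)
  n <- length(disp_history)
  need <- if (scheme == "backward_difference_1") 2L else 3L
  if (n < need)
    stop("insufficient displacement history for ", scheme,
         ": need ", need, " levels, have ", n)
  if (scheme == "backward_difference_1") {
    (disp_history[[n]] - disp_history[[n - 1L]]) / dt
  } else {
    (1.5 * disp_history[[n]] - 2 * disp_history[[n - 1L]] +
       0.5 * disp_history[[n - 2L]]) / dt
  }
}

#' Mesh-motion settings
#'
#' Pseudo-solid linear elasticity parameters for propagating the boundary
#' displacement through the volume. Only ratios matter for the resulting
#' displacement; the inverse-volume Jacobian stiffening protects small
#' cells from inversion.
#'
#' @param elastic_modulus nominal modulus (arbitrary units).
#' @param poisson_ratio in `[0, 0.5)`.
#' @param stiffening_exponent `>= 0`; element stiffness is scaled by
#'   `(mean cell volume / cell volume)^exponent`.
#' @param linear_solver_tolerance residual tolerance check.
#' @export
mesh_motion_settings <- function(elastic_modulus = 1, poisson_ratio = 0.3,
                                 stiffening_exponent = 1,
                                 linear_solver_tolerance = 1e-9) {
  stopifnot(poisson_ratio >= 0, poisson_ratio < 0.5,
            stiffening_exponent >= 0, linear_solver_tolerance > 0)
  structure(list(elastic_modulus = elastic_modulus,
                 poisson_ratio = poisson_ratio,
                 stiffening_exponent = stiffening_exponent,
                 linear_solver_tolerance = linear_solver_tolerance),
            class = "af_mesh_motion_settings")
}

# Factorized pseudo-solid operator on the reference mesh. Returns a closure
# mapping a boundary displacement field to the volumetric displacement.
mesh_motion_operator <- function(mesh, settings = mesh_motion_settings()) {
  d <- mesh$dim
  nn <- nrow(mesh$points)
  geom <- fem_geom(mesh, mesh$points)
  E <- settings$elastic_modulus; nu <- settings$poisson_ratio
  lam <- E * nu / ((1 + nu) * (1 - 2 * nu))
  muL <- E / (2 * (1 + nu))
  stiff <- (mean(geom$vol) / geom$vol)^settings$stiffening_exponent
  gl <- geom$gradlam
  cl <- mesh$cells
  np1 <- d + 1L
  ii <- jj <- xx <- list()
  k <- 1L
  for (a in seq_len(d)) for (b in seq_len(d)) {
    for (i in seq_len(np1)) for (j in seq_len(np1)) {
      gij <- 0
      for (kk in seq_len(d)) gij <- gij + gl[, i, kk] * gl[, j, kk]
      val <- muL * ((a == b) * gij + gl[, j, a] * gl[, i, b]) +
        lam * gl[, j, b] * gl[, i, a]
      ii[[k]] <- (a - 1L) * nn + cl[, i]
      jj[[k]] <- (b - 1L) * nn + cl[, j]
      xx[[k]] <- geom$vol * stiff * val
      k <- k + 1L
    }
  }
  K <- Matrix::sparseMatrix(i = unlist(ii), j = unlist(jj), x = unlist(xx),
                            dims = c(d * nn, d * nn))
  bn <- boundary_nodes(mesh)
  bdofs <- as.vector(outer(bn, (seq_len(d) - 1L) * nn, `+`))
  free <- setdiff(seq_len(d * nn), bdofs)
  Kff <- K[free, free, drop = FALSE]
  fac <- Matrix::Cholesky(Matrix::forceSymmetric(Kff), LDL = FALSE)
  list(K = K, free = free, bdofs = bdofs, bn = bn, nn = nn, d = d,
       fac = fac, mesh = mesh, settings = settings)
}

#' Propagate a boundary displacement into the volume
#'
#' Solves homogeneous isotropic linear elasticity with the boundary field
#' as Dirichlet data on the whole boundary; errors if the displaced mesh
#' has inverted elements.
#'
#' @param mesh an [af_mesh].
#' @param boundary_disp boundary `af_displacement` covering all boundary
#'   nodes.
#' @param settings an [mesh_motion_settings()].
#' @param op optional precomputed operator from `mesh_motion_operator`
#'   (reused across time steps).
#' @return full nodal displacement matrix `n_nodes x d` (m).
#' @export
solve_mesh_motion <- function(mesh, boundary_disp,
                              settings = mesh_motion_settings(), op = NULL) {
  if (is.null(op)) op <- mesh_motion_operator(mesh, settings)
  d <- op$d; nn <- op$nn
  bn_all <- boundary_nodes(mesh)
  if (!all(bn_all %in% boundary_disp$nodes))
    stop("boundary displacement must cover every boundary node")
  x <- numeric(d * nn)
  for (a in seq_len(d))
    x[(a - 1L) * nn + boundary_disp$nodes] <- boundary_disp$values[, a]
  rhs <- -as.vector(op$K[op$free, op$bdofs, drop = FALSE] %*% x[op$bdofs])
  x[op$free] <- as.vector(Matrix::solve(op$fac, rhs))
  res <- max(abs(op$K[op$free, , drop = FALSE] %*% x - 0))
  disp <- matrix(x, nn, d)
  newpts <- mesh$points + disp
  v <- cell_volumes(newpts, mesh$cells)
  if (any(v <= 0))
    stop("mesh motion inverted ", sum(v <= 0), " elements; increase the ",
         "stiffening_exponent or reduce the forcing amplitude")
  if (res > settings$linear_solver_tolerance * max(1, max(abs(x))))
    warning("mesh-motion residual above tolerance: ", format(res))
  disp
}
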
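# Wall traction and wall shear stress extraction, and the per-patch /
# per-cycle metrics reported for the ovary patches (FSS in dynes/cm^2,
# 1 Pa = 10 dynes/cm^2).

PA_TO_DYN <- 10

#' Wall traction by the consistent-flux method
#'
#' Recovers the boundary traction t = sigma.n (sigma = -pI + mu(grad u +
#' grad u^T)) variationally: the discrete momentum residual tested with
#' boundary basis functions equals the boundary virtual work, so nodal
#' tractions solve a boundary mass system. This is markedly more accurate
#' on simplex meshes than differentiating the velocity at the wall.
#'
#' @param state `af_flow_state` (from [advance_flow()]; states built by
#'   hand are treated as steady Stokes states with no body force).
#' @param mesh the reference [af_mesh].
#' @param props [fluid_properties()].
#' @param patch optional patch name to restrict the result.
#' @param settings solver settings (only used when `state` lacks an
#'   assembled operator).
#' @param body_force body force assumed for hand-built states.
#' @return list with `dofs` (boundary velocity dofs), `coords`, `traction`
#'   (n x d, Pa), `normals` (outward unit), `patch` labels per dof.
#' @export
wall_traction <- function(state, mesh, props, patch = NULL,
                          settings = solver_settings(), body_force = NULL) {
  if (!is.null(state$opr)) {
    A <- state$opr$A; F <- state$opr$F
    vsp <- state$opr$vsp; d <- state$opr$d; nV <- state$opr$nV
    x <- c(as.vector(state$u), state$p,
           numeric(nrow(A) - length(state$u) - length(state$p)))
  } else {
    st <- settings; st$include_convection <- FALSE
    st$pressure_constraint <- "none"
    opctx <- flow_operator(mesh, state$points, props, st, dtc = NULL)
    vsp <- opctx$vsp; d <- opctx$d; nV <- opctx$nV
    A <- opctx$A0
    F <- flow_rhs(opctx, body_force = body_force)
    x <- c(as.vector(state$u), state$p)
  }
  if (!is.null(patch) && !patch %in% mesh$facet_patch)
    stop("patch '", patch, "' not present; patches: ",
         paste(unique(mesh$facet_patch), collapse = ", "))
  r <- as.vector(A %*% x - F)
  bd <- boundary_dofs(vsp)
  Mb <- asm_boundary_mass(vsp)
  Mbb <- Mb[bd, bd, drop = FALSE]
  traction <- matrix(0, length(bd), d)
  for (a in seq_len(d)) {
    traction[, a] <- sparse_solve(Mbb, r[(a - 1L) * nV + bd])
  }
  normals <- dof_normals_weak(vsp, Mbb = Mbb, bd = bd)[bd, , drop = FALSE]
  lab <- dof_patch_labels(vsp)[bd]
  out <- list(dofs = bd, coords = vsp$dof_coords[bd, , drop = FALSE],
              traction = traction, normals = normals, patch = lab,
              time = state$time)
  if (!is.null(patch)) {
    pd <- boundary_dofs(vsp, patch)
    keep <- bd %in% pd
    out <- lapply(out[names(out) != "time"],
                  function(z) if (is.matrix(z)) z[keep, , drop = FALSE]
                              else z[keep])
    out$time <- state$time
  }
  out
}

# one label per boundary dof (fixed patch priority: ovaries win at patch
# junctions so ovary metrics see their rim nodes)
dof_patch_labels <- function(vsp) {
  mesh <- vsp$mesh
  fd <- facet_dofs(vsp)
  lab <- character(vsp$ndof)
  patches <- unique(mesh$facet_patch)
  pri <- c(setdiff(patches, c("ovary_left", "ovary_right")),
           intersect(c("ovary_left", "ovary_right"), patches))
  for (p in pri) {
    sel <- mesh$facet_patch == p
    lab[unique(as.vector(fd[sel, , drop = FALSE]))] <- p
  }
  lab
}

#' Tangential projection of wall traction
#'
#' The wall shear stress is the tangential part of the traction,
#' `tau_w = t - (t.n) n`; by construction `tau_w . n = 0` and the
#' magnitude is reported both in Pa and dynes/cm^2 (x 10).
#'
#' @param traction matrix `n x d` of traction vectors (Pa).
#' @param normals matrix of outward unit normals, aligned row-by-row.
#' @return list of class `af_wss`: `tau` (vectors, Pa), `mag_pa`,
#'   `mag_dyn_cm2`.
#' @export
wall_shear <- function(traction, normals) {
  traction <- as.matrix(traction); normals <- as.matrix(normals)
  stopifnot(all(dim(traction) == dim(normals)))
  nlen <- sqrt(rowSums(normals^2))
  if (any(abs(nlen - 1) > 1e-8))
    stop("normals must be unit vectors")
  tn <- rowSums(traction * normals)
  tau <- traction - tn * normals
  mag <- sqrt(rowSums(tau^2))
  structure(list(tau = tau, mag_pa = mag, mag_dyn_cm2 = PA_TO_DYN * mag),
            class = "af_wss")
}

# WSS fields on every boundary dof for one state (used per snapshot by
# run_cycles).
wss_fields <- function(state, mesh, props) {
  tr <- wall_traction(state, mesh, props)
  ws <- wall_shear(tr$traction, tr$normals)
  list(time = tr$time, dofs = tr$dofs, patch = tr$patch,
       tau = ws$tau, mag_pa = ws$mag_pa, mag_dyn_cm2 = ws$mag_dyn_cm2,
       normals = tr$normals, coords = tr$coords)
}

# snapshot indices of the final full cycle of a history
final_cycle_indices <- function(history) {
  spc <- history$steps_per_cycle %/% history$stride
  ns <- length(history$snapshots)
  ncyc <- ns %/% spc
  if (ncyc < 1) stop("history does not cover a full cycle")
  (ncyc - 1L) * spc + seq_len(spc)
}

#' Per-patch wall shear stress metrics over the final cycle
#'
#' `mean_fss`: area-weighted spatial mean of |tau_w|, then averaged over
#' the snapshots of the final forcing cycle. `peak_fss`: maximum over
#' patch nodes and snapshots of the final cycle. Also returns the time
#' series of the spatial maximum (the quantity plotted per breathing
#' cycle). All FSS values in dynes/cm^2.
#'
#' @param history `af_flow_history` from [run_cycles()], or a list of WSS
#'   fields (then `times` spanning one cycle is assumed).
#' @param mesh the cavity mesh.
#' @param patch patch name (e.g. `"ovary_left"`).
#' @return list of class `af_patch_metrics`.
#' @export
patch_metrics <- function(history, mesh, patch) {
  if (inherits(history, "af_flow_history")) {
    idx <- final_cycle_indices(history)
    wss <- history$wss[idx]
    times <- history$times[idx]
    vorder <- velocity_order(history$settings)
  } else {
    wss <- history; times <- vapply(wss, `[[`, numeric(1), "time")
    vorder <- 2L
  }
  if (!patch %in% mesh$facet_patch) stop("empty patch: ", patch)
  vsp <- fem_space(mesh, vorder)
  pd <- boundary_dofs(vsp, patch)
  if (!length(pd)) stop("empty patch: ", patch)
  # lumped boundary mass over the patch facets = nodal area weights
  Mb <- asm_boundary_mass(vsp, facet_sel = mesh$facet_patch == patch)
  wts <- as.vector(Mb %*% rep(1, vsp$ndof))[pd]
  means <- peaks <- numeric(length(wss))
  for (s in seq_along(wss)) {
    f <- wss[[s]]
    loc <- match(pd, f$dofs)
    mag <- f$mag_dyn_cm2[loc]
    means[s] <- sum(wts * mag) / sum(wts)
    peaks[s] <- max(mag)
  }
  structure(list(patch = patch, mean_fss = mean(means),
                 peak_fss = max(peaks),
                 time_series = data.frame(time_s = times,
                                          spatial_mean_dyncm2 = means,
                                          spatial_max_dyncm2 = peaks)),
            class = "af_patch_metrics")
}

#' Domain velocity metrics over the final cycle
#'
#' `mean_speed`: volume-weighted average of |u| over the domain, averaged
#' over the final-cycle snapshots; `peak_speed`: maximum nodal |u| over
#' the final cycle. Reported in cm/s.
#'
#' @param history `af_flow_history`.
#' @param mesh the cavity mesh.
#' @return list `(mean_speed, peak_speed)` in cm/s.
#' @export
velocity_metrics <- function(history, mesh) {
  idx <- final_cycle_indices(history)
  vorder <- velocity_order(history$settings)
  rule <- default_volume_rule(mesh$dim)
  means <- peaks <- numeric(length(idx))
  for (k in seq_along(idx)) {
    st <- history$snapshots[[idx[k]]]
    vsp <- fem_space(mesh, vorder, st$points)
    geom <- fem_geom(mesh, st$points)
    bV <- fem_basis_at_quad(geom, vorder, rule)
    uq <- field_at_quad(vsp, bV, st$u)
    tot <- 0
    for (q in seq_len(bV$nq))
      tot <- tot + sum(bV$w[q] * geom$vol * sqrt(rowSums(uq[[q]]^2)))
    means[k] <- tot / sum(geom$vol)
    peaks[k] <- max(sqrt(rowSums(st$u^2)))
  }
  list(mean_speed = 100 * mean(means), peak_speed = 100 * max(peaks))
}

#' Cycle summary
#'
#' Deterministic aggregation of the final-cycle metrics: domain mean/peak
#' speed (cm/s) and per-ovary mean/peak FSS (dynes/cm^2), plus the preset
#' and a digest of the run configuration.
#'
#' @param history `af_flow_history`.
#' @param mesh the cavity mesh.
#' @return list of class `af_cycle_summary` (JSON-serializable via
#'   [summary_to_json()]).
#' @export
summarize <- function(history, mesh) {
  vm <- velocity_metrics(history, mesh)
  patches <- intersect(c("ovary_left", "ovary_right"),
                       unique(mesh$facet_patch))
  pm <- lapply(patches, function(p) patch_metrics(history, mesh, p))
  names(pm) <- patches
  cfg <- list(preset = unclass(history$preset),
              settings = unclass(history$settings),
              props = unclass(history$props), z_ov = history$z_ov)
  structure(list(
    preset = history$preset,
    mean_speed_cm_s = vm$mean_speed, peak_speed_cm_s = vm$peak_speed,
    patch_metrics = pm,
    max_volume_drift = max(history$volume_drift),
    periodicity_residual = if (history$n_cycles >= 2)
      periodicity_residual(history) else NA_real_,
    config_digest = config_digest(cfg)), class = "af_cycle_summary")
}

#' @export
print.af_cycle_summary <- function(x, ...) {
  cat(sprintf("<cycle summary> A = %.3f m, f = %.2f Hz\n",
              x$preset$amplitude, x$preset$frequency))
  cat(sprintf("  speed (cm/s): mean %.3f, peak %.3f\n",
              x$mean_speed_cm_s, x$peak_speed_cm_s))
  for (p in names(x$patch_metrics))
    cat(sprintf("  %-12s FSS (dyn/cm2): mean %.3f, peak %.3f\n", p,
                x$patch_metrics[[p]]$mean_fss,
                x$patch_metrics[[p]]$peak_fss))
  cat(sprintf("  volume drift %.2e, periodicity residual %.3g\n",
              x$max_volume_drift, x$periodicity_residual))
  invisible(x)
}

#' Serialize / restore a cycle summary
#'
#' @param summary an `af_cycle_summary`.
#' @param path file to write.
#' @export
summary_to_json <- function(summary, path) {
  x <- list(
    preset = unclass(summary$preset),
    mean_speed_cm_s = summary$mean_speed_cm_s,
    peak_speed_cm_s = summary$peak_speed_cm_s,
    patch_metrics = lapply(summary$patch_metrics, function(p)
      list(patch = p$patch, mean_fss = p$mean_fss, peak_fss = p$peak_fss,
           time_series = p$time_series)),
    max_volume_drift = summary$max_volume_drift,
    periodicity_residual = summary$periodicity_residual,
    config_digest = summary$config_digest)
  jsonlite::write_json(x, path, auto_unbox = TRUE, digits = NA,
                       dataframe = "columns")
  invisible(path)
}
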
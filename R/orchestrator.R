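#' Run a configured pipeline
#'
#' Executes one of the three pipeline modes from a validated
#' configuration and writes its artifacts under the output directory:
#'
#' * `cavity` — breathing-driven cavity simulation: `summary.json`
#'   (cycle summary), `patch_series.csv`, `mesh.msh`, a VTU snapshot time
#'   series with a `.pvd` collection, and `run_log.txt` with
#'   nondimensional diagnostics (Reynolds, Womersley, CFL) per cycle.
#' * `bioreactor` — operating points for the configured target FSS
#'   levels: `operating_points.json` and `cell_profile.csv`.
#' * `verify` — the analytic verification suite: `verification.json`.
#'
#' Outputs are deterministic for a fixed configuration and embed the
#' configuration digest.
#'
#' @param config an `af_run_config` from [run_config()], or a path/list
#'   accepted by it.
#' @param out_dir output directory (created if missing).
#' @return list of produced artifact paths and in-memory results.
#' @export
run <- function(config, out_dir = "asciflow_out") {
  if (!inherits(config, "af_run_config")) config <- run_config(config)
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  switch(config$mode,
         cavity = run_cavity_mode(config, out_dir),
         bioreactor = run_bioreactor_mode(config, out_dir),
         verify = run_verify_mode(config, out_dir))
}

run_cavity_mode <- function(config, out_dir) {
  mesh <- build_cavity_mesh(config$geometry)
  settings <- config$solver
  props <- config$fluid
  pre <- config$preset
  log_path <- file.path(out_dir, "run_log.txt")
  logf <- function(...) cat(sprintf(...), "\n", sep = "",
                            file = log_path, append = TRUE)
  cat(sprintf("asciflow cavity run, config %s\n", config$digest),
      file = log_path)
  hist <- run_cycles(mesh, pre, config$geometry, props, settings)
  smry <- summarize(hist, mesh)
  # nondimensional diagnostics per cycle
  nu <- props$dynamic_viscosity / props$density
  Lref <- config$geometry$cavity_height
  spc <- hist$steps_per_cycle %/% hist$stride
  for (cyc in seq_len(hist$n_cycles)) {
    idx <- (cyc - 1L) * spc + seq_len(spc)
    idx <- idx[idx <= length(hist$snapshots)]
    umax <- max(vapply(hist$snapshots[idx],
                       function(s) max(sqrt(rowSums(s$u^2))), numeric(1)))
    h <- config$geometry$mesh_size
    logf("cycle %d: Re = %.3g, Womersley = %.3g, CFL = %.3g, max|u| = %.3g m/s",
         cyc, umax * Lref / nu,
         (Lref / 2) * sqrt(2 * pi * pre$frequency / nu),
         umax * hist$settings$dt / h, umax)
  }
  summary_to_json(smry, file.path(out_dir, "summary.json"))
  write_patch_series(hist, mesh, file.path(out_dir, "patch_series.csv"))
  write_msh(mesh, file.path(out_dir, "mesh.msh"))
  stridev <- config$outputs$vtu_stride %||% 4L
  keep <- seq(1L, length(hist$snapshots), by = stridev)
  files <- character(0)
  for (k in keep) {
    s <- hist$snapshots[[k]]
    f <- sprintf("snapshot_%04d.vtu", k)
    vsp_nn <- nrow(mesh$points)
    write_vtu(mesh, file.path(out_dir, f),
              point_data = list(
                velocity = s$u[seq_len(vsp_nn), , drop = FALSE],
                pressure = s$p,
                mesh_displacement = s$points - mesh$points),
              points = s$points)
    files <- c(files, f)
  }
  write_pvd(files, hist$times[keep], file.path(out_dir, "snapshots.pvd"))
  logf("summary digest %s", smry$config_digest)
  list(history = hist, summary = smry, out_dir = out_dir)
}

run_bioreactor_mode <- function(config, out_dir) {
  rig <- config$bioreactor
  cell <- do.call(cell_model, c(rig$cell %||% list(), list(quiet = TRUE)))
  gel <- do.call(hydrogel_spec, c(rig$hydrogel %||% list(),
                                  list(quiet = TRUE)))
  chamber <- do.call(chamber_spec, rig$chamber %||% list())
  targets <- rig$target_fss %||% c(1, 5, 11)
  props <- config$fluid
  solver <- cell_channel_solver(cell, props,
                                rig$resolution_scale %||% 1)
  ops <- lapply(targets, inverse_design, cell = cell, chamber = chamber,
                gel = gel, props = props, solver = solver)
  names(ops) <- paste0("fss_", targets)
  jsonlite::write_json(
    c(lapply(ops, unclass), list(config_digest = config$digest)),
    file.path(out_dir, "operating_points.json"),
    auto_unbox = TRUE, digits = NA)
  prof <- solver$profile(ops[[length(ops)]]$inlet_speed)
  utils::write.csv(
    data.frame(arclength_m = prof$arclength_m,
               fss_dyncm2 = prof$fss_dyn_cm2),
    file.path(out_dir, "cell_profile.csv"), row.names = FALSE)
  list(operating_points = ops, profile = prof, out_dir = out_dir)
}

run_verify_mode <- function(config, out_dir) {
  cases <- c("poiseuille_wss", "womersley_wss", "stokes_sphere_wss",
             "isovolumetry", "gcl_uniform_translation",
             "bioreactor_linearity")
  reps <- lapply(cases, verify)
  names(reps) <- cases
  jsonlite::write_json(
    c(lapply(reps, function(r) unclass(r)[c("case", "computed", "oracle",
                                            "rel_errors", "tolerance",
                                            "pass")]),
      list(config_digest = config$digest)),
    file.path(out_dir, "verification.json"), auto_unbox = TRUE, digits = NA)
  list(reports = reps, out_dir = out_dir)
}

#' Human-readable report with figures
#'
#' Renders a cycle summary (per-ovary maximum-FSS time series over the
#' final breathing cycle plus a metrics table) or an operating point /
#' FSS profile (FSS against cell-surface arclength).
#'
#' @param x an `af_cycle_summary` or `af_fss_profile`.
#' @param file optional PNG path for the figure.
#' @return the ggplot object, invisibly.
#' @export
report <- function(x, file = NULL) {
  if (inherits(x, "af_cycle_summary")) {
    df <- do.call(rbind, lapply(names(x$patch_metrics), function(p)
      cbind(patch = p, x$patch_metrics[[p]]$time_series)))
    print(x)
    g <- ggplot2::ggplot(df, ggplot2::aes(
      x = .data$time_s, y = .data$spatial_max_dyncm2,
      colour = .data$patch)) +
      ggplot2::geom_line() +
      ggplot2::labs(x = "time (s)",
                    y = "maximum FSS on ovary (dynes/cm²)",
                    title = sprintf("Ovary FSS, final breathing cycle (A = %.0f cm, f = %.2f Hz)",
                                    100 * x$preset$amplitude,
                                    x$preset$frequency)) +
      ggplot2::theme_minimal()
  } else if (inherits(x, "af_fss_profile")) {
    df <- data.frame(s = x$arclength_m * 1e6, fss = x$fss_dyn_cm2)
    g <- ggplot2::ggplot(df, ggplot2::aes(x = .data$s, y = .data$fss)) +
      ggplot2::geom_line() +
      ggplot2::labs(x = "arclength along cell surface (µm)",
                    y = "FSS (dynes/cm²)",
                    title = sprintf("Idealized-cell surface FSS, U = %.3g m/s",
                                    x$U)) +
      ggplot2::theme_minimal()
  } else stop("report() expects a cycle summary or an FSS profile")
  if (!is.null(file)) ggplot2::ggsave(file, g, width = 6, height = 4,
                                      dpi = 150)
  invisible(g)
}
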
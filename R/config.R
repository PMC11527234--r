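# Run configuration: YAML in, validated nested specs out, with a stable
# content digest.

#' Content digest of a configuration
#'
#' MD5 of the canonical JSON serialization (names sorted recursively), so
#' the digest is stable under field reordering and changes iff the content
#' changes.
#'
#' @param cfg a (nested) list.
#' @return hex digest string.
#' @export
config_digest <- function(cfg) {
  canon <- canonicalize(cfg)
  txt <- jsonlite::toJSON(canon, auto_unbox = TRUE, digits = NA,
                          null = "null")
  tmp <- tempfile()
  on.exit(unlink(tmp))
  writeLines(as.character(txt), tmp)
  unname(tools::md5sum(tmp))
}

canonicalize <- function(x) {
  if (is.list(x)) {
    if (!is.null(names(x)) && any(nzchar(names(x))))
      x <- x[order(names(x))]
    lapply(x, canonicalize)
  } else if (is.matrix(x)) {
    as.list(as.data.frame(x))
  } else x
}

#' Load and validate a run configuration
#'
#' Reads a YAML configuration with optional blocks `geometry`, `preset`
#' (name or amplitude/frequency), `fluid`, `solver`, `mesh_motion`, `mode`
#' and `outputs`, fills defaults, and constructs the validated nested
#' specification objects.
#'
#' @param path YAML file, or a list already parsed.
#' @return list of class `af_run_config` with validated components and a
#'   content `digest`.
#' @export
run_config <- function(path) {
  raw <- if (is.character(path)) yaml::read_yaml(path) else path
  if (!is.list(raw)) stop("configuration must be a mapping")
  mode <- raw$mode %||% "cavity"
  if (!mode %in% c("cavity", "bioreactor", "verify"))
    stop("mode must be one of cavity, bioreactor, verify")
  geom <- do.call(cavity_spec, raw$geometry %||% list())
  pre <- if (is.character(raw$preset %||% "regular")) {
    preset(raw$preset %||% "regular")
  } else do.call(breathing_preset, raw$preset)
  fluid <- do.call(fluid_properties, raw$fluid %||% list())
  solver <- do.call(solver_settings, raw$solver %||% list())
  mm <- do.call(mesh_motion_settings, raw$mesh_motion %||% list())
  rig <- raw$bioreactor %||% list()
  out <- list(mode = mode, geometry = geom, preset = pre, fluid = fluid,
              solver = solver, mesh_motion = mm, bioreactor = rig,
              outputs = raw$outputs %||% list())
  out$digest <- config_digest(lapply(out, function(z)
    if (is.list(z)) unclass(z) else z))
  class(out) <- "af_run_config"
  out
}
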
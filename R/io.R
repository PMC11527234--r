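# Mesh and field I/O: minimal ASCII writers/readers for the two standard
# unstructured-mesh exchange formats used by the pipeline (XML VTU for
# visualization time series, Gmsh MSH 2.2 for mesh exchange). Patch labels
# travel as integer tags with a name table.

#' Write a mesh (with optional point data) as ASCII VTU
#'
#' @param mesh an [af_mesh].
#' @param file output path (`.vtu`).
#' @param point_data named list of per-node vectors or matrices (vectors
#'   of length `n_nodes`, matrices `n_nodes x d`).
#' @param points optional displaced coordinates.
#' @return the file path, invisibly.
#' @export
write_vtu <- function(mesh, file, point_data = list(), points = NULL) {
  p <- if (is.null(points)) mesh$points else points
  if (ncol(p) == 2L) p <- cbind(p, 0)
  nn <- nrow(p); ne <- nrow(mesh$cells)
  vtk_type <- if (mesh$dim == 2L) 5L else 10L   # triangle / tetra
  con <- file(file, "w")
  on.exit(close(con))
  w <- function(...) cat(..., "\n", sep = "", file = con)
  num <- function(x) paste(format(x, digits = 12, trim = TRUE),
                           collapse = " ")
  w('<?xml version="1.0"?>')
  w('<VTKFile type="UnstructuredGrid" version="0.1" byte_order="LittleEndian">')
  w('<UnstructuredGrid>')
  w(sprintf('<Piece NumberOfPoints="%d" NumberOfCells="%d">', nn, ne))
  w('<Points><DataArray type="Float64" NumberOfComponents="3" format="ascii">')
  w(num(t(p)))
  w('</DataArray></Points>')
  w('<Cells>')
  w('<DataArray type="Int32" Name="connectivity" format="ascii">')
  w(paste(t(mesh$cells) - 1L, collapse = " "))
  w('</DataArray>')
  w('<DataArray type="Int32" Name="offsets" format="ascii">')
  w(paste(seq_len(ne) * (mesh$dim + 1L), collapse = " "))
  w('</DataArray>')
  w('<DataArray type="UInt8" Name="types" format="ascii">')
  w(paste(rep(vtk_type, ne), collapse = " "))
  w('</DataArray>')
  w('</Cells>')
  if (length(point_data)) {
    w('<PointData>')
    for (nmv in names(point_data)) {
      v <- point_data[[nmv]]
      if (is.matrix(v)) {
        if (ncol(v) == 2L) v <- cbind(v, 0)
        w(sprintf('<DataArray type="Float64" Name="%s" NumberOfComponents="%d" format="ascii">',
                  nmv, ncol(v)))
        w(num(t(v)))
      } else {
        w(sprintf('<DataArray type="Float64" Name="%s" format="ascii">', nmv))
        w(num(v))
      }
      w('</DataArray>')
    }
    w('</PointData>')
  }
  w('</Piece>')
  w('</UnstructuredGrid>')
  w('</VTKFile>')
  invisible(file)
}

#' Write a PVD collection referencing a VTU time series
#'
#' @param files VTU file names (relative to the PVD location).
#' @param times time stamps (s).
#' @param file output `.pvd` path.
#' @export
write_pvd <- function(files, times, file) {
  con <- file(file, "w")
  on.exit(close(con))
  cat('<?xml version="1.0"?>\n<VTKFile type="Collection" version="0.1">\n',
      '<Collection>\n', sep = "", file = con)
  for (i in seq_along(files))
    cat(sprintf('<DataSet timestep="%.10g" part="0" file="%s"/>\n',
                times[i], files[i]), file = con)
  cat('</Collection>\n</VTKFile>\n', file = con)
  invisible(file)
}

#' Write / read a mesh in Gmsh MSH 2.2 ASCII format
#'
#' Boundary facets are written as lower-dimensional elements carrying
#' physical tags; the physical-name table stores the patch labels, so a
#' round trip preserves the patch taxonomy.
#'
#' @param mesh an [af_mesh].
#' @param file path (`.msh`).
#' @export
write_msh <- function(mesh, file) {
  patches <- sort(unique(mesh$facet_patch))
  ptag <- seq_along(patches)
  names(ptag) <- patches
  d <- mesh$dim
  con <- file(file, "w")
  on.exit(close(con))
  w <- function(...) cat(..., "\n", sep = "", file = con)
  w("$MeshFormat"); w("2.2 0 8"); w("$EndMeshFormat")
  w("$PhysicalNames"); w(length(patches) + 1L)
  for (p in patches) w(sprintf('%d %d "%s"', d - 1L, ptag[[p]], p))
  w(sprintf('%d %d "domain"', d, length(patches) + 1L))
  w("$EndPhysicalNames")
  w("$Nodes"); w(nrow(mesh$points))
  p3 <- mesh$points
  if (d == 2L) p3 <- cbind(p3, 0)
  for (i in seq_len(nrow(p3)))
    w(paste(c(i, format(p3[i, ], digits = 15)), collapse = " "))
  w("$EndNodes")
  ftype <- if (d == 2L) 1L else 2L   # line / triangle
  ctype <- if (d == 2L) 2L else 4L   # triangle / tetra
  nf <- nrow(mesh$facets); ne <- nrow(mesh$cells)
  w("$Elements"); w(nf + ne)
  id <- 0L
  for (i in seq_len(nf)) {
    id <- id + 1L
    tg <- ptag[[mesh$facet_patch[i]]]
    w(paste(c(id, ftype, 2L, tg, tg, mesh$facets[i, ]), collapse = " "))
  }
  dom <- length(patches) + 1L
  for (i in seq_len(ne)) {
    id <- id + 1L
    w(paste(c(id, ctype, 2L, dom, dom, mesh$cells[i, ]), collapse = " "))
  }
  w("$EndElements")
  invisible(file)
}

#' @rdname write_msh
#' @export
read_msh <- function(file) {
  lines <- readLines(file)
  sec <- function(name) {
    i0 <- which(lines == paste0("$", name)) + 1L
    i1 <- which(lines == paste0("$End", name)) - 1L
    if (!length(i0)) stop("missing $", name, " section")
    lines[i0:i1]
  }
  pn <- sec("PhysicalNames")[-1]
  pn_split <- strsplit(trimws(pn), "\\s+")
  tags <- vapply(pn_split, function(z) as.integer(z[2]), integer(1))
  nms <- vapply(pn_split, function(z)
    gsub('"', "", paste(z[-(1:2)], collapse = " ")), character(1))
  dims <- vapply(pn_split, function(z) as.integer(z[1]), integer(1))
  nodes <- sec("Nodes")[-1]
  nmat <- do.call(rbind, lapply(strsplit(trimws(nodes), "\\s+"),
                                as.numeric))
  pts <- nmat[order(nmat[, 1]), 2:4, drop = FALSE]
  el <- sec("Elements")[-1]
  emat <- lapply(strsplit(trimws(el), "\\s+"), as.integer)
  etype <- vapply(emat, `[`, integer(1), 2L)
  d <- if (any(etype == 4L)) 3L else 2L
  ctype <- if (d == 2L) 2L else 4L
  ftype <- if (d == 2L) 1L else 2L
  if (d == 2L) pts <- pts[, 1:2, drop = FALSE]
  cells <- do.call(rbind, lapply(emat[etype == ctype], function(z)
    z[(length(z) - d):length(z)]))
  fac <- do.call(rbind, lapply(emat[etype == ftype], function(z)
    z[(length(z) - d + 1L):length(z)]))
  ftag <- vapply(emat[etype == ftype], function(z) z[4L], integer(1))
  lab <- nms[match(ftag, tags)]
  m <- af_mesh(pts, cells, validate = FALSE)
  # re-associate patch labels with the (re-extracted, outward-oriented)
  # boundary facets
  key_in <- facet_key(fac)
  key_out <- facet_key(m$facets)
  patch <- lab[match(key_out, key_in)]
  if (anyNA(patch)) stop("boundary facets in file do not cover the boundary")
  af_mesh(pts, cells, m$facets, patch)
}

#' Write per-snapshot patch WSS time series as CSV
#'
#' Columns: `time_s, patch, spatial_mean_dyncm2, spatial_max_dyncm2`.
#'
#' @param history `af_flow_history`.
#' @param mesh the cavity mesh.
#' @param file output CSV path.
#' @param patches patch names (default: the ovary patches).
#' @export
write_patch_series <- function(history, mesh, file,
                               patches = c("ovary_left", "ovary_right")) {
  rows <- list()
  for (p in intersect(patches, unique(mesh$facet_patch))) {
    pm <- patch_metrics_all_cycles(history, mesh, p)
    rows[[p]] <- cbind(patch = p, pm)
  }
  df <- do.call(rbind, rows)
  df <- df[, c("time_s", "patch", "spatial_mean_dyncm2",
               "spatial_max_dyncm2")]
  utils::write.csv(df, file, row.names = FALSE, quote = FALSE)
  invisible(file)
}

# patch series over every snapshot (not only the final cycle)
patch_metrics_all_cycles <- function(history, mesh, patch) {
  vsp <- fem_space(mesh, velocity_order(history$settings))
  pd <- boundary_dofs(vsp, patch)
  Mb <- asm_boundary_mass(vsp, facet_sel = mesh$facet_patch == patch)
  wts <- as.vector(Mb %*% rep(1, vsp$ndof))[pd]
  out <- data.frame(time_s = history$times,
                    spatial_mean_dyncm2 = NA_real_,
                    spatial_max_dyncm2 = NA_real_)
  for (s in seq_along(history$wss)) {
    f <- history$wss[[s]]
    mag <- f$mag_dyn_cm2[match(pd, f$dofs)]
    out$spatial_mean_dyncm2[s] <- sum(wts * mag) / sum(wts)
    out$spatial_max_dyncm2[s] <- max(mag)
  }
  out
}
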
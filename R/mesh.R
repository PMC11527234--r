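#' Unstructured simplex mesh with tagged boundary patches
#'
#' Container for the triangulated (2D) or tetrahedralized (3D) fluid domain.
#' Boundary facets are stored with outward orientation and each carries
#' exactly one patch label; the union of patches covers the whole boundary.
#'
#' @param points numeric matrix `n_nodes x d` of node coordinates (m).
#' @param cells integer matrix `n_cells x (d+1)` of simplex connectivity
#'   (1-based). Cells are re-oriented to positive signed volume.
#' @param facets integer matrix `n_facets x d` of boundary facet
#'   connectivity, outward-oriented. If `NULL`, facets are extracted from
#'   `cells` and labelled `"boundary"`.
#' @param facet_patch character vector of patch labels, one per facet.
#' @param validate run the full invariant checks (positive volumes, labelled
#'   boundary cover). Fixture meshes for error-path tests may disable this.
#' @return an object of class `af_mesh`.
#' @export
af_mesh <- function(points, cells, facets = NULL, facet_patch = NULL,
                    validate = TRUE) {
  points <- as.matrix(points)
  storage.mode(points) <- "double"
  cells <- as.matrix(cells)
  storage.mode(cells) <- "integer"
  d <- ncol(points)
  if (!d %in% 2:3) stop("mesh dimension must be 2 or 3")
  if (ncol(cells) != d + 1L) stop("cells must have d+1 vertices per row")

  cells <- orient_cells(points, cells)
  if (is.null(facets)) {
    bf <- boundary_facets_from_cells(points, cells)
    facets <- bf
    facet_patch <- rep("boundary", nrow(bf))
  } else {
    facets <- as.matrix(facets)
    storage.mode(facets) <- "integer"
  }
  if (is.null(facet_patch) || length(facet_patch) != nrow(facets))
    stop("facet_patch must label every boundary facet")

  m <- structure(list(points = points, cells = cells, facets = facets,
                      facet_patch = as.character(facet_patch), dim = d),
                 class = "af_mesh")
  if (validate) validate_mesh(m)
  m
}

#' @export
print.af_mesh <- function(x, ...) {
  cat(sprintf("<af_mesh> %dD: %d nodes, %d cells, %d boundary facets\n",
              x$dim, nrow(x$points), nrow(x$cells), nrow(x$facets)))
  tab <- table(x$facet_patch)
  cat("  patches:", paste(sprintf("%s (%d)", names(tab), tab), collapse = ", "),
      "\n")
  invisible(x)
}

# Signed volumes of all cells (areas in 2D).
cell_volumes <- function(points, cells) {
  d <- ncol(points)
  p0 <- points[cells[, 1L], , drop = FALSE]
  if (d == 2L) {
    e1 <- points[cells[, 2L], , drop = FALSE] - p0
    e2 <- points[cells[, 3L], , drop = FALSE] - p0
    (e1[, 1] * e2[, 2] - e1[, 2] * e2[, 1]) / 2
  } else {
    e1 <- points[cells[, 2L], , drop = FALSE] - p0
    e2 <- points[cells[, 3L], , drop = FALSE] - p0
    e3 <- points[cells[, 4L], , drop = FALSE] - p0
    (e1[, 1] * (e2[, 2] * e3[, 3] - e2[, 3] * e3[, 2]) -
     e1[, 2] * (e2[, 1] * e3[, 3] - e2[, 3] * e3[, 1]) +
     e1[, 3] * (e2[, 1] * e3[, 2] - e2[, 2] * e3[, 1])) / 6
  }
}

# Flip negatively oriented cells so all signed volumes are positive.
orient_cells <- function(points, cells) {
  v <- cell_volumes(points, cells)
  neg <- which(v < 0)
  if (length(neg)) {
    tmp <- cells[neg, 2L]
    cells[neg, 2L] <- cells[neg, 3L]
    cells[neg, 3L] <- tmp
  }
  cells
}

# Local facet index sets: facet j is opposite local vertex j, oriented so the
# outward normal points away from the opposite vertex (cells positively
# oriented).
local_facets <- function(d) {
  if (d == 2L) list(c(2L, 3L), c(3L, 1L), c(1L, 2L))
  else list(c(2L, 3L, 4L), c(1L, 4L, 3L), c(1L, 2L, 4L), c(1L, 3L, 2L))
}

all_cell_facets <- function(cells, d) {
  lf <- local_facets(d)
  do.call(rbind, lapply(lf, function(ix) cells[, ix, drop = FALSE]))
}

facet_key <- function(f) {
  fs <- t(apply(f, 1L, sort))
  do.call(paste, c(as.data.frame(fs), sep = "_"))
}

# Extract outward-oriented boundary facets (those appearing in exactly one
# cell).
boundary_facets_from_cells <- function(points, cells) {
  d <- ncol(points)
  af <- all_cell_facets(cells, d)
  key <- facet_key(af)
  cnt <- table(key)
  bnd <- af[key %in% names(cnt)[cnt == 1L], , drop = FALSE]
  storage.mode(bnd) <- "integer"
  bnd
}

# Outward unit normals and measures (lengths in 2D, areas in 3D) of oriented
# boundary facets.
facet_normals <- function(mesh) {
  p <- mesh$points
  f <- mesh$facets
  if (mesh$dim == 2L) {
    t1 <- p[f[, 2L], , drop = FALSE] - p[f[, 1L], , drop = FALSE]
    len <- sqrt(rowSums(t1^2))
    n <- cbind(t1[, 2], -t1[, 1]) / len
    list(normal = n, area = len)
  } else {
    e1 <- p[f[, 2L], , drop = FALSE] - p[f[, 1L], , drop = FALSE]
    e2 <- p[f[, 3L], , drop = FALSE] - p[f[, 1L], , drop = FALSE]
    cr <- cbind(e1[, 2] * e2[, 3] - e1[, 3] * e2[, 2],
                e1[, 3] * e2[, 1] - e1[, 1] * e2[, 3],
                e1[, 1] * e2[, 2] - e1[, 2] * e2[, 1])
    a2 <- sqrt(rowSums(cr^2))
    list(normal = cr / a2, area = a2 / 2)
  }
}

validate_mesh <- function(mesh) {
  v <- cell_volumes(mesh$points, mesh$cells)
  bad <- which(v <= 0)
  if (length(bad))
    stop("mesh has non-positive cell volumes in cells: ",
         paste(utils::head(bad, 10L), collapse = ", "))
  if (any(!is.finite(mesh$points))) stop("mesh has non-finite coordinates")
  fn <- facet_normals(mesh)
  if (any(fn$area <= 0) || any(!is.finite(fn$area)))
    stop("mesh has degenerate boundary facets")
  # Boundary cover: stored facets must be exactly the topological boundary.
  bf <- boundary_facets_from_cells(mesh$points, mesh$cells)
  if (!setequal(facet_key(bf), facet_key(mesh$facets)) ||
      nrow(bf) != nrow(mesh$facets))
    stop("patch labels do not cover the mesh boundary exactly")
  # Outward orientation: facet normal must point away from the domain.
  ctr <- facet_centroids(mesh)
  inw <- inward_offset_points(mesh)
  dotp <- rowSums(fn$normal * (ctr - inw))
  if (any(dotp <= 0)) stop("boundary facets are not consistently outward-oriented")
  invisible(TRUE)
}

facet_centroids <- function(mesh) {
  f <- mesh$facets
  out <- 0
  for (j in seq_len(ncol(f))) out <- out + mesh$points[f[, j], , drop = FALSE]
  out / ncol(f)
}

# A point just inside the domain for each boundary facet: centroid of the
# (unique) adjacent cell.
inward_offset_points <- function(mesh) {
  d <- mesh$dim
  af <- all_cell_facets(mesh$cells, d)
  keys <- facet_key(af)
  cellof <- rep(seq_len(nrow(mesh$cells)), d + 1L)
  idx <- match(facet_key(mesh$facets), keys)
  adj <- cellof[idx]
  ctr <- 0
  for (j in seq_len(d + 1L))
    ctr <- ctr + mesh$points[mesh$cells[adj, j], , drop = FALSE]
  ctr / (d + 1L)
}

#' Total mesh volume (area in 2D)
#'
#' Sum of signed cell volumes; errors if any cell is inverted, naming the
#' offending cells.
#'
#' @param mesh an [af_mesh].
#' @return volume in m^3 (m^2 for planar meshes).
#' @export
compute_volume <- function(mesh) {
  v <- cell_volumes(mesh$points, mesh$cells)
  bad <- which(v <= 0)
  if (length(bad))
    stop("inverted cells: ", paste(utils::head(bad, 10L), collapse = ", "))
  sum(v)
}

# Volume enclosed by an oriented boundary surface with (possibly displaced)
# node coordinates, via the divergence theorem: V = (1/d) * sum centroid.n A.
# Only boundary node positions matter, which is what the isovolumetric
# compensation solve needs.
enclosed_volume <- function(mesh, displaced_points = NULL) {
  p <- if (is.null(displaced_points)) mesh$points else displaced_points
  f <- mesh$facets
  if (mesh$dim == 2L) {
    x1 <- p[f[, 1L], , drop = FALSE]; x2 <- p[f[, 2L], , drop = FALSE]
    # shoelace over oriented segments
    sum(x1[, 1] * x2[, 2] - x2[, 1] * x1[, 2]) / 2
  } else {
    x1 <- p[f[, 1L], , drop = FALSE]
    x2 <- p[f[, 2L], , drop = FALSE]
    x3 <- p[f[, 3L], , drop = FALSE]
    sum(x1[, 1] * (x2[, 2] * x3[, 3] - x2[, 3] * x3[, 2]) -
        x1[, 2] * (x2[, 1] * x3[, 3] - x2[, 3] * x3[, 1]) +
        x1[, 3] * (x2[, 1] * x3[, 2] - x2[, 2] * x3[, 1])) / 6
  }
}

# Unique edges (sorted node pairs) of the mesh; returns matrix ne x 2 and,
# for each cell, the local-edge -> global-edge index map.
mesh_edges <- function(mesh) {
  d <- mesh$dim
  le <- if (d == 2L) list(c(1L, 2L), c(2L, 3L), c(3L, 1L))
        else list(c(1L, 2L), c(1L, 3L), c(1L, 4L), c(2L, 3L), c(2L, 4L),
                  c(3L, 4L))
  pairs <- do.call(rbind, lapply(le, function(ix) mesh$cells[, ix]))
  a <- pmin(pairs[, 1L], pairs[, 2L]); b <- pmax(pairs[, 1L], pairs[, 2L])
  key <- a * (nrow(mesh$points) + 1) + b
  uk <- sort(unique(key))
  idx <- match(key, uk)
  ua <- a[match(uk, key)]; ub <- b[match(uk, key)]
  list(edges = cbind(ua, ub),
       cell_edge = matrix(idx, nrow = nrow(mesh$cells)),
       n_edges = length(uk))
}

#' Uniform red refinement
#'
#' Each triangle is split into 4 children, each tetrahedron into 8 (corner
#' tetrahedra plus an octahedron cut along a fixed diagonal). Boundary facets
#' are split with patch labels inherited by the children; volume and patch
#' areas are preserved exactly for straight-sided meshes.
#'
#' @param mesh an [af_mesh].
#' @param levels number of uniform refinements (`0` returns the mesh
#'   unchanged).
#' @return refined [af_mesh].
#' @export
refine <- function(mesh, levels = 1L) {
  stopifnot(levels >= 0)
  if (levels == 0L) return(mesh)
  for (l in seq_len(levels)) mesh <- refine_once(mesh)
  mesh
}

refine_once <- function(mesh) {
  d <- mesh$dim
  ed <- mesh_edges(mesh)
  nn <- nrow(mesh$points)
  mid <- (mesh$points[ed$edges[, 1L], , drop = FALSE] +
          mesh$points[ed$edges[, 2L], , drop = FALSE]) / 2
  points <- rbind(mesh$points, mid)
  midof <- function(a, b) {             # global midpoint node of edge (a, b)
    key <- pmin(a, b) * (nn + 1) + pmax(a, b)
    ukey <- ed$edges[, 1L] * (nn + 1) + ed$edges[, 2L]
    nn + match(key, ukey)
  }
  cl <- mesh$cells
  if (d == 2L) {
    m12 <- midof(cl[, 1], cl[, 2]); m23 <- midof(cl[, 2], cl[, 3])
    m31 <- midof(cl[, 3], cl[, 1])
    cells <- rbind(cbind(cl[, 1], m12, m31), cbind(m12, cl[, 2], m23),
                   cbind(m31, m23, cl[, 3]), cbind(m12, m23, m31))
    f <- mesh$facets
    fm <- midof(f[, 1], f[, 2])
    facets <- rbind(cbind(f[, 1], fm), cbind(fm, f[, 2]))
    patch <- rep(mesh$facet_patch, 2L)
  } else {
    e1 <- midof(cl[, 1], cl[, 2]); e2 <- midof(cl[, 1], cl[, 3])
    e3 <- midof(cl[, 1], cl[, 4]); e4 <- midof(cl[, 2], cl[, 3])
    e5 <- midof(cl[, 2], cl[, 4]); e6 <- midof(cl[, 3], cl[, 4])
    cells <- rbind(
      cbind(cl[, 1], e1, e2, e3), cbind(cl[, 2], e1, e4, e5),
      cbind(cl[, 3], e2, e4, e6), cbind(cl[, 4], e3, e5, e6),
      # octahedron cut along the e2-e5 diagonal (Bey's rule)
      cbind(e1, e2, e3, e5), cbind(e1, e2, e4, e5),
      cbind(e2, e3, e5, e6), cbind(e2, e4, e5, e6))
    f <- mesh$facets
    f12 <- midof(f[, 1], f[, 2]); f23 <- midof(f[, 2], f[, 3])
    f31 <- midof(f[, 3], f[, 1])
    facets <- rbind(cbind(f[, 1], f12, f31), cbind(f12, f[, 2], f23),
                    cbind(f31, f23, f[, 3]), cbind(f12, f23, f31))
    patch <- rep(mesh$facet_patch, 4L)
  }
  af_mesh(points, cells, facets, patch, validate = FALSE)
}

#' Mesh quality summary
#'
#' Counts, extremal cell volumes, cell aspect ratios (circumscribed over
#' inscribed ball diameter proxy: longest edge over `d * volume /
#' surface-proxy`), and the boundary area broken down by patch. The mesh is
#' validated first; degenerate meshes error rather than report.
#'
#' @param mesh an [af_mesh].
#' @return list of class `af_quality_report`.
#' @export
quality_report <- function(mesh) {
  validate_mesh(mesh)
  v <- cell_volumes(mesh$points, mesh$cells)
  ed <- mesh_edges(mesh)
  el <- sqrt(rowSums((mesh$points[ed$edges[, 1], , drop = FALSE] -
                      mesh$points[ed$edges[, 2], , drop = FALSE])^2))
  hmax <- apply(matrix(el[ed$cell_edge], nrow = nrow(mesh$cells)), 1L, max)
  d <- mesh$dim
  # regular-simplex-normalized shape measure: 1 for equilateral cells
  reg <- if (d == 2L) sqrt(3) / 4 else sqrt(2) / 12
  aspect <- (reg * hmax^d) / v
  fn <- facet_normals(mesh)
  areas <- tapply(fn$area, mesh$facet_patch, sum)
  structure(list(
    n_nodes = nrow(mesh$points), n_cells = nrow(mesh$cells),
    min_cell_volume = min(v), max_cell_volume = max(v),
    min_aspect = min(aspect), max_aspect = max(aspect),
    max_edge_length = max(el), min_edge_length = min(el),
    boundary_area_by_patch = as.list(areas),
    total_boundary_area = sum(fn$area)), class = "af_quality_report")
}

#' @export
print.af_quality_report <- function(x, ...) {
  cat(sprintf("<quality> %d nodes, %d cells; cell volume [%.3g, %.3g]; aspect [%.2f, %.2f]\n",
              x$n_nodes, x$n_cells, x$min_cell_volume, x$max_cell_volume,
              x$min_aspect, x$max_aspect))
  for (p in names(x$boundary_area_by_patch))
    cat(sprintf("  patch %-12s area %.6g\n", p, x$boundary_area_by_patch[[p]]))
  invisible(x)
}

# Boundary node indices (vertices touching any boundary facet).
boundary_nodes <- function(mesh) sort(unique(as.vector(mesh$facets)))


af_mesh_shallow <- function(mesh, points) {
  m <- mesh; m$points <- points; m
}

# sum `vals` into bins `idx` of length n (sparse accumulate)
tabulate_add <- function(idx, vals, n) {
  out <- numeric(n)
  s <- rowsum(vals, idx)
  out[as.integer(rownames(s))] <- s[, 1L]
  out
}
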
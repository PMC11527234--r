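#' Synthetic peritoneal-cavity specification
#'
#' Parametrizes the stand-in geometry for the ascites-filled peritoneal
#' cavity: a box-shaped fluid domain with a deformable top (diaphragm),
#' fixed lateral walls and floor, and two spherical-cap "ovary" protrusions
#' on the floor. The z axis is cranio-caudal with `z = cavity_height` at the
#' diaphragm. All lengths in metres.
#'
#' Either explicit dimensions or a `target_volume` (with `aspect` ratios
#' width:depth relative to height) may be given; with a target volume the
#' height is adjusted analytically so the realized fluid volume (box minus
#' ovary protrusions) matches the target.
#'
#' @param cavity_width,cavity_depth,cavity_height box dimensions (m). Depth
#'   is ignored in 2D mode.
#' @param target_volume optional fluid volume (m^3); overrides
#'   `cavity_height` via the aspect ratios.
#' @param aspect length-2 ratios `c(width/height, depth/height)` used when
#'   `target_volume` is given.
#' @param ovary_radius sphere radius of the ovary protrusions (m).
#' @param ovary_centers optional 2 x 3 matrix of sphere centers; centers must
#'   lie below the floor plane (`z < 0`) and within radius of it so the caps
#'   protrude from the wall. Default: centers at thirds of the width, mid
#'   depth, submerged by `0.3 * ovary_radius`.
#' @param z_ov ovary reference height (m): motion is zero at and below this
#'   height. Defaults to the top of the ovary protrusions.
#' @param mesh_size target horizontal node spacing (m).
#' @param vertical_coarsening ratio of vertical to horizontal spacing.
#' @param refinement_level each level halves the spacing (regenerating the
#'   boundary, so curved ovary caps are resolved better, unlike [refine()]).
#' @param jitter_frac interior-node jitter amplitude as a fraction of local
#'   spacing (0 keeps the structured mesh; jitter breaks mirror symmetry).
#' @param seed integer controlling the (deterministic) jitter.
#' @param dim 2 for the vertical mid-plane cross-section mode, 3 for the
#'   full cavity.
#' @return object of class `af_cavity_spec`.
#' @export
cavity_spec <- function(cavity_width = 0.18, cavity_depth = 0.08,
                        cavity_height = 0.20, target_volume = NULL,
                        aspect = c(0.55, 0.33),
                        ovary_radius = 0.015, ovary_centers = NULL,
                        z_ov = NULL, mesh_size = 0.0065,
                        vertical_coarsening = 2.5,
                        refinement_level = 0L, jitter_frac = 0,
                        seed = 1L, dim = 2L) {
  dim <- as.integer(dim)
  stopifnot(dim %in% 2:3, ovary_radius > 0, mesh_size > 0,
            refinement_level >= 0, vertical_coarsening > 0)
  submerge <- 0.3 * ovary_radius
  if (!is.null(target_volume)) {
    stopifnot(target_volume > 0, length(aspect) == 2, all(aspect > 0))
    # V = W*D*H - 2 * cap_volume  =>  solve H with W = a1 H, D = a2 H
    hcap <- ovary_radius - submerge
    vcap <- pi * hcap^2 * (3 * ovary_radius - hcap) / 3
    cavity_height <- ((target_volume + 2 * vcap) / prod(aspect))^(1 / 3)
    cavity_width <- aspect[1] * cavity_height
    cavity_depth <- aspect[2] * cavity_height
  }
  stopifnot(cavity_width > 0, cavity_depth > 0, cavity_height > 0)
  if (is.null(ovary_centers)) {
    ovary_centers <- rbind(
      c(cavity_width / 3, cavity_depth / 2, -submerge),
      c(2 * cavity_width / 3, cavity_depth / 2, -submerge))
  }
  ovary_centers <- as.matrix(ovary_centers)
  if (!all(dim(ovary_centers) == c(2L, 3L)))
    stop("ovary_centers must be a 2 x 3 matrix")
  if (any(ovary_centers[, 3] >= 0) ||
      any(-ovary_centers[, 3] >= ovary_radius))
    stop("ovary spheres must intersect the floor: require -radius < center z < 0")
  prot <- ovary_radius + ovary_centers[, 3]   # protrusion heights
  if (is.null(z_ov)) z_ov <- max(prot)
  if (z_ov > cavity_height) stop("z_ov must not exceed cavity_height")
  if (z_ov <= 0) stop("z_ov must be positive")
  structure(list(cavity_width = cavity_width, cavity_depth = cavity_depth,
                 cavity_height = cavity_height,
                 target_volume = target_volume,
                 ovary_radius = ovary_radius, ovary_centers = ovary_centers,
                 z_ov = z_ov, mesh_size = mesh_size,
                 vertical_coarsening = vertical_coarsening,
                 refinement_level = as.integer(refinement_level),
                 jitter_frac = jitter_frac, seed = as.integer(seed),
                 dim = dim), class = "af_cavity_spec")
}

# Floor elevation profile: height of the ovary cap surfaces above z = 0.
# 2D: x only (caps become circular arcs); 3D: (x, y).
cavity_floor_profile <- function(spec, x, y = NULL) {
  b <- numeric(length(x))
  for (k in 1:2) {
    ctr <- spec$ovary_centers[k, ]
    r2 <- (x - ctr[1])^2
    if (!is.null(y)) r2 <- r2 + (y - ctr[2])^2
    inside <- r2 < spec$ovary_radius^2
    h <- numeric(length(x))
    h[inside] <- sqrt(spec$ovary_radius^2 - r2[inside]) + ctr[3]
    b <- pmax(b, pmax(h, 0))
  }
  b
}

# Deterministic pseudo-noise in [-1, 1) independent of the global RNG.
hash_noise <- function(idx, seed, channel = 0) {
  x <- sin(idx * 12.9898 + seed * 78.233 + channel * 37.719) * 43758.5453
  2 * (x - floor(x)) - 1
}

#' Build the synthetic cavity mesh
#'
#' Generates a structured simplex mesh of the cavity described by a
#' [cavity_spec()]: the floor is displaced onto the ovary cap surfaces and
#' the column above is sheared accordingly. Boundary facets are tagged
#' `diaphragm` (top), `lateral` (sides), `floor`, `ovary_left` and
#' `ovary_right`. Deterministic for a fixed spec and seed.
#'
#' @param spec an `af_cavity_spec`.
#' @return an [af_mesh] with the five cavity patches.
#' @export
build_cavity_mesh <- function(spec) {
  stopifnot(inherits(spec, "af_cavity_spec"))
  scale <- 2^spec$refinement_level
  hx <- spec$mesh_size / scale
  hz <- spec$mesh_size * spec$vertical_coarsening / scale
  W <- spec$cavity_width; H <- spec$cavity_height
  nx <- max(4L, as.integer(ceiling(W / hx)))
  if (nx %% 2L == 1L) nx <- nx + 1L   # even: keeps mirror symmetry available
  nz <- max(4L, as.integer(ceiling(H / hz)))
  if (spec$dim == 2L) {
    m <- cavity_mesh_2d(spec, nx, nz)
  } else {
    D <- spec$cavity_depth
    ny <- max(3L, as.integer(ceiling(D / hx)))
    m <- cavity_mesh_3d(spec, nx, ny, nz)
  }
  if (spec$jitter_frac > 0) m <- jitter_interior(m, spec)
  validate_mesh(m)
  m
}

cavity_mesh_2d <- function(spec, nx, nz) {
  W <- spec$cavity_width; H <- spec$cavity_height
  xs <- seq(0, W, length.out = nx + 1L)
  eta <- seq(0, 1, length.out = nz + 1L)
  b <- cavity_floor_profile(spec, xs)
  X <- rep(xs, times = nz + 1L)
  E <- rep(eta, each = nx + 1L)
  B <- rep(b, times = nz + 1L)
  Z <- B + E * (H - B)
  points <- cbind(X, Z)
  nid <- function(i, j) (j - 1L) * (nx + 1L) + i   # i in 1..nx+1, j in 1..nz+1
  cells <- matrix(0L, 2L * nx * nz, 3L)
  r <- 1L
  for (j in seq_len(nz)) {
    for (i in seq_len(nx)) {
      a <- nid(i, j); bq <- nid(i + 1L, j)
      c2 <- nid(i + 1L, j + 1L); d2 <- nid(i, j + 1L)
      # mirror-symmetric diagonal pattern about x = W/2
      if (i <= nx %/% 2L) {
        cells[r, ] <- c(a, bq, c2); cells[r + 1L, ] <- c(a, c2, d2)
      } else {
        cells[r, ] <- c(a, bq, d2); cells[r + 1L, ] <- c(bq, c2, d2)
      }
      r <- r + 2L
    }
  }
  # boundary facets
  fac <- NULL; pat <- NULL
  tol <- 1e-12 * max(W, H)
  for (i in seq_len(nx)) {                       # bottom, oriented outward (-z)
    fac <- rbind(fac, c(nid(i, 1L), nid(i + 1L, 1L)))
    xm <- (xs[i] + xs[i + 1L]) / 2
    bm <- cavity_floor_profile(spec, xm)
    pat <- c(pat, if (bm > tol) {
      if (xm < W / 2) "ovary_left" else "ovary_right"
    } else "floor")
  }
  for (i in seq_len(nx)) {                       # top (+z)
    fac <- rbind(fac, c(nid(i + 1L, nz + 1L), nid(i, nz + 1L)))
    pat <- c(pat, "diaphragm")
  }
  for (j in seq_len(nz)) {                       # left (-x)
    fac <- rbind(fac, c(nid(1L, j + 1L), nid(1L, j)))
    pat <- c(pat, "lateral")
  }
  for (j in seq_len(nz)) {                       # right (+x)
    fac <- rbind(fac, c(nid(nx + 1L, j), nid(nx + 1L, j + 1L)))
    pat <- c(pat, "lateral")
  }
  af_mesh(points, cells, fac, pat, validate = FALSE)
}

cavity_mesh_3d <- function(spec, nx, ny, nz) {
  W <- spec$cavity_width; D <- spec$cavity_depth; H <- spec$cavity_height
  xs <- seq(0, W, length.out = nx + 1L)
  ys <- seq(0, D, length.out = ny + 1L)
  eta <- seq(0, 1, length.out = nz + 1L)
  grid <- expand.grid(x = xs, y = ys, eta = eta)
  b <- cavity_floor_profile(spec, grid$x, grid$y)
  z <- b + grid$eta * (H - b)
  points <- cbind(grid$x, grid$y, z)
  nid <- function(i, j, k)
    (k - 1L) * (nx + 1L) * (ny + 1L) + (j - 1L) * (nx + 1L) + i
  cells <- matrix(0L, 6L * nx * ny * nz, 4L)
  r <- 1L
  for (k in seq_len(nz)) for (j in seq_len(ny)) for (i in seq_len(nx)) {
    v000 <- nid(i, j, k);      v100 <- nid(i + 1L, j, k)
    v010 <- nid(i, j + 1L, k); v110 <- nid(i + 1L, j + 1L, k)
    v001 <- nid(i, j, k + 1L); v101 <- nid(i + 1L, j, k + 1L)
    v011 <- nid(i, j + 1L, k + 1L); v111 <- nid(i + 1L, j + 1L, k + 1L)
    # 6-tet split of the hex along the v000-v111 diagonal
    cells[r,      ] <- c(v000, v100, v110, v111)
    cells[r + 1L, ] <- c(v000, v110, v010, v111)
    cells[r + 2L, ] <- c(v000, v010, v011, v111)
    cells[r + 3L, ] <- c(v000, v011, v001, v111)
    cells[r + 4L, ] <- c(v000, v001, v101, v111)
    cells[r + 5L, ] <- c(v000, v101, v100, v111)
    r <- r + 6L
  }
  m0 <- af_mesh(points, cells, validate = FALSE)
  bf <- m0$facets
  ctr <- facet_centroids(m0)
  tol <- 1e-9 * max(W, D, H)
  pat <- character(nrow(bf))
  on_top <- abs(ctr[, 3] - H) < tol
  on_side <- ctr[, 1] < tol | ctr[, 1] > W - tol |
             ctr[, 2] < tol | ctr[, 2] > D - tol
  bfloor <- cavity_floor_profile(spec, ctr[, 1], ctr[, 2])
  pat[] <- "floor"
  pat[bfloor > tol & !on_top & !on_side] <-
    ifelse(ctr[bfloor > tol & !on_top & !on_side, 1] < W / 2,
           "ovary_left", "ovary_right")
  pat[on_side & !on_top] <- "lateral"
  pat[on_top] <- "diaphragm"
  af_mesh(points, cells, bf, pat, validate = FALSE)
}

jitter_interior <- function(mesh, spec) {
  bn <- boundary_nodes(mesh)
  interior <- setdiff(seq_len(nrow(mesh$points)), bn)
  if (!length(interior)) return(mesh)
  ed <- mesh_edges(mesh)
  hmin <- min(sqrt(rowSums((mesh$points[ed$edges[, 1], , drop = FALSE] -
                            mesh$points[ed$edges[, 2], , drop = FALSE])^2)))
  amp <- spec$jitter_frac * hmin / 2
  for (k in seq_len(mesh$dim)) {
    mesh$points[interior, k] <- mesh$points[interior, k] +
      amp * hash_noise(interior, spec$seed, k)
  }
  mesh
}

#' Structured rectangle mesh
#'
#' Axis-aligned `[x0, x0+width] x [y0, y0+height]` triangulated on an
#' `nx x ny` grid, with patches `left`, `right`, `bottom`, `top`. Optional
#' monotone grading functions remap the unit grid coordinates.
#'
#' @param nx,ny grid divisions.
#' @param width,height side lengths (m).
#' @param x0,y0 lower-left corner.
#' @param grade_x,grade_y optional functions mapping `[0,1] -> [0,1]`.
#' @param bottom_profile optional function `b(x)` displacing the floor; the
#'   column above is sheared (used for bump-on-wall channels).
#' @param bottom_patch_fun optional function of facet mid-x returning the
#'   patch label for bottom facets (default all `"bottom"`).
#' @return an [af_mesh].
#' @export
mesh_rectangle <- function(nx, ny, width = 1, height = 1, x0 = 0, y0 = 0,
                           grade_x = NULL, grade_y = NULL,
                           bottom_profile = NULL, bottom_patch_fun = NULL) {
  xs <- seq(0, 1, length.out = nx + 1L)
  ys <- seq(0, 1, length.out = ny + 1L)
  if (!is.null(grade_x)) xs <- grade_x(xs)
  if (!is.null(grade_y)) ys <- grade_y(ys)
  xs <- x0 + width * xs
  b <- if (is.null(bottom_profile)) rep(0, nx + 1L) else bottom_profile(xs)
  X <- rep(xs, times = ny + 1L)
  B <- rep(b, times = ny + 1L)
  ETA <- rep(ys, each = nx + 1L)
  Y <- y0 + B + ETA * (height - B)
  points <- cbind(X, Y)
  nid <- function(i, j) (j - 1L) * (nx + 1L) + i
  cells <- matrix(0L, 2L * nx * ny, 3L)
  r <- 1L
  for (j in seq_len(ny)) for (i in seq_len(nx)) {
    a <- nid(i, j); bb <- nid(i + 1L, j)
    cc <- nid(i + 1L, j + 1L); dd <- nid(i, j + 1L)
    if (i <= nx %/% 2L) {
      cells[r, ] <- c(a, bb, cc); cells[r + 1L, ] <- c(a, cc, dd)
    } else {
      cells[r, ] <- c(a, bb, dd); cells[r + 1L, ] <- c(bb, cc, dd)
    }
    r <- r + 2L
  }
  fac <- NULL; pat <- NULL
  for (i in seq_len(nx)) {
    fac <- rbind(fac, c(nid(i, 1L), nid(i + 1L, 1L)))
    xm <- (xs[i] + xs[i + 1L]) / 2
    pat <- c(pat, if (is.null(bottom_patch_fun)) "bottom"
             else bottom_patch_fun(xm))
  }
  for (i in seq_len(nx)) {
    fac <- rbind(fac, c(nid(i + 1L, ny + 1L), nid(i, ny + 1L)))
    pat <- c(pat, "top")
  }
  for (j in seq_len(ny)) {
    fac <- rbind(fac, c(nid(1L, j + 1L), nid(1L, j)))
    pat <- c(pat, "left")
  }
  for (j in seq_len(ny)) {
    fac <- rbind(fac, c(nid(nx + 1L, j), nid(nx + 1L, j + 1L)))
    pat <- c(pat, "right")
  }
  af_mesh(points, cells, fac, pat)
}

#' Structured box mesh (3D)
#'
#' Unit-style box `[0,w] x [0,d] x [0,h]` split into tetrahedra, with face
#' patches `xmin`, `xmax`, `ymin`, `ymax`, `zmin`, `zmax`.
#'
#' @param nx,ny,nz grid divisions.
#' @param w,d,h side lengths.
#' @return an [af_mesh].
#' @export
mesh_box <- function(nx, ny, nz, w = 1, d = 1, h = 1) {
  spec <- list(cavity_width = w, cavity_depth = d, cavity_height = h,
               ovary_centers = matrix(c(-1, -1, -0.1, -1, -1, -0.1), 2, 3,
                                      byrow = TRUE),
               ovary_radius = 0.05)
  # reuse the 3D cavity builder with a flat floor (ovaries out of domain)
  m <- cavity_mesh_3d(structure(spec, class = "af_cavity_spec"), nx, ny, nz)
  ctr <- facet_centroids(m)
  tol <- 1e-9 * max(w, d, h)
  pat <- character(nrow(m$facets))
  pat[abs(ctr[, 1]) < tol] <- "xmin"; pat[abs(ctr[, 1] - w) < tol] <- "xmax"
  pat[abs(ctr[, 2]) < tol] <- "ymin"; pat[abs(ctr[, 2] - d) < tol] <- "ymax"
  pat[abs(ctr[, 3]) < tol] <- "zmin"; pat[abs(ctr[, 3] - h) < tol] <- "zmax"
  if (any(pat == "")) stop("unlabelled box facet")
  m$facet_patch <- pat
  validate_mesh(m)
  m
}

# Two-sided clustering toward t0 in [0,1]: maps a uniform grid s to a grid
# refined near t = t0 (sinh stretching: slope minimal at the cluster
# point), with strength `beta` > 0.
grade_cluster <- function(t0, beta) {
  s0 <- stats::uniroot(function(s0) {
    t0 * (1 + sinh(beta * (1 - s0)) / sinh(beta * s0)) - 1
  }, c(1e-6, 1 - 1e-6), tol = 1e-14)$root
  cc <- t0 / sinh(beta * s0)
  function(s) t0 + cc * sinh(beta * (s - s0))
}

# one-sided geometric refinement toward t = 0 with ratio `ratio` < 1 for the
# first spacing relative to uniform
grade_wall <- function(strength = 2.5) {
  function(s) (exp(strength * s) - 1) / (exp(strength) - 1)
}
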
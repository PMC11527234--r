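# Finite-element machinery on simplex meshes: P1/P2 Lagrange spaces,
# vectorized operator assembly, and constrained sparse solves. All
# assembly loops run over basis-function pairs and quadrature points with
# length-n_cells vector arithmetic, so cost scales as nb^2 * nq vector ops.

# Shape-function table for order 1 or 2 on the d-simplex: N(lambda) values
# and the gradient expansion gradN_i = sum_m C[i, m](lambda) grad(lambda_m).
shape_eval <- function(order, lambda) {
  np1 <- length(lambda)
  if (order == 1L) {
    N <- lambda
    C <- diag(np1)
  } else {
    vert <- lambda * (2 * lambda - 1)
    pairs <- edge_pairs(np1 - 1L)
    edgeN <- vapply(pairs, function(pr) 4 * lambda[pr[1]] * lambda[pr[2]],
                    numeric(1))
    N <- c(vert, edgeN)
    nb <- np1 + length(pairs)
    C <- matrix(0, nb, np1)
    for (i in seq_len(np1)) C[i, i] <- 4 * lambda[i] - 1
    for (k in seq_along(pairs)) {
      pr <- pairs[[k]]
      C[np1 + k, pr[1]] <- 4 * lambda[pr[2]]
      C[np1 + k, pr[2]] <- 4 * lambda[pr[1]]
    }
  }
  list(N = N, C = C)
}

# Local edge ordering shared with mesh_edges()
edge_pairs <- function(d) {
  if (d == 1L) list(c(1L, 2L))
  else if (d == 2L) list(c(1L, 2L), c(2L, 3L), c(3L, 1L))
  else list(c(1L, 2L), c(1L, 3L), c(1L, 4L), c(2L, 3L), c(2L, 4L),
            c(3L, 4L))
}

# Scalar function space on a mesh. order = 1 (vertex dofs) or 2 (vertex +
# edge-midpoint dofs). `points` overrides the mesh coordinates (moving mesh).
fem_space <- function(mesh, order = 2L, points = NULL) {
  p <- if (is.null(points)) mesh$points else points
  nn <- nrow(p)
  if (order == 1L) {
    cell_dofs <- mesh$cells
    ndof <- nn
    dof_coords <- p
    ed <- NULL
  } else {
    ed <- mesh_edges(mesh)
    cell_dofs <- cbind(mesh$cells, nn + ed$cell_edge)
    ndof <- nn + ed$n_edges
    dof_coords <- rbind(p, (p[ed$edges[, 1], , drop = FALSE] +
                            p[ed$edges[, 2], , drop = FALSE]) / 2)
  }
  list(mesh = mesh, order = order, points = p, nn = nn, ndof = ndof,
       cell_dofs = cell_dofs, dof_coords = dof_coords, edges = ed)
}

# Update coordinates of an existing space (same topology).
space_with_points <- function(space, points) {
  space$points <- points
  if (space$order == 2L) {
    ed <- space$edges
    space$dof_coords <- rbind(points,
      (points[ed$edges[, 1], , drop = FALSE] +
       points[ed$edges[, 2], , drop = FALSE]) / 2)
  } else space$dof_coords <- points
  space
}

# Per-quadrature-point geometric data: element volumes, barycentric
# gradients, and shape values/gradients for the requested order(s).
fem_geom <- function(mesh, points) {
  d <- mesh$dim
  cl <- mesh$cells
  p0 <- points[cl[, 1L], , drop = FALSE]
  if (d == 2L) {
    e1 <- points[cl[, 2L], , drop = FALSE] - p0
    e2 <- points[cl[, 3L], , drop = FALSE] - p0
    D <- e1[, 1] * e2[, 2] - e1[, 2] * e2[, 1]
    gl <- array(0, c(nrow(cl), 3L, 2L))
    gl[, 2L, 1L] <- e2[, 2] / D;  gl[, 2L, 2L] <- -e2[, 1] / D
    gl[, 3L, 1L] <- -e1[, 2] / D; gl[, 3L, 2L] <- e1[, 1] / D
    gl[, 1L, ] <- -(gl[, 2L, ] + gl[, 3L, ])
    vol <- D / 2
  } else {
    e1 <- points[cl[, 2L], , drop = FALSE] - p0
    e2 <- points[cl[, 3L], , drop = FALSE] - p0
    e3 <- points[cl[, 4L], , drop = FALSE] - p0
    cr23 <- cbind(e2[, 2] * e3[, 3] - e2[, 3] * e3[, 2],
                  e2[, 3] * e3[, 1] - e2[, 1] * e3[, 3],
                  e2[, 1] * e3[, 2] - e2[, 2] * e3[, 1])
    cr31 <- cbind(e3[, 2] * e1[, 3] - e3[, 3] * e1[, 2],
                  e3[, 3] * e1[, 1] - e3[, 1] * e1[, 3],
                  e3[, 1] * e1[, 2] - e3[, 2] * e1[, 1])
    cr12 <- cbind(e1[, 2] * e2[, 3] - e1[, 3] * e2[, 2],
                  e1[, 3] * e2[, 1] - e1[, 1] * e2[, 3],
                  e1[, 1] * e2[, 2] - e1[, 2] * e2[, 1])
    D <- rowSums(e1 * cr23)
    gl <- array(0, c(nrow(cl), 4L, 3L))
    gl[, 2L, ] <- cr23 / D
    gl[, 3L, ] <- cr31 / D
    gl[, 4L, ] <- cr12 / D
    gl[, 1L, ] <- -(gl[, 2L, ] + gl[, 3L, ] + gl[, 4L, ])
    vol <- D / 6
  }
  if (any(vol <= 0)) stop("element inversion: non-positive volumes in cells ",
                          paste(utils::head(which(vol <= 0), 10), collapse = ", "))
  list(vol = vol, gradlam = gl, d = d)
}

# Full per-quadrature-point basis data for one order.
fem_basis_at_quad <- function(geom, order, rule) {
  d <- geom$d
  nq <- nrow(rule$bary)
  Nq <- list(); Gq <- list()
  for (q in seq_len(nq)) {
    se <- shape_eval(order, rule$bary[q, ])
    Nq[[q]] <- se$N
    nb <- length(se$N)
    G <- vector("list", d)
    for (k in seq_len(d)) {
      # (ne x (d+1)) %*% ((d+1) x nb) -> ne x nb
      G[[k]] <- geom$gradlam[, , k] %*% t(se$C)
    }
    Gq[[q]] <- G
  }
  list(N = Nq, G = Gq, nb = length(Nq[[1]]), nq = nq, w = rule$w)
}

# Scalar mass matrix: int N_i N_j
asm_mass <- function(space, geom, basis) {
  nb <- basis$nb; ne <- length(geom$vol)
  cfs <- matrix(0, nb, nb)
  for (q in seq_len(basis$nq))
    cfs <- cfs + basis$w[q] * tcrossprod(basis$N[[q]])
  ii <- jj <- xx <- vector("list", nb * nb)
  k <- 1L
  for (i in seq_len(nb)) for (j in seq_len(nb)) {
    ii[[k]] <- space$cell_dofs[, i]; jj[[k]] <- space$cell_dofs[, j]
    xx[[k]] <- geom$vol * cfs[i, j]
    k <- k + 1L
  }
  Matrix::sparseMatrix(i = unlist(ii), j = unlist(jj), x = unlist(xx),
                       dims = c(space$ndof, space$ndof))
}

# Scalar stiffness: int coef * grad N_i . grad N_j  (coef per element or 1)
asm_stiffness <- function(space, geom, basis, coef = 1) {
  nb <- basis$nb
  ii <- jj <- xx <- vector("list", nb * nb)
  k <- 1L
  for (i in seq_len(nb)) for (j in seq_len(nb)) {
    acc <- 0
    for (q in seq_len(basis$nq)) {
      G <- basis$G[[q]]
      s <- 0
      for (kk in seq_len(geom$d)) s <- s + G[[kk]][, i] * G[[kk]][, j]
      acc <- acc + basis$w[q] * s
    }
    ii[[k]] <- space$cell_dofs[, i]; jj[[k]] <- space$cell_dofs[, j]
    xx[[k]] <- geom$vol * coef * acc
    k <- k + 1L
  }
  Matrix::sparseMatrix(i = unlist(ii), j = unlist(jj), x = unlist(xx),
                       dims = c(space$ndof, space$ndof))
}

# RHS load vector int f N_i with f given at quadrature points as a matrix
# (ne x nq) or a scalar.
asm_load <- function(space, geom, basis, f = 1) {
  out <- numeric(space$ndof)
  for (q in seq_len(basis$nq)) {
    fq <- if (is.matrix(f)) f[, q] else f
    wq <- basis$w[q] * geom$vol * fq
    for (i in seq_len(basis$nb)) {
      out <- out + tabulate_add(space$cell_dofs[, i], wq * basis$N[[q]][i],
                                space$ndof)
    }
  }
  out
}

# Evaluate a coefficient field (dof vector or ne x d matrix of dof values)
# at quadrature points: returns list over q of (ne x ncol) matrices.
field_at_quad <- function(space, basis, U) {
  U <- as.matrix(U)
  lapply(seq_len(basis$nq), function(q) {
    out <- matrix(0, nrow(space$cell_dofs), ncol(U))
    for (i in seq_len(basis$nb))
      out <- out + basis$N[[q]][i] * U[space$cell_dofs[, i], , drop = FALSE]
    out
  })
}

# Sparse direct solve via explicit LU (avoids the slow generic solve path).
sparse_solve <- function(A, b) {
  as.vector(Matrix::solve(Matrix::lu(methods::as(A, "CsparseMatrix")), b))
}

# Solve A x = b with Dirichlet constraints x[dofs] = vals.
solve_constrained <- function(A, b, dofs, vals) {
  n <- nrow(A)
  free <- setdiff(seq_len(n), dofs)
  x <- numeric(n)
  x[dofs] <- vals
  rhs <- b[free]
  if (length(dofs)) rhs <- rhs - as.vector(A[free, dofs, drop = FALSE] %*% vals)
  Aff <- methods::as(A[free, free, drop = FALSE], "CsparseMatrix")
  x[free] <- as.vector(Matrix::solve(Matrix::lu(Aff), rhs))
  x
}

# Boundary facet dof matrix for a space: per facet, the dofs of its
# (d-1)-simplex trace element, ordered (vertices..., edge midpoints...).
facet_dofs <- function(space) {
  mesh <- space$mesh
  f <- mesh$facets
  if (space$order == 1L) return(f)
  nn <- space$nn
  ed <- space$edges
  ukey <- ed$edges[, 1L] * (nn + 1) + ed$edges[, 2L]
  midof <- function(a, b) {
    key <- pmin(a, b) * (nn + 1) + pmax(a, b)
    nn + match(key, ukey)
  }
  if (mesh$dim == 2L) {
    cbind(f, midof(f[, 1L], f[, 2L]))
  } else {
    cbind(f, midof(f[, 1L], f[, 2L]), midof(f[, 2L], f[, 3L]),
          midof(f[, 3L], f[, 1L]))
  }
}

# All boundary scalar dofs of a space (vertices on the boundary plus, for
# P2, midpoints of boundary facet edges), optionally restricted to patches.
boundary_dofs <- function(space, patches = NULL) {
  fd <- facet_dofs(space)
  sel <- if (is.null(patches)) rep(TRUE, nrow(fd))
         else space$mesh$facet_patch %in% patches
  sort(unique(as.vector(fd[sel, , drop = FALSE])))
}

# Facet measures (length/area) for current coordinates.
facet_measures <- function(mesh, points) {
  fn <- facet_normals(af_mesh_shallow(mesh, points))
  fn
}

# Boundary mass matrix over (a subset of) facets for the trace space of
# `space`; used by the consistent-flux traction solve and by patch
# area-weighted means. Consistent (non-lumped).
asm_boundary_mass <- function(space, facet_sel = NULL) {
  mesh <- space$mesh
  fdofs <- facet_dofs(space)
  if (!is.null(facet_sel)) fdofs <- fdofs[facet_sel, , drop = FALSE]
  meas <- facet_measures(mesh, space$points)$area
  if (!is.null(facet_sel)) meas <- meas[facet_sel]
  rule <- gm_rule(2L, mesh$dim - 1L)
  nb <- ncol(fdofs)
  cfs <- matrix(0, nb, nb)
  for (q in seq_len(nrow(rule$bary))) {
    se <- shape_eval(space$order, rule$bary[q, ])
    cfs <- cfs + rule$w[q] * tcrossprod(se$N)
  }
  ii <- jj <- xx <- vector("list", nb * nb)
  k <- 1L
  for (i in seq_len(nb)) for (j in seq_len(nb)) {
    ii[[k]] <- fdofs[, i]; jj[[k]] <- fdofs[, j]
    xx[[k]] <- meas * cfs[i, j]
    k <- k + 1L
  }
  Matrix::sparseMatrix(i = unlist(ii), j = unlist(jj), x = unlist(xx),
                       dims = c(space$ndof, space$ndof))
}

# Variationally consistent outward unit normal at each boundary dof:
# normalize(M_b^{-1} . \oint n N_i ds). On flat patches this equals the
# geometric normal; at patch junctions it is the mass-weighted average that
# makes a hydrostatic pressure contribution to the consistent-flux traction
# exactly normal, so the tangential projection is pressure-invariant.
dof_normals_weak <- function(space, Mbb = NULL, bd = NULL) {
  mesh <- space$mesh
  fn <- facet_measures(mesh, space$points)
  fdofs <- facet_dofs(space)
  rule <- gm_rule(2L, mesh$dim - 1L)
  nb <- ncol(fdofs)
  nint <- numeric(nb)              # int N_i over reference facet
  for (q in seq_len(nrow(rule$bary))) {
    se <- shape_eval(space$order, rule$bary[q, ])
    nint <- nint + rule$w[q] * se$N
  }
  b <- matrix(0, space$ndof, mesh$dim)
  for (j in seq_len(nb)) for (k in seq_len(mesh$dim)) {
    b[, k] <- b[, k] + tabulate_add(fdofs[, j],
                                    fn$normal[, k] * fn$area * nint[j],
                                    space$ndof)
  }
  if (is.null(bd)) bd <- boundary_dofs(space)
  if (is.null(Mbb)) Mbb <- asm_boundary_mass(space)[bd, bd, drop = FALSE]
  nt <- matrix(0, space$ndof, mesh$dim)
  for (k in seq_len(mesh$dim))
    nt[bd, k] <- sparse_solve(Mbb, b[bd, k])
  len <- sqrt(rowSums(nt^2))
  keep <- len > 0
  nt[keep, ] <- nt[keep, , drop = FALSE] / len[keep]
  nt
}

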
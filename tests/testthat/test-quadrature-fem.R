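# Quadrature and finite-element kernel checks against closed forms.

test_that("simplex quadrature integrates all monomials up to degree 5 exactly", {
  for (d in 1:3) {
    q <- asciflow:::default_volume_rule(d)
    alphas <- asciflow:::compositions(5L, d + 2L)[, seq_len(d + 1L),
                                                  drop = FALSE]
    for (r in seq_len(nrow(alphas))) {
      a <- alphas[r, ]
      approx <- sum(q$w * apply(q$bary, 1, function(l) prod(l^a)))
      exact <- asciflow:::simplex_monomial_integral(a, d)
      expect_equal(approx, exact, tolerance = 1e-12)
    }
  }
})

test_that("P2 interpolation reproduces quadratic fields at quadrature points", {
  m <- mesh_rectangle(3, 2, 1.3, 0.7)
  vsp <- asciflow:::fem_space(m, 2L)
  f <- function(x) 1 + 2 * x[, 1] - x[, 2] + 0.5 * x[, 1]^2 +
    x[, 1] * x[, 2] - 0.25 * x[, 2]^2
  U <- cbind(f(vsp$dof_coords))
  geom <- asciflow:::fem_geom(m, m$points)
  bV <- asciflow:::fem_basis_at_quad(geom, 2L, asciflow:::default_volume_rule(2L))
  xq <- asciflow:::field_at_quad(vsp, bV, vsp$dof_coords)
  uq <- asciflow:::field_at_quad(vsp, bV, U)
  for (q in seq_along(uq))
    expect_equal(uq[[q]][, 1], f(xq[[q]]), tolerance = 1e-12)
})

test_that("constrained sparse solve matches a dense reference", {
  set.seed(42)
  n <- 30
  A <- Matrix::Matrix(diag(4, n) + 0.5 * matrix(stats::rnorm(n * n), n, n) *
                        (abs(outer(1:n, 1:n, "-")) <= 2), sparse = TRUE)
  b <- stats::rnorm(n)
  dofs <- c(3L, 17L); vals <- c(1.5, -2)
  x <- asciflow:::solve_constrained(A, b, dofs, vals)
  free <- setdiff(1:n, dofs)
  Ad <- as.matrix(A)
  xd <- numeric(n); xd[dofs] <- vals
  xd[free] <- solve(Ad[free, free], b[free] - Ad[free, dofs] %*% vals)
  expect_equal(x, xd, tolerance = 1e-10)
})

test_that("mass and stiffness assembly integrate exactly on affine meshes", {
  m <- mesh_rectangle(4, 3, 2, 1)
  for (order in 1:2) {
    sp <- asciflow:::fem_space(m, order)
    geom <- asciflow:::fem_geom(m, m$points)
    basis <- asciflow:::fem_basis_at_quad(geom, order,
                                          asciflow:::default_volume_rule(2L))
    M <- asciflow:::asm_mass(sp, geom, basis)
    expect_equal(sum(M), 2, tolerance = 1e-12)           # int 1 dx = area
    K <- asciflow:::asm_stiffness(sp, geom, basis)
    # int |grad x|^2 = area for the linear field x
    xfield <- sp$dof_coords[, 1]
    expect_equal(as.numeric(xfield %*% K %*% xfield), 2, tolerance = 1e-12)
    expect_equal(max(abs(K %*% rep(1, sp$ndof))), 0, tolerance = 1e-12)
  }
})
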
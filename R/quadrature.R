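#' Simplex quadrature rules
#'
#' Grundmann-Moeller quadrature of degree `2s + 1` on the reference
#' `d`-simplex. Points are returned as full barycentric coordinates
#' (`n_points x (d+1)`), weights sum to one so that the rule integrates
#' against the *measure-normalized* simplex: multiply by the element volume
#' when assembling. Some weights are negative (a property of the
#' construction, harmless for assembly).
#'
#' @param s rule index; the rule is exact for polynomials of degree `2s + 1`.
#' @param d simplex dimension (1, 2 or 3).
#' @return list with `bary` (matrix of barycentric coordinates) and `w`
#'   (weights summing to 1).
#' @keywords internal
gm_rule <- function(s, d) {
  stopifnot(s >= 0, d >= 1)
  deg <- 2 * s + 1
  pts <- NULL
  wts <- NULL
  for (i in 0:s) {
    m <- s - i
    comps <- compositions(m, d + 1)
    denom <- d + deg - 2 * i
    bary <- (2 * comps + 1) / denom
    w <- (-1)^i * 2^(-2 * s) * denom^deg /
      (factorial(i) * factorial(d + deg - i))
    pts <- rbind(pts, bary)
    wts <- c(wts, rep(w, nrow(bary)))
  }
  # Normalize so constants integrate exactly against unit measure.
  list(bary = pts, w = wts / sum(wts))
}

# All compositions (ordered partitions) of integer m into k nonnegative parts.
compositions <- function(m, k) {
  if (k == 1) return(matrix(m, 1, 1))
  out <- NULL
  for (first in m:0) {
    rest <- compositions(m - first, k - 1)
    out <- rbind(out, cbind(first, rest))
  }
  dimnames(out) <- NULL
  out
}

# Exact integral of a barycentric monomial prod(lambda^alpha) over the
# reference d-simplex, normalized by simplex measure:
#   d! * prod(alpha!) / (|alpha| + d)!
# Used by the test suite to validate the rules.
simplex_monomial_integral <- function(alpha, d) {
  factorial(d) * prod(factorial(alpha)) / factorial(sum(alpha) + d)
}

# Default volume rule per dimension (degree 5: exact for P2 mass and
# convection products).
default_volume_rule <- function(d) gm_rule(2L, d)

# Facet rule: quadrature on the (d-1)-simplex boundary facet.
default_facet_rule <- function(d) gm_rule(2L, d - 1L)
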
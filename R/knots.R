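#' Knot specification for a clamped B-spline basis
#'
#' Defines the polynomial degree and break sequence of the spline space used
#' throughout the package. Boundary knots are *clamped* (repeated `degree + 1`
#' times), so the spline interpolates its first and last B-spline coefficients
#' at the domain endpoints and the basis forms a partition of unity on
#' `[a, b]`.
#'
#' The basis dimension is `length(breaks) - 1 + degree`; e.g. five breaks with
#' quintic (degree 5) splines give a 9-dimensional basis.
#'
#' @param breaks Strictly increasing numeric vector of break points (days);
#'   the first and last entries are the domain endpoints.
#' @param degree Positive integer polynomial degree (order minus one).
#' @return An object of class `"knot_spec"` with elements `breaks`, `degree`,
#'   `a`, `b` and `dim`.
#' @examples
#' ks <- knot_spec(c(0, 2, 5, 8, 10), degree = 5)
#' ks$dim  # 9
#' @export
knot_spec <- function(breaks, degree) {
  breaks <- as.numeric(breaks)
  degree <- as.integer(degree)
  if (length(degree) != 1L || is.na(degree) || degree < 1L)
    stop("'degree' must be a single positive integer")
  if (length(breaks) < 2L || anyNA(breaks))
    stop("'breaks' must contain at least 2 finite values")
  d <- diff(breaks)
  if (any(d <= 0)) {
    i <- which(d <= 0)[1L]
    stop(sprintf("'breaks' must be strictly increasing: breaks[%d] = %g >= breaks[%d] = %g",
                 i, breaks[i], i + 1L, breaks[i + 1L]))
  }
  structure(list(breaks = breaks, degree = degree,
                 a = breaks[1L], b = breaks[length(breaks)],
                 dim = length(breaks) - 1L + degree),
            class = "knot_spec")
}

#' @export
print.knot_spec <- function(x, ...) {
  cat(sprintf("Clamped B-spline basis: degree %d, %d breaks on [%g, %g], dimension %d\n",
              x$degree, length(x$breaks), x$a, x$b, x$dim))
  invisible(x)
}

#' Extended (clamped) knot sequence
#'
#' Returns the full nondecreasing knot sequence with the boundary knots
#' repeated `degree + 1` times, as required by the Cox–de Boor recursion for a
#' clamped basis. Its length is `length(breaks) + 2 * degree`.
#'
#' @param spec A [knot_spec()].
#' @return Numeric vector of knots.
#' @export
build_knots <- function(spec) {
  stopifnot(inherits(spec, "knot_spec"))
  k <- spec$degree
  c(rep(spec$a, k + 1L),
    spec$breaks[-c(1L, length(spec$breaks))],
    rep(spec$b, k + 1L))
}

#' Evaluate the B-spline basis (or a derivative) at given points
#'
#' Thin wrapper around [splines::splineDesign()] on the clamped knot sequence.
#' Rows sum to one for `deriv = 0` (partition of unity) and to zero for
#' `deriv >= 1`.
#'
#' @param spec A [knot_spec()].
#' @param x Evaluation points, all within the domain `[a, b]`.
#' @param deriv Nonnegative integer derivative order, at most `degree`.
#' @return Numeric matrix, `length(x)` rows by `spec$dim` columns.
#' @export
eval_basis <- function(spec, x, deriv = 0L) {
  stopifnot(inherits(spec, "knot_spec"))
  x <- as.numeric(x)
  deriv <- as.integer(deriv)
  if (deriv < 0L || deriv > spec$degree)
    stop("'deriv' must be between 0 and the spline degree")
  eps <- 1e-10 * max(1, abs(spec$a), abs(spec$b))
  if (any(x < spec$a - eps | x > spec$b + eps))
    stop(sprintf("evaluation points must lie within the domain [%g, %g]",
                 spec$a, spec$b))
  x <- pmin(pmax(x, spec$a), spec$b)
  splines::splineDesign(build_knots(spec), x, ord = spec$degree + 1L,
                        derivs = rep(deriv, length(x)))
}

# Gram matrix of derivative order l >= 0 by Gauss-Legendre quadrature per knot
# interval; l = 0 gives the plain L2 Gram matrix used by the functional
# regression. Derivative products are piecewise polynomial of degree
# 2*(k - l), so k - l + 1 nodes per interval are exact.
.gram <- function(spec, l) {
  k <- spec$degree
  kn <- build_knots(spec)
  p <- spec$dim
  nq <- max(k - l + 1L, 2L)
  P <- matrix(0, p, p)
  for (i in seq_len(length(spec$breaks) - 1L)) {
    gl <- pracma::gaussLegendre(nq, spec$breaks[i], spec$breaks[i + 1L])
    D <- splines::splineDesign(kn, gl$x, ord = k + 1L, derivs = rep(l, nq))
    P <- P + crossprod(D, gl$w * D)
  }
  (P + t(P)) / 2
}

#' Roughness penalty Gram matrix
#'
#' Computes the matrix `P` with entries `P[i, j] = integral over [a, b] of
#' B_i^(l)(t) B_j^(l)(t) dt`, so that for a spline with coefficient vector `b`
#' the roughness `integral (s^(l))^2` equals the quadratic form `t(b) P b`.
#' Entries are exact: the integrands are piecewise polynomials integrated by
#' Gauss-Legendre quadrature of sufficient order on each knot interval.
#'
#' @param spec A [knot_spec()].
#' @param order Derivative order `l` of the penalty, `1 <= l <= degree - 1`.
#' @return Symmetric positive semi-definite matrix of size `spec$dim`.
#' @export
penalty_gram <- function(spec, order = 1L) {
  stopifnot(inherits(spec, "knot_spec"))
  order <- as.integer(order)
  if (order < 1L || order > spec$degree)
    stop("penalty 'order' must satisfy 1 <= order <= degree")
  .gram(spec, order)
}

#' L2 Gram matrix of the basis
#'
#' The matrix of inner products `integral B_i(t) B_j(t) dt`, used to evaluate
#' exact L2 norms of splines from their coefficients.
#'
#' @param spec A [knot_spec()].
#' @return Symmetric positive definite matrix of size `spec$dim`.
#' @export
basis_gram <- function(spec) {
  stopifnot(inherits(spec, "knot_spec"))
  .gram(spec, 0L)
}

#' Integrate a spline over its domain
#'
#' The default uses the exact B-spline antiderivative identity:
#' `integral of sum(b_i B_i)` over `[a, b]` equals
#' `sum(b_i * (t[i + k + 1] - t[i]) / (k + 1))` on the clamped knot sequence
#' `t`. A composed-trapezoid evaluation on a fine grid is available as a
#' cross-check.
#'
#' @param coef Spline coefficient vector of length `spec$dim`.
#' @param spec A [knot_spec()].
#' @param method `"exact"` (antiderivative identity) or `"trapezoid"`.
#' @param n Number of grid points for the trapezoid rule.
#' @return The integral (days times the units of the spline values).
#' @export
integrate_spline <- function(coef, spec, method = c("exact", "trapezoid"),
                             n = 10001L) {
  stopifnot(inherits(spec, "knot_spec"))
  method <- match.arg(method)
  coef <- as.numeric(coef)
  if (length(coef) != spec$dim)
    stop(sprintf("'coef' must have length %d (the basis dimension), got %d",
                 spec$dim, length(coef)))
  if (method == "exact") {
    k <- spec$degree
    kn <- build_knots(spec)
    i <- seq_along(coef)
    sum(coef * (kn[i + k + 1L] - kn[i]) / (k + 1L))
  } else {
    g <- seq(spec$a, spec$b, length.out = n)
    pracma::trapz(g, drop(eval_basis(spec, g) %*% coef))
  }
}

#' Write / read a spline as plain JSON
#'
#' Serialises `{degree, breaks, coefficients}` — the same shape as published
#' B-spline coefficient tables — so fitted curves can be exchanged as text.
#'
#' @param coef Coefficient vector.
#' @param spec A [knot_spec()].
#' @param path File path.
#' @return `read_spline()` returns a list with elements `spec` and `coef`.
#' @export
write_spline <- function(coef, spec, path) {
  stopifnot(inherits(spec, "knot_spec"), length(coef) == spec$dim)
  jsonlite::write_json(list(degree = spec$degree, breaks = spec$breaks,
                            coefficients = as.numeric(coef)),
                       path, digits = NA, auto_unbox = FALSE)
  invisible(path)
}

#' @rdname write_spline
#' @export
read_spline <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  spec <- knot_spec(obj$breaks, obj$degree)
  coef <- as.numeric(obj$coefficients)
  if (length(coef) != spec$dim)
    stop(sprintf("coefficient vector length %d does not match basis dimension %d",
                 length(coef), spec$dim))
  list(spec = spec, coef = coef)
}
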
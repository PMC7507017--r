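# Independent oracles used across the suite. These deliberately avoid the
# package's Gram-matrix / NNLS code paths: integrals are done on fine grids
# and the constrained fit is reproduced by a log-barrier QP in the original
# coefficient space.

# trapezoid-rule Gram matrix of derivative order l (oracle for penalty_gram)
grid_gram <- function(spec, l, n = 200001L) {
  g <- seq(spec$a, spec$b, length.out = n)
  D <- eval_basis(spec, g, deriv = l)
  h <- diff(g)
  w <- c(h / 2, 0) + c(0, h / 2)  # trapezoid weights
  crossprod(D, w * D)
}

# brute-force shape-constrained penalised LS in b-space via constrOptim,
# with the roughness term integrated on a fine grid (independent quadrature)
brute_force_fit <- function(days, y, spec, l = 1L, alpha = 0.5,
                            w = rep(1, length(days)), n_grid = 20001L) {
  p <- spec$dim
  C <- eval_basis(spec, days)
  Pg <- grid_gram(spec, l, n = n_grid)
  fn <- function(b) {
    alpha * sum(w * (y - drop(C %*% b))^2) +
      (1 - alpha) * drop(crossprod(b, Pg %*% b))
  }
  gr <- function(b) {
    -2 * alpha * drop(crossprod(C, w * (y - drop(C %*% b)))) +
      2 * (1 - alpha) * drop(Pg %*% b)
  }
  # constraints: b1 >= 0 and consecutive differences >= 0
  ui <- rbind(c(1, rep(0, p - 1L)),
              cbind(-diag(p - 1L), 0) + cbind(0, diag(p - 1L)))
  ci <- rep(0, p)
  start <- seq(0.1, 0.2, length.out = p)  # strictly feasible interior point
  out <- stats::constrOptim(start, fn, gr, ui = ui, ci = ci,
                            outer.eps = 1e-10, method = "BFGS",
                            control = list(maxit = 500, reltol = 1e-14))
  out$par
}

# composed trapezoid area under a fitted spline (oracle for exact CGI)
trapz_area <- function(fit, n = 10001L) {
  g <- seq(fit$spec$a, fit$spec$b, length.out = n)
  pracma::trapz(g, predict(fit, g))
}

kader_control <- function() smoothing_control(breaks = c(0, 2, 5, 8, 10))

# Printed continuous-index row for the 32 hypothetical records (one value
# per record A1..H4)
kader_printed_cgi <- c(
  5.447, 8.873, 7.483, 5.862, 7.076, 7.525, 7.979, 8.440,
  7.979, 6.313, 4.621, 2.929, 7.437, 8.551, 7.955, 8.048,
  6.109, 7.076, 7.979, 8.873, 1.512, 3.387, 5.229, 7.082,
  4.750, 5.938, 4.886, 3.269, 1.512, 7.979, 2.203, 8.690)
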
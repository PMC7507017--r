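#' Smoothing configuration for the monotone spline fit
#'
#' Collects the parameters of the penalised least-squares criterion
#' `(1 - alpha) * integral (f^(l))^2 + alpha * sum w_i (y_i - f(t_i))^2`:
#' the spline degree `k`, the penalty derivative order `l`, the break
#' sequence, the smoothness/fidelity tradeoff `alpha` and per-point weights.
#'
#' When `breaks = NULL` the break sequence is resolved from the data domain at
#' fit time: `c(0, 7, 14, 21, 28)` for 28-day experiments, `c(0, 2, 5, 8, 10)`
#' for 10-day experiments, otherwise five equally spaced breaks.
#'
#' @param degree Spline degree `k` (default 5, quintic).
#' @param penalty_order Derivative order `l` penalised in the roughness term
#'   (default 1); must satisfy `penalty_order <= degree - 1`.
#' @param breaks Break sequence, or `NULL` to resolve from the data.
#' @param alpha Tradeoff in `(0, 1)`; larger values favour data fidelity over
#'   smoothness (default 0.5, an even compromise).
#' @param weights Nonnegative per-observation weights, or `NULL` for unit
#'   weights.
#' @return An object of class `"smoothing_control"`.
#' @export
smoothing_control <- function(degree = 5L, penalty_order = 1L, breaks = NULL,
                              alpha = 0.5, weights = NULL) {
  degree <- as.integer(degree)
  penalty_order <- as.integer(penalty_order)
  if (degree < 1L) stop("'degree' must be positive")
  if (penalty_order < 1L || penalty_order > degree)
    stop("'penalty_order' must satisfy 1 <= penalty_order <= degree")
  if (!is.numeric(alpha) || length(alpha) != 1L || alpha <= 0 || alpha >= 1)
    stop("'alpha' must be a single number strictly between 0 and 1")
  if (!is.null(weights)) {
    weights <- as.numeric(weights)
    if (any(weights < 0)) stop("'weights' must be nonnegative")
    if (all(weights == 0)) stop("at least one weight must be positive")
  }
  if (!is.null(breaks)) breaks <- as.numeric(breaks)
  structure(list(degree = degree, penalty_order = penalty_order,
                 breaks = breaks, alpha = alpha, weights = weights),
            class = "smoothing_control")
}

.resolve_breaks <- function(control, days) {
  if (!is.null(control$breaks)) return(control$breaks)
  a <- min(days); b <- max(days)
  if (isTRUE(all.equal(c(a, b), c(0, 28)))) return(c(0, 7, 14, 21, 28))
  if (isTRUE(all.equal(c(a, b), c(0, 10)))) return(c(0, 2, 5, 8, 10))
  seq(a, b, length.out = 5L)
}

#' Solve the shape-constrained penalised least-squares problem
#'
#' Minimises `alpha * sum(w * (y - C b)^2) + (1 - alpha) * t(b) P b` subject
#' to the spline being nonnegative and nondecreasing. Monotonicity is enforced
#' through the sufficient condition that consecutive B-spline coefficients are
#' nondecreasing (the derivative of a degree-`k` spline is a degree-`(k-1)`
#' spline whose coefficients are positive multiples of those differences);
#' nonnegativity through a nonnegative first coefficient. Substituting
#' `b = T g` with `T` the cumulative-sum map and `g >= 0` turns the problem
#' into one canonical nonnegative least-squares (NNLS) system solved by the
#' Lawson–Hanson algorithm.
#'
#' @param C Collocation matrix (basis evaluated at the data days).
#' @param P Penalty Gram matrix from [penalty_gram()].
#' @param y Observed values.
#' @param w Nonnegative weights, one per observation.
#' @param alpha Tradeoff in `(0, 1)`.
#' @return List with the coefficient vector `coef`, the increment vector
#'   `increments` (`g`), the NNLS gradient `gradient` at the solution and the
#'   scaled maximum KKT violation `kkt`.
#' @export
solve_constrained_ls <- function(C, P, y, w = rep(1, length(y)), alpha = 0.5) {
  C <- as.matrix(C); P <- as.matrix(P)
  p <- ncol(C)
  if (nrow(P) != p || ncol(P) != p)
    stop("'P' must be square with size ncol(C)")
  if (length(y) != nrow(C) || length(w) != nrow(C))
    stop("'y' and 'w' must have one entry per row of C")
  if (all(w == 0)) stop("all weights are zero")
  ee <- eigen(P, symmetric = TRUE)
  R <- diag(sqrt(pmax(ee$values, 0)), p) %*% t(ee$vectors)
  Tm <- matrix(0, p, p); Tm[lower.tri(Tm, diag = TRUE)] <- 1
  A <- rbind(sqrt(alpha) * (sqrt(w) * C) %*% Tm,
             sqrt(1 - alpha) * (R %*% Tm))
  z <- c(sqrt(alpha) * sqrt(w) * y, rep(0, p))
  if (max(abs(z)) == 0) {
    g <- rep(0, p)
  } else {
    sol <- pracma::lsqnonneg(A, z)
    g <- sol$x
  }
  grad <- drop(crossprod(A, A %*% g - z))
  scale <- max(abs(crossprod(A, z)), 1)
  kkt <- max(c(abs(grad[g > 0]), -pmin(grad[g <= 0], 0), 0)) / scale
  list(coef = cumsum(g), increments = g, gradient = grad, kkt = kkt)
}

#' Fit the absolute germination distribution function (AGDF)
#'
#' Fits a nonnegative, nondecreasing smoothing spline to cumulative
#' germination data by minimising
#' `(1 - alpha) * integral (f^(l))^2 + alpha * sum w_i (y_i - f(t_i))^2`
#' over the cone of shape-feasible splines (see [solve_constrained_ls()]).
#' The fitted curve is the continuous representation of the germination
#' process; its area is the continuous germination index ([cgi()]).
#'
#' @param x A [germination_record()], a data frame with columns `day` and `y`,
#'   or a numeric vector of observation days (with `y` supplied).
#' @param ... Passed to methods.
#' @return An object of class `"agdf"` with components `coefficients`,
#'   `spec` (the [knot_spec()]), `control`, `data` (days, y, weights),
#'   `fitted.values`, `residuals`, `kkt` and `record` (when fitted from one).
#' @examples
#' rec <- kader_records()[["A1"]]
#' fit <- agdf(rec)
#' cgi(fit)
#' @export
agdf <- function(x, ...) UseMethod("agdf")

#' @rdname agdf
#' @param y Observed values at `x` (default method).
#' @param control A [smoothing_control()].
#' @export
agdf.default <- function(x, y, control = smoothing_control(), ...) {
  days <- as.numeric(x)
  y <- as.numeric(y)
  if (length(days) != length(y)) stop("'x' and 'y' lengths differ")
  if (anyNA(days) || anyNA(y)) stop("missing values in the data")
  if (any(duplicated(days))) stop("duplicate observation days are not allowed")
  o <- order(days); days <- days[o]; y <- y[o]
  if (length(days) < 2L) stop("at least 2 observations are required")
  stopifnot(inherits(control, "smoothing_control"))
  breaks <- .resolve_breaks(control, days)
  spec <- knot_spec(breaks, control$degree)
  eps <- 1e-10 * max(1, abs(spec$b))
  if (any(days < spec$a - eps | days > spec$b + eps))
    stop(sprintf("observation days must lie within the spline domain [%g, %g]",
                 spec$a, spec$b))
  w <- control$weights
  if (is.null(w)) w <- rep(1, length(days))
  if (length(w) != length(days))
    stop("'weights' must have one entry per observation")
  if (sum(w > 0) < 2L) stop("at least 2 observations with positive weight are required")
  C <- eval_basis(spec, days)
  P <- penalty_gram(spec, control$penalty_order)
  sol <- solve_constrained_ls(C, P, y, w, control$alpha)
  fitted <- drop(C %*% sol$coef)
  structure(list(coefficients = sol$coef, increments = sol$increments,
                 spec = spec, control = control,
                 data = list(days = days, y = y, weights = w),
                 fitted.values = fitted, residuals = y - fitted,
                 kkt = sol$kkt, record = NULL, call = match.call()),
            class = "agdf")
}

#' @rdname agdf
#' @export
agdf.germination_record <- function(x, control = smoothing_control(), ...) {
  fit <- agdf.default(x$days, x$cumulative, control = control, ...)
  fit$record <- x
  fit$call <- match.call()
  fit
}

#' @rdname agdf
#' @export
agdf.data.frame <- function(x, control = smoothing_control(), ...) {
  nm <- names(x)
  dcol <- intersect(c("day", "days", "t"), nm)[1L]
  ycol <- intersect(c("y", "cumulative", "value"), nm)[1L]
  if (is.na(dcol) || is.na(ycol))
    stop("data frame must have a day column ('day'/'days'/'t') and a value column ('y'/'cumulative'/'value')")
  agdf.default(x[[dcol]], x[[ycol]], control = control, ...)
}

#' @export
print.agdf <- function(x, digits = 4L, ...) {
  cat("Nondecreasing nonnegative smoothing spline (AGDF)\n")
  if (!is.null(x$record) && nzchar(x$record$accession))
    cat(sprintf("  accession: %s\n", x$record$accession))
  cat(sprintf("  degree %d, penalty order %d, alpha %g, domain [%g, %g]\n",
              x$spec$degree, x$control$penalty_order, x$control$alpha,
              x$spec$a, x$spec$b))
  cat("  coefficients:\n")
  print(round(x$coefficients, digits))
  cat(sprintf("  CGI (area under curve): %s\n", format(cgi(x), digits = digits)))
  invisible(x)
}

#' @export
coef.agdf <- function(object, ...) object$coefficients

#' @export
fitted.agdf <- function(object, ...) object$fitted.values

#' @export
residuals.agdf <- function(object, ...) object$residuals

#' Evaluate a fitted AGDF
#'
#' @param object An [agdf()] fit.
#' @param newdata Evaluation points in the spline domain; defaults to the
#'   observation days.
#' @param deriv Derivative order (0 for the curve itself).
#' @param ... Unused.
#' @return Numeric vector of spline (or derivative) values.
#' @export
predict.agdf <- function(object, newdata = NULL, deriv = 0L, ...) {
  if (is.null(newdata)) newdata <- object$data$days
  drop(eval_basis(object$spec, newdata, deriv) %*% object$coefficients)
}

#' @export
plot.agdf <- function(x, n = 201L, ...) {
  g <- seq(x$spec$a, x$spec$b, length.out = n)
  graphics::plot(g, predict(x, g), type = "l",
                 xlab = "day", ylab = "cumulative germination (proportion)",
                 ylim = c(0, max(1, x$data$y)), ...)
  graphics::points(x$data$days, x$data$y, pch = 16)
  invisible(x)
}

#' @export
summary.agdf <- function(object, ...) {
  g <- seq(object$spec$a, object$spec$b, length.out = 2001L)
  s <- predict(object, g)
  s1 <- predict(object, g, deriv = 1L)
  out <- list(fit = object, cgi = cgi(object),
              min_value = min(s), min_slope = min(s1),
              rss = sum(object$data$weights * object$residuals^2),
              roughness = drop(crossprod(object$coefficients,
                penalty_gram(object$spec, object$control$penalty_order) %*%
                  object$coefficients)))
  class(out) <- "summary.agdf"
  out
}

#' @export
print.summary.agdf <- function(x, digits = 4L, ...) {
  print(x$fit, digits = digits)
  cat(sprintf("  weighted RSS %.4g, roughness %.4g\n", x$rss, x$roughness))
  cat(sprintf("  shape check on 2001-point grid: min s = %.3g, min s' = %.3g\n",
              x$min_value, x$min_slope))
  invisible(x)
}
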
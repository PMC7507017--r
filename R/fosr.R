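#' Function-on-scalar regression of germination curves on a scalar index
#'
#' Fits the functional linear model `y_i(t) = beta0(t) + x_i * beta1(t) +
#' eps_i(t)` where the responses `y_i` are fitted AGDF splines sharing one
#' basis and the covariate `x` is a scalar germination index. Because
#' responses and coefficient functions share the basis, minimising the
#' integrated least-squares criterion reduces exactly to ordinary least
#' squares on the B-spline coefficient matrix; the global coefficient of
#' determination
#' `R2_glob = sum_i ||yhat_i - ybar||^2 / sum_i ||y_i - ybar||^2`
#' is evaluated with exact L2 norms through the basis Gram matrix.
#'
#' A constant covariate (or otherwise rank-deficient design) makes the model
#' singular; the fit is then flagged and the R-squared values are `NA`.
#'
#' @param curves List of [agdf()] fits sharing degree and breaks (at least 3).
#' @param x Numeric covariate, one value per curve; `NA` entries are not
#'   allowed.
#' @param label Optional covariate name used in printing.
#' @return An object of class `"fosr"` with components `coefficients` (2 x p
#'   matrix of B-spline coefficients of `beta0`, `beta1`), `X`, `Y` (N x p
#'   response coefficients), `fitted` (N x p), `residuals`, `spec`, `gram`,
#'   `r2_glob`, `singular`.
#' @examples
#' recs <- kader_records(c("C1", "C2", "C3", "C4"))
#' fits <- lapply(recs, agdf)
#' fosr(fits, sapply(recs, total_germination), label = "TG")$r2_glob  # 1
#' @export
fosr <- function(curves, x, label = deparse1(substitute(x))) {
  label <- paste(as.character(label), collapse = " ")
  if (nchar(label) > 40L) label <- "x"
  stopifnot(is.list(curves), all(vapply(curves, inherits, TRUE, "agdf")))
  N <- length(curves)
  if (N < 3L) stop("at least 3 curves are required")
  x <- as.numeric(x)
  if (length(x) != N) stop("'x' must have one value per curve")
  if (anyNA(x)) stop("missing covariate values are not allowed")
  spec <- curves[[1L]]$spec
  same <- vapply(curves, function(f)
    f$spec$degree == spec$degree &&
      length(f$spec$breaks) == length(spec$breaks) &&
      all(abs(f$spec$breaks - spec$breaks) < 1e-12), TRUE)
  if (!all(same)) stop("all curves must share the same degree and breaks")

  Y <- t(vapply(curves, coef, numeric(spec$dim)))
  X <- cbind(`(Intercept)` = 1, x)
  colnames(X)[2L] <- label
  G <- basis_gram(spec)

  XtX <- crossprod(X)
  singular <- stats::var(x) < 1e-12 || kappa(XtX, exact = TRUE) > 1e12
  if (singular) {
    B <- matrix(NA_real_, 2L, spec$dim)
    fitted <- resid <- matrix(NA_real_, N, spec$dim)
    r2 <- NA_real_
  } else {
    B <- solve(XtX, crossprod(X, Y))
    fitted <- X %*% B
    resid <- Y - fitted
    ybar <- colMeans(Y)
    Dh <- sweep(fitted, 2L, ybar)
    Dy <- sweep(Y, 2L, ybar)
    ssr <- sum(Dh * (Dh %*% G))
    sst <- sum(Dy * (Dy %*% G))
    r2 <- if (sst < 1e-12) NA_real_ else ssr / sst
  }
  rownames(B) <- colnames(X)
  structure(list(coefficients = B, X = X, Y = Y, x = x, label = label,
                 fitted = fitted, residuals = resid, spec = spec, gram = G,
                 r2_glob = r2, singular = singular, call = match.call()),
            class = "fosr")
}

#' @export
print.fosr <- function(x, ...) {
  cat("Function-on-scalar regression of germination curves\n")
  cat(sprintf("  %d curves, covariate '%s', basis dimension %d on [%g, %g]\n",
              nrow(x$Y), x$label, x$spec$dim, x$spec$a, x$spec$b))
  if (x$singular) {
    cat("  model is singular (constant or collinear covariate); R-squared is NA\n")
  } else {
    cat(sprintf("  global R-squared: %.4f\n", x$r2_glob))
  }
  invisible(x)
}

#' @export
coef.fosr <- function(object, ...) object$coefficients

#' @export
fitted.fosr <- function(object, ...) object$fitted

#' @export
residuals.fosr <- function(object, ...) object$residuals

#' Predict germination curves from a fitted functional regression
#'
#' @param object A [fosr()] fit.
#' @param newx Covariate values; defaults to the training covariate.
#' @param t Optional evaluation days; if supplied, returns a matrix of curve
#'   values (rows = covariate values), otherwise the coefficient matrix.
#' @param ... Unused.
#' @export
predict.fosr <- function(object, newx = NULL, t = NULL, ...) {
  if (object$singular) stop("cannot predict from a singular fit")
  if (is.null(newx)) newx <- object$x
  Bc <- cbind(1, as.numeric(newx)) %*% object$coefficients
  if (is.null(t)) return(Bc)
  Bc %*% t(eval_basis(object$spec, t))
}

#' @export
summary.fosr <- function(object, grid_n = 101L, ...) {
  out <- list(fit = object)
  if (!object$singular) {
    g <- seq(object$spec$a, object$spec$b, length.out = grid_n)
    out$r2_t <- r2_pointwise(object, g)
  }
  class(out) <- "summary.fosr"
  out
}

#' @export
print.summary.fosr <- function(x, ...) {
  print(x$fit)
  if (!is.null(x$r2_t)) {
    ok <- x$r2_t$defined
    cat(sprintf("  pointwise R-squared over the domain: min %.3f, median %.3f, max %.3f\n",
                min(x$r2_t$r2[ok]), stats::median(x$r2_t$r2[ok]), max(x$r2_t$r2[ok])))
  }
  invisible(x)
}

#' Pointwise coefficient of determination
#'
#' At each day `t`, `R2(t) = sum_i (yhat_i(t) - ybar(t))^2 /
#' sum_i (y_i(t) - ybar(t))^2` (the explained/total form, which equals
#' `1 - SSE/SST` here because the design includes an intercept). Values are
#' clipped to `[0, 1]` for reporting; points where the curves nearly coincide
#' (`SST(t) < 1e-12`) are flagged undefined.
#'
#' @param fit A non-singular [fosr()] fit.
#' @param t Evaluation days.
#' @return Data frame with columns `t`, `r2` and `defined`.
#' @export
r2_pointwise <- function(fit, t) {
  stopifnot(inherits(fit, "fosr"))
  if (fit$singular) stop("pointwise R-squared is undefined for a singular fit")
  Bt <- eval_basis(fit$spec, t)
  Yh <- fit$fitted %*% t(Bt)
  Yo <- fit$Y %*% t(Bt)
  yb <- colMeans(Yo)
  ssr <- colSums(sweep(Yh, 2L, yb)^2)
  sst <- colSums(sweep(Yo, 2L, yb)^2)
  defined <- sst >= 1e-12
  r2 <- ifelse(defined, pmin(pmax(ssr / sst, 0), 1), NA_real_)
  data.frame(t = as.numeric(t), r2 = r2, defined = defined)
}

#' Global coefficient of determination
#'
#' @param fit A [fosr()] fit.
#' @return `R2_glob`, or `NA` for a singular fit.
#' @export
r2_global <- function(fit) {
  stopifnot(inherits(fit, "fosr"))
  fit$r2_glob
}

#' Score germination indices by functional regression
#'
#' Computes the requested indices for every record, fits the AGDF splines,
#' and regresses the curves on each index in turn, reporting the global
#' R-squared per index (`NA` when the model is singular, e.g. a constant
#' index). Optionally drops zero-germination accessions first — both cohort
#' definitions used in practice (all accessions vs. germinating accessions
#' only) are expressible.
#'
#' @param records List of [germination_record()] objects (at least 3 usable).
#' @param control A [smoothing_control()].
#' @param indices Character vector among `"lt50"`, `"tg"`, `"mgt"`, `"cvg"`,
#'   `"gi"`, `"cgi"`.
#' @param drop_zero_germination Drop records with zero final germination
#'   before fitting.
#' @param period Scoring period for the germination index.
#' @return Data frame with columns `index`, `r2_glob`, `n`, `singular`. The
#'   underlying `fosr` fits are attached as attribute `"fits"`.
#' @examples
#' compare_indices(kader_records(c("C1", "C2", "C3", "C4")))
#' @export
compare_indices <- function(records, control = smoothing_control(),
                            indices = c("lt50", "tg", "mgt", "cvg", "gi", "cgi"),
                            drop_zero_germination = FALSE, period = NULL) {
  indices <- match.arg(indices, several.ok = TRUE)
  if (inherits(records, "germination_record")) records <- list(records)
  if (drop_zero_germination)
    records <- Filter(function(r) total_germination(r) > 0, records)
  if (length(records) < 3L)
    stop("at least 3 usable records are required for the regression stage")
  tab <- germination_indices(records, control = control, period = period)
  fits <- attr(tab, "fits")
  models <- lapply(indices, function(ix) {
    xv <- tab[[ix]]
    if (anyNA(xv)) return(NULL)  # undefined index for some accession
    fosr(fits, xv, label = toupper(ix))
  })
  names(models) <- indices
  out <- data.frame(
    index = toupper(indices),
    r2_glob = vapply(models, function(m) if (is.null(m)) NA_real_ else m$r2_glob, 0),
    n = length(records),
    singular = vapply(models, function(m) is.null(m) || m$singular, TRUE),
    stringsAsFactors = FALSE)
  rownames(out) <- NULL
  attr(out, "fits") <- models
  out
}
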
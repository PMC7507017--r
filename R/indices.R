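#' Classical germination indices
#'
#' Scalar summaries of a discrete germination record. For a record with
#' per-day germinated counts `n_i` on days `t_i` (see [per_day_counts()]):
#'
#' * `total_germination`: final cumulative proportion of planted seeds, in
#'   `[0, 1]`.
#' * `mean_germination_time`: count-weighted mean day,
#'   `sum(n_i * t_i) / sum(n_i)` (days); lower is faster.
#' * `coefficient_of_velocity`: `100 * sum(n_i) / sum(n_i * t_i)`
#'   (percent per day); higher is faster.
#' * `germination_index`: weighted count score
#'   `sum((T - t_i + 1) * n_i)` over a `period` of `T` days, giving maximum
#'   weight to the first day. Counts are in the record's seed units.
#' * `lt50`: first observation day at which cumulative germination reaches
#'   half of its *final* level; with `interpolate = TRUE`, the linearly
#'   interpolated crossing time instead.
#'
#' Indices that divide by the total germinated count are undefined for a
#' record with zero germination and are returned as `NA`; the germination
#' index is 0 exactly when nothing germinated.
#'
#' @param record A [germination_record()].
#' @return A single numeric value (or `NA` when undefined).
#' @seealso [cgi()] for the continuous index, [germination_indices()] for the
#'   batch table.
#' @export
total_germination <- function(record) {
  stopifnot(inherits(record, "germination_record"))
  record$cumulative[length(record$cumulative)]
}

#' @rdname total_germination
#' @export
mean_germination_time <- function(record) {
  n <- per_day_counts(record)
  if (sum(n) <= 0) return(NA_real_)
  t <- as.numeric(names(n))
  sum(n * t) / sum(n)
}

#' @rdname total_germination
#' @export
coefficient_of_velocity <- function(record) {
  n <- per_day_counts(record)
  if (sum(n) <= 0) return(NA_real_)
  t <- as.numeric(names(n))
  100 * sum(n) / sum(n * t)
}

#' @rdname total_germination
#' @param period Length `T` of the scoring period in days; defaults to the
#'   last observation day.
#' @export
germination_index <- function(record, period = max(record$days)) {
  n <- per_day_counts(record)
  t <- as.numeric(names(n))
  if (any(t > period))
    stop(sprintf("observation day %g exceeds the scoring period of %g days",
                 max(t), period))
  sum((period - t + 1) * n)
}

#' @rdname total_germination
#' @param interpolate Linearly interpolate the crossing time instead of
#'   returning the first observation day at or past the threshold.
#' @export
lt50 <- function(record, interpolate = FALSE) {
  stopifnot(inherits(record, "germination_record"))
  y <- record$cumulative
  final <- y[length(y)]
  if (final <= 0) return(NA_real_)
  thr <- final / 2
  i <- which(y >= thr)[1L]
  if (!interpolate || i == 1L || y[i] == thr) return(record$days[i])
  t0 <- record$days[i - 1L]; t1 <- record$days[i]
  y0 <- y[i - 1L]; y1 <- y[i]
  t0 + (thr - y0) / (y1 - y0) * (t1 - t0)
}

#' Continuous germination index (CGI)
#'
#' The area under the fitted AGDF over its domain,
#' `CGI = integral from a to b of s(t) dt`, computed by default with the exact
#' B-spline antiderivative identity (a composed-trapezoid evaluation is
#' available as a cross-check). Because the spline is nonnegative,
#' nondecreasing and fitted to proportions, the CGI lies in `[0, b - a]`; it
#' grows with both the final germination proportion and the germination
#' speed.
#'
#' @param fit An [agdf()] fit.
#' @param method `"exact"` or `"trapezoid"` (see [integrate_spline()]).
#' @param ... Passed to [integrate_spline()].
#' @return The index, in days times proportion.
#' @export
cgi <- function(fit, method = c("exact", "trapezoid"), ...) {
  stopifnot(inherits(fit, "agdf"))
  integrate_spline(coef(fit), fit$spec, method = match.arg(method), ...)
}

#' Index table for a set of accessions
#'
#' Computes all six indices (LT50, TG, MGT, CVG, GI, CGI) for each record,
#' fitting the AGDF with the given control for the CGI column. Undefined
#' indices (zero-germination records) are reported as `NA`.
#'
#' @param records A list of [germination_record()] objects (or a single one).
#' @param control A [smoothing_control()] used for the spline fits.
#' @param period Scoring period for the germination index; defaults to each
#'   record's last observation day.
#' @return A data frame with columns `accession`, `lt50`, `tg`, `mgt`, `cvg`,
#'   `gi`, `cgi`, one row per record. The fitted `agdf` objects are attached
#'   as attribute `"fits"`.
#' @export
germination_indices <- function(records, control = smoothing_control(),
                                period = NULL) {
  if (inherits(records, "germination_record")) records <- list(records)
  stopifnot(all(vapply(records, inherits, TRUE, "germination_record")))
  fits <- lapply(records, agdf, control = control)
  out <- data.frame(
    accession = vapply(records, function(r) r$accession, ""),
    lt50 = vapply(records, lt50, 0),
    tg = vapply(records, total_germination, 0),
    mgt = vapply(records, mean_germination_time, 0),
    cvg = vapply(records, coefficient_of_velocity, 0),
    gi = vapply(records, function(r)
      germination_index(r, if (is.null(period)) max(r$days) else period), 0),
    cgi = vapply(fits, cgi, 0),
    stringsAsFactors = FALSE)
  attr(out, "fits") <- fits
  out
}
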
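#' A single accession's germination record
#'
#' Stores the observation days, the cumulative proportion of planted seeds
#' germinated by each day, and the number of seeds planted. The record is the
#' discrete raw input to the spline smoother and to the classical indices.
#'
#' Scoring conventionally starts the day after planting, so a day-zero
#' observation with zero germination is prepended when absent
#' (`anchor = TRUE`, the default).
#'
#' @param days Strictly increasing nonnegative observation days.
#' @param cumulative Cumulative germinated proportions in `[0, 1]`,
#'   nondecreasing, one per day.
#' @param total_seeds Positive integer, seeds planted.
#' @param accession Accession label.
#' @param anchor Prepend `(t = 0, y = 0)` when day 0 is absent.
#' @return An object of class `"germination_record"`.
#' @examples
#' r <- germination_record(1:10, cumsum(c(0, 0, 0, 15, 80, 0, 0, 0, 0, 0)) / 100,
#'                         total_seeds = 100, accession = "A1")
#' total_germination(r)
#' @export
germination_record <- function(days, cumulative, total_seeds,
                               accession = "", anchor = TRUE) {
  days <- as.numeric(days)
  cumulative <- as.numeric(cumulative)
  if (length(days) != length(cumulative))
    stop("'days' and 'cumulative' must have the same length")
  if (anyNA(days) || anyNA(cumulative))
    stop("missing values are not allowed in a germination record")
  if (any(days < 0)) stop("'days' must be nonnegative")
  d <- diff(days)
  if (any(d == 0)) stop("duplicate observation days are not allowed")
  if (any(d < 0)) stop("'days' must be strictly increasing")
  if (anchor && days[1L] > 0) {
    days <- c(0, days)
    cumulative <- c(0, cumulative)
  }
  dy <- diff(cumulative)
  if (any(dy < -1e-12)) {
    i <- which(dy < -1e-12)[1L]
    stop(sprintf("cumulative germination decreases between day %g (%g) and day %g (%g)",
                 days[i], cumulative[i], days[i + 1L], cumulative[i + 1L]))
  }
  if (any(cumulative < -1e-12) || any(cumulative > 1 + 1e-9))
    stop("cumulative proportions must lie in [0, 1]")
  total_seeds <- as.integer(total_seeds)
  if (length(total_seeds) != 1L || is.na(total_seeds) || total_seeds < 1L)
    stop("'total_seeds' must be a single positive integer")
  structure(list(accession = as.character(accession), days = days,
                 cumulative = pmin(pmax(cumulative, 0), 1),
                 total_seeds = total_seeds),
            class = "germination_record")
}

#' @export
print.germination_record <- function(x, ...) {
  cat(sprintf("Germination record '%s': %d seeds, %d observation days on [%g, %g], final germination %.1f%%\n",
              x$accession, x$total_seeds, length(x$days),
              min(x$days), max(x$days), 100 * x$cumulative[length(x$cumulative)]))
  invisible(x)
}

#' Per-day germinated seed counts
#'
#' First differences of the cumulative record, in seed units
#' (`total_seeds * proportion`). Day 0 is dropped; the counts sum to the final
#' cumulative count.
#'
#' @param record A [germination_record()].
#' @return Numeric vector of counts named by observation day.
#' @export
per_day_counts <- function(record) {
  stopifnot(inherits(record, "germination_record"))
  n <- diff(record$cumulative) * record$total_seeds
  names(n) <- record$days[-1L]
  n
}
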
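#' Hill-type cumulative germination curve
#'
#' Expected cumulative germinated proportion
#' `p(t) = tg_max * t^shape / (half_time^shape + t^shape)`: a sigmoid rising
#' from 0 to the plateau `tg_max`, reaching half the plateau at `half_time`.
#' Hill curves are a standard parametric stand-in for germination time
#' courses and drive the package's synthetic-data generator.
#'
#' @param t Days (nonnegative).
#' @param tg_max Plateau proportion in `(0, 1]` (viable fraction).
#' @param half_time Day at which half the plateau is reached (> 0).
#' @param shape Hill exponent (> 1); larger is steeper.
#' @return Expected cumulative proportions.
#' @export
hill_curve <- function(t, tg_max, half_time, shape) {
  stopifnot(tg_max >= 0, tg_max <= 1, half_time > 0, shape > 1)
  tg_max * t^shape / (half_time^shape + t^shape)
}

#' Parameter set for one simulated accession
#'
#' @param tg_max,half_time,shape Hill-curve parameters, see [hill_curve()].
#'   `tg_max = 0` gives an all-zero (fully dormant) accession.
#' @param total_seeds Seeds planted (default 25, a typical assay size).
#' @return A list of class `"hill_params"`.
#' @export
hill_params <- function(tg_max, half_time, shape = 4, total_seeds = 25L) {
  if (tg_max < 0 || tg_max > 1) stop("'tg_max' must lie in [0, 1]")
  if (half_time <= 0) stop("'half_time' must be positive")
  if (shape <= 1) stop("'shape' must exceed 1")
  total_seeds <- as.integer(total_seeds)
  if (total_seeds < 1L) stop("'total_seeds' must be positive")
  structure(list(tg_max = tg_max, half_time = half_time, shape = shape,
                 total_seeds = total_seeds), class = "hill_params")
}

#' Simulate a cohort of germination records
#'
#' Draws daily germination counts from Hill-type cumulative curves with
#' binomial sampling noise. Increments are drawn sequentially from the seeds
#' not yet germinated with the conditional hazard
#' `(p(t_j) - p(t_{j-1})) / (1 - p(t_{j-1}))`, so the cumulative count at day
#' `t` is exactly `Binomial(total_seeds, p(t))` while the record is
#' nondecreasing by construction.
#'
#' @param params A single [hill_params()] or a list of them, one per
#'   accession.
#' @param days Integer observation days starting at 1.
#' @param seed Optional integer seed for reproducibility.
#' @param accessions Optional character labels.
#' @return A named list of [germination_record()] objects.
#' @examples
#' cohort <- simulate_cohort(list(hill_params(0.9, 3), hill_params(0.9, 6)),
#'                           days = 1:10, seed = 1)
#' @export
simulate_cohort <- function(params, days = 1:28, seed = NULL,
                            accessions = NULL) {
  if (inherits(params, "hill_params")) params <- list(params)
  stopifnot(all(vapply(params, inherits, TRUE, "hill_params")))
  days <- as.numeric(days)
  if (days[1L] < 1 || any(diff(days) <= 0))
    stop("'days' must be increasing and start at day 1 or later")
  if (!is.null(seed)) set.seed(seed)
  if (is.null(accessions)) accessions <- paste0("sim", seq_along(params))
  recs <- lapply(seq_along(params), function(i) {
    pp <- params[[i]]
    p <- hill_curve(days, pp$tg_max, pp$half_time, pp$shape)
    N <- pp$total_seeds
    cum <- numeric(length(days))
    germinated <- 0L
    p_prev <- 0
    for (j in seq_along(days)) {
      haz <- if (p_prev >= 1) 0 else (p[j] - p_prev) / (1 - p_prev)
      haz <- min(max(haz, 0), 1)
      germinated <- germinated + stats::rbinom(1L, N - germinated, haz)
      cum[j] <- germinated
      p_prev <- p[j]
    }
    germination_record(days, cum / N, total_seeds = N,
                       accession = accessions[i])
  })
  names(recs) <- accessions
  recs
}
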
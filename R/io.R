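#' Read germination records from CSV
#'
#' Two layouts are supported. *Wide*: one row per accession with columns
#' `accession`, `total_seeds`, then one column per observation day (named
#' `day_1`, `day_2`, ... or plain numbers). *Long*: columns `accession`,
#' `day`, `count` plus `total_seeds`. Counts may be per-day increments or
#' cumulative, in seed counts or percent of planted seeds; missing values are
#' rejected rather than imputed, and a cumulative decrease is an error naming
#' the offending row and day.
#'
#' @param path CSV file path.
#' @param mode `"per-day"` (increments) or `"cumulative"`.
#' @param units `"count"` (seeds) or `"percent"` (percent of planted seeds).
#' @param layout `"wide"` or `"long"`.
#' @return A named list of [germination_record()] objects.
#' @export
read_germination <- function(path, mode = c("per-day", "cumulative"),
                             units = c("count", "percent"),
                             layout = c("wide", "long")) {
  mode <- match.arg(mode); units <- match.arg(units)
  layout <- match.arg(layout)
  tab <- utils::read.csv(path, check.names = FALSE, stringsAsFactors = FALSE)
  if (layout == "long") {
    need <- c("accession", "day", "count", "total_seeds")
    if (!all(need %in% names(tab)))
      stop("long layout requires columns: ", paste(need, collapse = ", "))
    sp <- split(tab, tab$accession)
    recs <- lapply(sp, function(d) {
      d <- d[order(d$day), ]
      .build_record(d$accession[1L], d$day, d$count, d$total_seeds[1L],
                    mode, units)
    })
    return(recs[unique(tab$accession)])
  }
  if (!all(c("accession", "total_seeds") %in% names(tab)))
    stop("wide layout requires columns 'accession' and 'total_seeds'")
  daycols <- setdiff(names(tab), c("accession", "total_seeds"))
  days <- suppressWarnings(as.numeric(sub("^day[_. ]?", "", daycols)))
  if (anyNA(days)) stop("day columns must be named like 'day_1', 'day_2', ...")
  o <- order(days)
  recs <- lapply(seq_len(nrow(tab)), function(i)
    .build_record(tab$accession[i], days[o],
                  as.numeric(tab[i, daycols[o]]), tab$total_seeds[i],
                  mode, units))
  names(recs) <- tab$accession
  recs
}

.build_record <- function(accession, days, values, total_seeds, mode, units) {
  if (anyNA(values))
    stop(sprintf("missing value in record '%s'; imputation is not supported",
                 accession))
  denom <- if (units == "percent") 100 else as.numeric(total_seeds)
  y <- values / denom
  if (mode == "per-day") {
    if (any(y < 0))
      stop(sprintf("negative per-day count in record '%s'", accession))
    y <- cumsum(y)
  } else if (any(diff(y) < -1e-12)) {
    i <- which(diff(y) < -1e-12)[1L]
    stop(sprintf("record '%s': cumulative count decreases at day %g",
                 accession, days[i + 1L]))
  }
  germination_record(days, y, total_seeds = total_seeds,
                     accession = accession)
}

#' Write germination records to a wide CSV
#'
#' Inverse of [read_germination()] (wide layout). Numbers are formatted with
#' `%.6g` so repeated runs produce byte-identical files.
#'
#' @param records Named list of [germination_record()] objects sharing one
#'   day grid.
#' @param path Output path.
#' @inheritParams read_germination
#' @export
write_germination <- function(records, path, mode = c("per-day", "cumulative"),
                              units = c("count", "percent")) {
  mode <- match.arg(mode); units <- match.arg(units)
  if (inherits(records, "germination_record")) records <- list(records)
  days <- records[[1L]]$days[-1L]
  rows <- vapply(records, function(r) {
    if (length(r$days) != length(records[[1L]]$days) ||
        any(r$days != records[[1L]]$days))
      stop("all records must share one observation-day grid")
    y <- r$cumulative
    v <- if (mode == "per-day") diff(y) else y[-1L]
    v * (if (units == "percent") 100 else r$total_seeds)
  }, numeric(length(days)))
  tab <- data.frame(
    accession = vapply(records, function(r) r$accession, ""),
    total_seeds = vapply(records, function(r) r$total_seeds, 1L),
    t(matrix(sprintf("%.6g", rows), nrow = length(days))),
    stringsAsFactors = FALSE, check.names = FALSE)
  names(tab)[-(1:2)] <- paste0("day_", days)
  utils::write.csv(tab, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read a smoothing configuration file
#'
#' Accepts YAML or JSON with fields `degree`, `penalty_order`, `breaks`,
#' `alpha` and optionally `weights`; omitted fields keep the
#' [smoothing_control()] defaults.
#'
#' @param path Configuration file path (`.yaml`, `.yml` or `.json`).
#' @return A [smoothing_control()].
#' @export
read_smoothing_config <- function(path) {
  cfg <- if (grepl("\\.json$", path, ignore.case = TRUE))
    jsonlite::read_json(path, simplifyVector = TRUE)
  else yaml::read_yaml(path)
  known <- c("degree", "penalty_order", "breaks", "alpha", "weights")
  extra <- setdiff(names(cfg), known)
  if (length(extra)) warning("ignoring unknown config fields: ",
                             paste(extra, collapse = ", "))
  args <- cfg[intersect(names(cfg), known)]
  do.call(smoothing_control, args)
}

#' Run the full germination analysis pipeline
#'
#' Fits the AGDF spline per accession, tabulates the six indices, and (when
#' at least 3 records are available) scores the indices by function-on-scalar
#' regression.
#'
#' @inheritParams compare_indices
#' @param quiet Suppress stage messages.
#' @return List with elements `fits` (agdf objects), `indices` (data frame),
#'   and `comparison` (data frame, or `NULL` when the regression stage was
#'   skipped).
#' @export
run_pipeline <- function(records, control = smoothing_control(),
                         indices = c("lt50", "tg", "mgt", "cvg", "gi", "cgi"),
                         drop_zero_germination = FALSE, period = NULL,
                         quiet = FALSE) {
  if (inherits(records, "germination_record")) records <- list(records)
  if (length(records) < 1L) stop("at least one record is required")
  say <- function(...) if (!quiet) message(sprintf(...))
  if (drop_zero_germination) {
    n0 <- length(records)
    records <- Filter(function(r) total_germination(r) > 0, records)
    say("dropped %d zero-germination accession(s), %d remain",
        n0 - length(records), length(records))
  }
  t0 <- proc.time()[3L]
  tab <- germination_indices(records, control = control, period = period)
  say("smoothed %d accession(s) and computed indices in %.2fs",
      length(records), proc.time()[3L] - t0)
  comparison <- NULL
  if (length(records) >= 3L) {
    t0 <- proc.time()[3L]
    comparison <- compare_indices(records, control = control,
                                  indices = indices, period = period)
    if (any(comparison$singular))
      say("singular regression model(s): %s",
          paste(comparison$index[comparison$singular], collapse = ", "))
    say("functional regression stage in %.2fs", proc.time()[3L] - t0)
  } else {
    warning("fewer than 3 records: functional regression stage skipped")
  }
  list(fits = attr(tab, "fits"), indices = tab, comparison = comparison)
}

#' Load a published B-spline coefficient table
#'
#' Reconstructs fitted AGDF splines from a CSV of B-spline coefficients (one
#' accession per row), such as the supplementary coefficient tables
#' distributed with germination studies. Coefficient columns are matched by
#' count against the basis dimension (columns named `b1` ... `bp` are
#' preferred; otherwise the first `p` numeric non-metadata columns are used);
#' extra metadata columns are tolerated. When a `CGI` column is present the
#' recomputed area under each spline is checked against it.
#'
#' @param path CSV path.
#' @param breaks Break sequence of the publishing basis (default
#'   `c(0, 7, 14, 21, 28)`, the 28-day assay layout).
#' @param degree Spline degree (default 5).
#' @param tol Tolerance for the CGI cross-check.
#' @return List with `splines` (list of `agdf`-like objects with
#'   `coefficients` and `spec`), `cgi` (recomputed values) and `table` (the
#'   raw data frame).
#' @export
load_appendix_coefficients <- function(path, breaks = c(0, 7, 14, 21, 28),
                                       degree = 5L, tol = 1e-3) {
  spec <- knot_spec(breaks, degree)
  tab <- utils::read.csv(path, check.names = FALSE, stringsAsFactors = FALSE)
  p <- spec$dim
  bnames <- paste0("b", seq_len(p))
  if (all(bnames %in% names(tab))) {
    cols <- bnames
  } else {
    num <- names(tab)[vapply(tab, is.numeric, TRUE)]
    num <- setdiff(num, c("CGI", "cgi", "LT50", "TG", "MGT", "CVG", "GI",
                          "lt50", "tg", "mgt", "cvg", "gi"))
    if (length(num) < p)
      stop(sprintf("expected %d coefficient columns for the %d-dimensional basis, found %d",
                   p, p, length(num)))
    cols <- num[seq_len(p)]
  }
  Bm <- as.matrix(tab[, cols])
  splines <- lapply(seq_len(nrow(Bm)), function(i) {
    b <- as.numeric(Bm[i, ])
    structure(list(coefficients = b, spec = spec,
                   control = smoothing_control(degree = degree,
                                               breaks = breaks),
                   data = NULL, fitted.values = NULL, residuals = NULL,
                   kkt = NA_real_, record = NULL),
              class = "agdf")
  })
  cgis <- vapply(splines, function(f) integrate_spline(f$coefficients, spec), 0)
  cgicol <- intersect(c("CGI", "cgi"), names(tab))
  if (length(cgicol)) {
    dev <- max(abs(cgis - tab[[cgicol[1L]]]))
    if (dev > tol)
      warning(sprintf("recomputed CGI deviates from the file's CGI column by up to %.4g", dev))
  }
  list(splines = splines, cgi = cgis, table = tab)
}

#' Write an index table to CSV
#'
#' One row per accession with columns `accession, lt50, tg, mgt, cvg, gi,
#' cgi`; undefined indices become empty fields and numbers use a fixed
#' `%.6g` format so outputs are byte-reproducible.
#'
#' @param indices Data frame from [germination_indices()].
#' @param path Output path.
#' @export
write_indices <- function(indices, path) {
  out <- indices
  for (cn in setdiff(names(out), "accession"))
    out[[cn]] <- ifelse(is.na(out[[cn]]), "", sprintf("%.6g", out[[cn]]))
  utils::write.csv(out, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
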
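#' Kader's hypothetical germination scenarios
#'
#' The classical benchmark of 8 germination scenarios (A-H) times 4 seed
#' populations (sets 1-4), each scoring 100 planted seeds daily over a 10-day
#' period. The scenarios span different germination speeds, spreads, onsets
#' and final proportions, and are the standard desk-scale test bed for
#' germination indices. Per-day percentages are stored to the printed one
#' decimal; sets built from thirds of 95 (31.6 a day for three days) total
#' 94.8 rather than 95, and no renormalisation is applied.
#'
#' @param ids Optional character vector of record ids (e.g. `"A1"`, `"C3"`)
#'   to subset; default all 32.
#' @return A named list of 32 [germination_record()] objects with ids
#'   `"A1"` ... `"H4"`, each with a day-0 zero anchor.
#' @examples
#' recs <- kader_records()
#' per_day_counts(recs[["A1"]])  # 15 seeds on day 4, 80 on day 5
#' @export
kader_records <- function(ids = NULL) {
  perday <- matrix(c(
    # A1..A4      B1..B4              C1..C4              D1..D4
    0, 95, 10, 0,  19, 23.7, 31.6, 47.5,  31.6, 25, 18.3, 11.6,  10, 70, 10, 15,
    # E1..E4             F1..F4       G1..G4              H1..H4
    13.5, 19, 31.6, 95,  0, 0, 0, 0,  9.5, 18.7, 27.5, 35,  0, 31.6, 0, 80,

    0, 0, 20, 0,   19, 23.7, 31.6, 47.5,  31.6, 25, 18.3, 11.6,  15, 15, 70, 70,
    13.5, 19, 31.6, 0,   0, 0, 0, 31.6,  9.5, 18.7, 27.5, 0,   0, 31.6, 0, 10,

    0, 0, 65, 15,  19, 23.7, 31.6, 0,     31.6, 25, 18.3, 11.6,  70, 10, 15, 10,
    13.5, 19, 31.6, 0,   0, 0, 0, 31.6,  9.5, 18.7, 0, 0,     0, 31.6, 0, 5,

    15, 0, 0, 35,  19, 23.7, 0, 0,        0, 0, 0, 0,            0, 0, 0, 0,
    13.5, 19, 0, 0,      0, 0, 31.6, 31.6, 9.5, 18.7, 0, 0,    0, 0, 0, 0,

    80, 0, 0, 45,  19, 0, 0, 0,           0, 0, 0, 0,            0, 0, 0, 0,
    13.5, 19, 0, 0,      0, 0, 31.6, 0,   9.5, 0, 0, 0,        0, 0, 0, 0,

    0, 0, 0, 0,    0, 0, 0, 0,            0, 0, 0, 0,            0, 0, 0, 0,
    13.5, 0, 0, 0,       0, 31.6, 31.6, 0, 9.5, 0, 0, 0,       0, 0, 0, 0,

    0, 0, 0, 0,    0, 0, 0, 0,            0, 0, 0, 0,            0, 0, 0, 0,
    13.5, 0, 0, 0,       0, 31.6, 0, 0,   9.5, 0, 0, 0,        0, 0, 0, 0,

    0, 0, 0, 0,    0, 0, 0, 0,            0, 0, 0, 0,            0, 0, 0, 0,
    0, 0, 0, 0,          31.6, 31.6, 0, 0, 9.5, 0, 0, 0,       31.6, 0, 80, 0,

    0, 0, 0, 0,    0, 0, 0, 0,            0, 0, 0, 0,            0, 0, 0, 0,
    0, 0, 0, 0,          31.6, 0, 0, 0,   9.5, 0, 0, 0,        31.6, 0, 10, 0,

    0, 0, 0, 0,    0, 0, 0, 0,            0, 0, 0, 0,            0, 0, 0, 0,
    0, 0, 0, 0,          31.6, 0, 0, 0,   9.5, 0, 0, 0,        31.6, 0, 5, 0
  ), nrow = 10L, byrow = TRUE)
  all_ids <- paste0(rep(LETTERS[1:8], each = 4L), rep(1:4, 8L))
  colnames(perday) <- all_ids
  recs <- lapply(all_ids, function(id)
    germination_record(days = 1:10,
                       cumulative = cumsum(perday[, id]) / 100,
                       total_seeds = 100L, accession = id))
  names(recs) <- all_ids
  if (!is.null(ids)) {
    if (!all(ids %in% all_ids)) stop("unknown record id(s)")
    recs <- recs[ids]
  }
  recs
}

#' @rdname kader_records
#' @return `kader_per_day()` returns the raw 10 x 32 per-day percentage
#'   matrix (rows = days 1-10, columns = record ids).
#' @export
kader_per_day <- function() {
  recs <- kader_records()
  sapply(recs, function(r) unname(per_day_counts(r)))
}
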
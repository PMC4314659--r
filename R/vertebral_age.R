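#' Direct age from a vertebral band-pair count
#'
#' Converts a consensus vertebral band-pair count to an age in years under the
#' winter deposition schedule assumed for these coastal carcharhinids:
#' the birthmark forms at (or shortly after) parturition, the second band
#' forms six months later during the first winter, and each subsequent band is
#' annual. Under those assumptions a shark with `n` band pairs is `n - 1.5`
#' years old.
#'
#' @param count Integer band-pair count (vectorised). Must be at least 2: the
#'   deposition schedule implies every post-first-winter shark carries the
#'   birth band plus the first-winter band.
#' @return Age in years (`count - 1.5`).
#' @examples
#' direct_age(20) # 18.5
#' direct_age(22) # 20.5
#' @seealso [expected_band_count()] for the inverse, [band_consensus()]
#' @export
direct_age <- function(count) {
  if (!is.numeric(count) || any(!is.finite(count)) || any(count != round(count)))
    stop("'count' must be whole band-pair counts")
  if (any(count < 2))
    stop("band-pair count below 2: deposition schedule implies at least the ",
         "birth band plus the first-winter band")
  count - 1.5
}

#' Expected band-pair count at a given age
#'
#' Inverse of the band-deposition schedule, used by the simulator to assign
#' true band counts: one band (the birthmark) from birth, a second at the
#' first winter (age 0.5 under winter-aligned births), then one per year.
#' The band is counted from the instant of its winter, so
#' `direct_age(expected_band_count(a)) == a` exactly at winter-aligned ages
#' `a = 0.5, 1.5, 2.5, ...`.
#'
#' @param age True age in years (vectorised), non-negative.
#' @return Integer band-pair count: 1 for `age` in `[0, 0.5)`, else
#'   `2 + floor(age - 0.5)`.
#' @examples
#' expected_band_count(18.5) # 20
#' expected_band_count(0.25) # 1
#' @export
expected_band_count <- function(age) {
  if (!is.numeric(age) || any(!is.finite(age))) stop("'age' must be finite")
  if (any(age < 0)) stop("negative age")
  ifelse(age < 0.5, 1L, 2L + as.integer(floor(age - 0.5)))
}

#' Consensus of independent reader band counts
#'
#' Band counts are accepted only on unanimity among readers: in practice
#' disagreeing readers re-read sections until they agree, so a disagreement in
#' the data means no consensus was recorded. No averaging or majority rule is
#' applied.
#'
#' @param reader_counts Integer vector of per-reader band-pair counts
#'   (length >= 1).
#' @return A list with `agreed` (logical) and `count` (the unanimous count, or
#'   `NA` when unresolved).
#' @examples
#' band_consensus(c(20, 20, 20)) # agreed, 20
#' band_consensus(c(20, 21, 20)) # unresolved
#' @export
band_consensus <- function(reader_counts) {
  if (length(reader_counts) == 0L) stop("no reader counts supplied")
  if (!is.numeric(reader_counts) || any(!is.finite(reader_counts)))
    stop("reader counts must be finite numbers")
  if (length(unique(reader_counts)) == 1L)
    list(agreed = TRUE, count = as.integer(reader_counts[1]))
  else
    list(agreed = FALSE, count = NA_integer_)
}

#' Consensus band counts per shark from a reader table
#'
#' Applies [band_consensus()] to each tag's reader counts. Sharks whose
#' readers disagree get `NA` (flagged in the returned table) and contribute no
#' direct age downstream.
#'
#' @param band_counts Data frame with columns `tag_id`, `reader_id`, `count`
#'   (one row per reader per shark), e.g. from [read_band_counts()].
#' @return Data frame with columns `tag_id`, `count` (consensus or `NA`),
#'   `agreed`, `n_readers`.
#' @export
consensus_band_counts <- function(band_counts) {
  stopifnot(is.data.frame(band_counts),
            all(c("tag_id", "count") %in% names(band_counts)))
  ids <- unique(band_counts$tag_id)
  rows <- lapply(ids, function(id) {
    cnts <- band_counts$count[band_counts$tag_id == id]
    cns <- band_consensus(cnts)
    data.frame(tag_id = id, count = cns$count, agreed = cns$agreed,
               n_readers = length(cnts), stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}
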
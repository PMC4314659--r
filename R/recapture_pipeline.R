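#' Convert days at liberty to years
#'
#' Uses the fisheries convention of 365.25 days per year, which reproduces all
#' printed year values in long-term shark recapture tables once rounded to one
#' decimal. The value returned is unrounded; the reporting layer rounds.
#'
#' @param days Integer days at liberty (vectorised), strictly positive.
#' @return Years at liberty.
#' @examples
#' years_at_liberty(5098) # 13.957...
#' @export
years_at_liberty <- function(days) {
  if (!is.numeric(days) || any(!is.finite(days))) stop("'days' must be finite")
  if (any(days <= 0)) stop("days at liberty must be positive")
  days / 365.25
}

#' Annualised growth rate at liberty
#'
#' Growth between tagging and recapture divided by years at liberty, in
#' mm/year, unrounded. Negative growth (recapture length below tagging length,
#' possible with angler-estimated measurements) is permitted here; the
#' pipeline flags such records but keeps them.
#'
#' @param growth_mm Growth in mm (recapture FL minus tagging FL), vectorised.
#' @param years Years at liberty, strictly positive.
#' @return Growth rate in mm/year.
#' @examples
#' annual_growth_rate(28, 4438 / 365.25) # 2.304... (reports as 2.3)
#' @export
annual_growth_rate <- function(growth_mm, years) {
  if (!is.numeric(growth_mm) || !is.numeric(years)) stop("numeric inputs required")
  if (any(!is.finite(years)) || any(years <= 0))
    stop("years at liberty must be positive")
  growth_mm / years
}

sex_levels_tag <- c("female", "male", "unknown")
quality_levels <- c("measured", "angler_estimate")

#' Read tagging-study CSV inputs
#'
#' Readers for the three flat files of a tagging study. Expected columns:
#' * `tags.csv`: `tag_id, species, sex, fl_tag_mm, date_tagged, quality`
#' * `recaptures.csv`: `tag_id, date_recaptured, days_at_liberty, fl_recap_mm,
#'   quality` (optional `band_count`)
#' * `band_counts.csv`: `tag_id, reader_id, count`
#'
#' Dates are ISO-8601 (`YYYY-MM-DD`) or blank; blank cells become `NA`.
#' Structural problems (missing columns, non-positive lengths, duplicate tag
#' ids) are caught by [validate_inputs()].
#'
#' @param path CSV file path.
#' @return A data frame.
#' @name read_tagging_data
#' @export
read_tags <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE, na.strings = c("NA", ""))
  need <- c("tag_id", "species", "sex", "fl_tag_mm", "quality")
  miss <- setdiff(need, names(df))
  if (length(miss)) stop("tags file missing column(s): ", paste(miss, collapse = ", "))
  if (!"date_tagged" %in% names(df)) df$date_tagged <- NA_character_
  df$tag_id <- as.character(df$tag_id)
  df
}

#' @rdname read_tagging_data
#' @export
read_recaptures <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE, na.strings = c("NA", ""))
  need <- c("tag_id")
  miss <- setdiff(need, names(df))
  if (length(miss)) stop("recaptures file missing column(s): ", paste(miss, collapse = ", "))
  for (col in c("date_recaptured", "quality"))
    if (!col %in% names(df)) df[[col]] <- NA_character_
  for (col in c("days_at_liberty", "fl_recap_mm"))
    if (!col %in% names(df)) df[[col]] <- NA_real_
  df$tag_id <- as.character(df$tag_id)
  df
}

#' @rdname read_tagging_data
#' @export
read_band_counts <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE, na.strings = c("NA", ""))
  need <- c("tag_id", "count")
  miss <- setdiff(need, names(df))
  if (length(miss)) stop("band counts file missing column(s): ", paste(miss, collapse = ", "))
  if (!"reader_id" %in% names(df)) df$reader_id <- seq_len(nrow(df))
  df$tag_id <- as.character(df$tag_id)
  df
}

# Days at liberty: supplied days win over date arithmetic; disagreement warns.
resolve_days <- function(tag_id, date_tagged, date_recaptured, days_at_liberty) {
  date_days <- NA_real_
  if (!is.na(date_tagged) && !is.na(date_recaptured))
    date_days <- as.numeric(as.Date(date_recaptured) - as.Date(date_tagged))
  if (!is.na(days_at_liberty)) {
    if (!is.na(date_days) && date_days != days_at_liberty)
      warning(sprintf(
        "tag %s: days_at_liberty (%g) disagrees with date difference (%g); using days_at_liberty",
        tag_id, days_at_liberty, date_days))
    return(days_at_liberty)
  }
  date_days
}

#' Derive one shark's liberty record
#'
#' Combines a tag record and its recapture event into the derived per-shark
#' quantities: years at liberty, growth and growth rate, and the
#' backtransformed ages at tagging and recapture. The backtransformed age at
#' recapture is the backtransformed age at tagging (growth-curve inversion of
#' the tagging fork length) plus time-at-liberty.
#'
#' Records whose tagging length is at or above the curve's `L_inf`, or with no
#' matching parameter set, are not errors: they are flagged
#' non-backtransformable (`backtransformable = FALSE`, age fields `NA`) with a
#' warning, and excluded from backtransformed summaries downstream.
#'
#' @param tag One tag record: a list or one-row data frame with `tag_id`,
#'   `species`, `sex`, `fl_tag_mm` (and optionally `date_tagged`, `quality`).
#' @param recap Matching recapture event: `tag_id`, `days_at_liberty` (or the
#'   two dates), optionally `fl_recap_mm`, `quality`.
#' @param params The [vbgf_params()] set for this shark's species and sex, or
#'   `NULL` if none is available.
#' @return One-row data frame (a liberty record) with columns `tag_id`,
#'   `species`, `sex`, `fl_tag_mm`, `fl_recap_mm`, `tag_quality`,
#'   `recap_quality`, `days_at_liberty`, `years_at_liberty`, `growth_mm`,
#'   `growth_rate`, `age_tag_bt`, `age_recap_bt`, `age_direct` (filled later),
#'   `backtransformable`, `negative_growth`.
#' @export
backtransform_record <- function(tag, recap, params) {
  tag <- as.list(tag); recap <- as.list(recap)
  if (!identical(as.character(tag$tag_id), as.character(recap$tag_id)))
    stop("tag and recapture records have different tag_id")
  fl_tag <- as.numeric(tag$fl_tag_mm)
  if (!is.finite(fl_tag) || fl_tag < 0) stop("fl_tag_mm must be a non-negative length")

  days <- resolve_days(tag$tag_id,
                       if (is.null(tag$date_tagged)) NA else tag$date_tagged,
                       if (is.null(recap$date_recaptured)) NA else recap$date_recaptured,
                       if (is.null(recap$days_at_liberty)) NA_real_
                       else as.numeric(recap$days_at_liberty))
  if (is.na(days)) stop(sprintf("tag %s: no days_at_liberty and no usable dates", tag$tag_id))
  yrs <- years_at_liberty(days)

  fl_recap <- if (is.null(recap$fl_recap_mm)) NA_real_ else as.numeric(recap$fl_recap_mm)
  growth <- if (is.na(fl_recap)) NA_real_ else fl_recap - fl_tag
  rate <- if (is.na(growth)) NA_real_ else annual_growth_rate(growth, yrs)
  neg <- isTRUE(!is.na(growth) && growth < 0)
  if (neg) warning(sprintf("tag %s: negative growth (%g mm); record retained", tag$tag_id, growth))

  bt_ok <- FALSE; age_tag_bt <- NA_real_; age_recap_bt <- NA_real_
  if (is.null(params)) {
    warning(sprintf("tag %s: no VBGF parameters for (%s, %s); non-backtransformable",
                    tag$tag_id, tag$species, tag$sex))
  } else if (fl_tag >= params$L_inf) {
    warning(sprintf("tag %s: fork length %g mm >= L_inf %g mm; non-backtransformable",
                    tag$tag_id, fl_tag, params$L_inf))
  } else {
    age_tag_bt <- age_at_length(params, fl_tag)
    age_recap_bt <- age_tag_bt + yrs
    bt_ok <- TRUE
  }

  data.frame(
    tag_id = as.character(tag$tag_id),
    species = as.character(tag$species),
    sex = as.character(tag$sex),
    fl_tag_mm = fl_tag,
    fl_recap_mm = fl_recap,
    tag_quality = if (is.null(tag$quality) || is.na(tag$quality)) "measured" else tag$quality,
    recap_quality = if (is.null(recap$quality) || is.na(recap$quality)) "missing" else recap$quality,
    days_at_liberty = days,
    years_at_liberty = yrs,
    growth_mm = growth,
    growth_rate = rate,
    age_tag_bt = age_tag_bt,
    age_recap_bt = age_recap_bt,
    age_direct = NA_real_,
    backtransformable = bt_ok,
    negative_growth = neg,
    stringsAsFactors = FALSE
  )
}

#' Build liberty records for a whole study
#'
#' Joins tags to recaptures by `tag_id`, derives each liberty record with
#' [backtransform_record()], and attaches direct vertebral ages where a
#' unanimous band count exists. Recaptures with no matching tag record are
#' skipped with a warning.
#'
#' @param tags Data frame from [read_tags()].
#' @param recaptures Data frame from [read_recaptures()].
#' @param registry Optional [vbgf_registry()]; without it every record is
#'   non-backtransformable.
#' @param band_counts Optional reader table from [read_band_counts()], or a
#'   pre-consensus table with one `count` per `tag_id`. A `band_count` column
#'   on `recaptures` is used as a single-reader count when no table is given.
#' @return Data frame of liberty records, one row per matched recapture.
#' @export
build_liberty_records <- function(tags, recaptures, registry = NULL,
                                  band_counts = NULL) {
  stopifnot(is.data.frame(tags), is.data.frame(recaptures))
  if (nrow(recaptures) == 0L) {
    out <- suppressWarnings(backtransform_record(
      list(tag_id = "x", species = "x", sex = "unknown", fl_tag_mm = 1),
      list(tag_id = "x", days_at_liberty = 1), NULL))
    return(out[0L, ])
  }

  if (is.null(band_counts) && "band_count" %in% names(recaptures) &&
      any(!is.na(recaptures$band_count)))
    band_counts <- data.frame(tag_id = recaptures$tag_id, reader_id = 1L,
                              count = recaptures$band_count,
                              stringsAsFactors = FALSE)[!is.na(recaptures$band_count), ]
  cons <- if (!is.null(band_counts) && nrow(band_counts))
    consensus_band_counts(band_counts) else NULL

  rows <- vector("list", nrow(recaptures))
  for (i in seq_len(nrow(recaptures))) {
    rc <- recaptures[i, , drop = FALSE]
    j <- match(rc$tag_id, tags$tag_id)
    if (is.na(j)) {
      warning(sprintf("recapture of tag %s has no tag record; row skipped", rc$tag_id))
      next
    }
    tg <- tags[j, , drop = FALSE]
    params <- if (is.null(registry)) NULL else lookup_vbgf(registry, tg$species, tg$sex)
    rec <- backtransform_record(tg, rc, params)
    if (!is.null(cons)) {
      ci <- match(rec$tag_id, cons$tag_id)
      if (!is.na(ci) && isTRUE(cons$agreed[ci]))
        rec$age_direct <- direct_age(cons$count[ci])
    }
    rows[[i]] <- rec
  }
  rows <- rows[!vapply(rows, is.null, logical(1))]
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Summarise times at liberty
#'
#' n, min, max, mean and sample standard deviation (divisor n - 1) of years at
#' liberty, on unrounded values, optionally restricted to one species.
#'
#' @param records Liberty records from [build_liberty_records()].
#' @param species Optional species filter.
#' @return A list with `n`, `min`, `max`, `mean`, `sd` (`sd` is `NA` when
#'   n < 2).
#' @export
summarize_liberty <- function(records, species = NULL) {
  stopifnot(is.data.frame(records))
  if (!is.null(species)) records <- records[records$species == species, , drop = FALSE]
  y <- records$years_at_liberty
  if (length(y) == 0L) stop("no liberty records selected")
  list(n = length(y), min = min(y), max = max(y), mean = mean(y),
       sd = if (length(y) >= 2L) stats::sd(y) else NA_real_)
}

#' Render the per-recapture report table
#'
#' Formats the liberty records as the standard tagging-and-recapture report:
#' one row per recapture, derived columns rounded to one decimal (half away
#' from zero), missing values rendered `"-"`, and angler-estimated lengths
#' marked with a trailing `*`.
#'
#' @param records Liberty records from [build_liberty_records()].
#' @param digits Decimals for derived columns (default 1).
#' @return Data frame of character columns, ready to write as CSV.
#' @export
build_table1 <- function(records, digits = 1) {
  stopifnot(is.data.frame(records))
  star <- function(value, quality) {
    out <- fmt_report(value, 0)
    flag <- !is.na(value) & !is.na(quality) & quality == "angler_estimate"
    out[flag] <- paste0(out[flag], "*")
    out
  }
  n <- nrow(records)
  out <- data.frame(
    species = as.character(records$species),
    tag_id = as.character(records$tag_id),
    initial_fl_mm = if (n) star(records$fl_tag_mm, records$tag_quality) else character(0),
    recapture_fl_mm = if (n) star(records$fl_recap_mm, records$recap_quality) else character(0),
    growth_mm = fmt_report(records$growth_mm, 0),
    days_at_liberty = fmt_report(records$days_at_liberty, 0),
    years_at_liberty = fmt_report(records$years_at_liberty, digits),
    sex = as.character(records$sex),
    age_tag_bt = fmt_report(records$age_tag_bt, digits),
    age_recap_bt = fmt_report(records$age_recap_bt, digits),
    age_direct = fmt_report(records$age_direct, digits),
    stringsAsFactors = FALSE
  )
  rownames(out) <- NULL
  out
}

#' Maximum longevity per species and sex
#'
#' For each species-by-sex group: the observed maximum longevity (largest
#' direct vertebral age) and the maximum backtransformed longevity (largest
#' backtransformed age at recapture). Groups with no usable value in a column
#' get `NA` there (rendered `"-"` in reports).
#'
#' @param records Liberty records from [build_liberty_records()].
#' @return Data frame with columns `species`, `sex`, `observed_max_direct`,
#'   `max_backtransformed` (unrounded).
#' @export
max_longevity_table <- function(records) {
  stopifnot(is.data.frame(records))
  if (nrow(records) == 0L)
    return(data.frame(species = character(0), sex = character(0),
                      observed_max_direct = numeric(0),
                      max_backtransformed = numeric(0)))
  groups <- unique(records[, c("species", "sex")])
  groups <- groups[order(groups$species, groups$sex), , drop = FALSE]
  maxna <- function(x) { x <- x[!is.na(x)]; if (length(x)) max(x) else NA_real_ }
  out <- do.call(rbind, lapply(seq_len(nrow(groups)), function(i) {
    sel <- records$species == groups$species[i] & records$sex == groups$sex[i]
    data.frame(species = groups$species[i], sex = groups$sex[i],
               observed_max_direct = maxna(records$age_direct[sel]),
               max_backtransformed = maxna(records$age_recap_bt[sel]),
               stringsAsFactors = FALSE)
  }))
  rownames(out) <- NULL
  out
}
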
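#' Round half away from zero
#'
#' The single rounding routine used by every reporter in the package, so that
#' printed tables are mutually consistent. Unlike base `round()` (banker's
#' rounding), exact halves round away from zero: `round_half_up(1.75, 1)` is
#' 1.8. Internal computation never rounds; only report rendering does.
#'
#' @param x Numeric vector.
#' @param digits Decimal places (default 1).
#' @return Rounded numeric vector.
#' @export
round_half_up <- function(x, digits = 1) {
  m <- 10^digits
  sign(x) * floor(abs(x) * m + 0.5) / m
}

# Render a numeric report cell: rounded, fixed decimals, "-" for missing.
fmt_report <- function(x, digits = 1) {
  out <- ifelse(is.na(x), "-",
                formatC(round_half_up(x, digits), format = "f", digits = digits))
  as.character(out)
}

#' Validate tagging-study input files
#'
#' Row- and column-level checks on the study CSVs before analysis: required
#' columns present, fork lengths positive (warning outside the plausible
#' 100-2000 mm range), days at liberty positive, no duplicate tag ids in the
#' tag file, known sex and quality codes, band counts whole and >= 2.
#'
#' @param tags_path,recaptures_path Paths to the tag and recapture CSVs.
#' @param band_counts_path Optional path to the reader band-count CSV.
#' @return Data frame of issues with columns `file`, `row`, `column`,
#'   `severity` (`"error"` or `"warning"`), `message`; zero rows when the
#'   files are clean.
#' @export
validate_inputs <- function(tags_path, recaptures_path, band_counts_path = NULL) {
  for (pth in c(tags_path, recaptures_path, band_counts_path))
    if (!is.null(pth) && !file.exists(pth)) stop("file not found: ", pth)

  issues <- list()
  add <- function(file, row, column, severity, message) {
    issues[[length(issues) + 1L]] <<- data.frame(
      file = file, row = row, column = column, severity = severity,
      message = message, stringsAsFactors = FALSE)
  }

  tags <- read_tags(tags_path)
  fn <- basename(tags_path)
  dup <- tags$tag_id[duplicated(tags$tag_id)]
  for (d in unique(dup))
    add(fn, which(tags$tag_id == d)[2], "tag_id", "error",
        sprintf("duplicate tag_id '%s'", d))
  for (i in seq_len(nrow(tags))) {
    fl <- tags$fl_tag_mm[i]
    if (is.na(fl) || !is.finite(fl) || fl <= 0)
      add(fn, i, "fl_tag_mm", "error", "fork length must be positive")
    else if (fl < 100 || fl > 2000)
      add(fn, i, "fl_tag_mm", "warning",
          sprintf("fork length %g mm outside plausible range 100-2000 mm", fl))
    if (!is.na(tags$sex[i]) && !tags$sex[i] %in% c("female", "male", "unknown"))
      add(fn, i, "sex", "error", sprintf("unknown sex code '%s'", tags$sex[i]))
    if (!is.na(tags$quality[i]) && !tags$quality[i] %in% quality_levels)
      add(fn, i, "quality", "error", sprintf("unknown quality code '%s'", tags$quality[i]))
  }

  recs <- read_recaptures(recaptures_path)
  fn <- basename(recaptures_path)
  for (i in seq_len(nrow(recs))) {
    d <- recs$days_at_liberty[i]
    if (is.na(d) && (is.na(recs$date_recaptured[i])))
      add(fn, i, "days_at_liberty", "error",
          "neither days_at_liberty nor recapture date given")
    if (!is.na(d) && d <= 0)
      add(fn, i, "days_at_liberty", "error", "days at liberty must be positive")
    fl <- recs$fl_recap_mm[i]
    if (!is.na(fl)) {
      if (fl <= 0) add(fn, i, "fl_recap_mm", "error", "fork length must be positive")
      else if (fl < 100 || fl > 2000)
        add(fn, i, "fl_recap_mm", "warning",
            sprintf("fork length %g mm outside plausible range 100-2000 mm", fl))
    }
    if (!is.na(recs$quality[i]) && !recs$quality[i] %in% c(quality_levels, "missing"))
      add(fn, i, "quality", "error", sprintf("unknown quality code '%s'", recs$quality[i]))
  }

  if (!is.null(band_counts_path)) {
    bc <- read_band_counts(band_counts_path)
    fn <- basename(band_counts_path)
    for (i in seq_len(nrow(bc))) {
      cnt <- bc$count[i]
      if (is.na(cnt) || cnt != round(cnt) || cnt < 2)
        add(fn, i, "count", "error", "band count must be a whole number >= 2")
    }
  }

  if (length(issues)) do.call(rbind, issues)
  else data.frame(file = character(0), row = integer(0), column = character(0),
                  severity = character(0), message = character(0),
                  stringsAsFactors = FALSE)
}

#' Run the full tagging-study analysis and write reports
#'
#' Reads and validates the study files, builds liberty records, and writes the
#' standard reports to `out_dir`:
#' * `table1.csv` — per-recapture tagging/recapture table (lengths, growth,
#'   time at liberty, backtransformed and direct ages), formatted as in
#'   [build_table1()];
#' * `table2.csv` — maximum longevity per species and sex by each ageing
#'   route;
#' * `comparison.csv` — the paired backtransformed-vs-direct ages and their
#'   differences (written when at least one complete pair exists);
#' * `summary.txt` — plain-text study summary: per-species time-at-liberty
#'   statistics, per-shark growth rates, and the paired t-test.
#'
#' Re-running on identical inputs produces byte-identical reports; every
#' printed number is the unrounded pipeline value passed through
#' [round_half_up()].
#'
#' @param tags_path,recaptures_path,params_path Paths to the tag CSV, the
#'   recapture CSV and the YAML VBGF parameter registry.
#' @param out_dir Output directory (created if missing).
#' @param band_counts_path Optional path to the reader band-count CSV.
#' @param alpha Significance level for the paired t-test (default 0.05).
#' @param digits Report rounding decimals (default 1).
#' @return Invisibly, a list with the in-memory results: `records`, `table1`,
#'   `table2`, `summaries`, `comparison` (or `NULL`), `validation`.
#' @export
run_analysis <- function(tags_path, recaptures_path, params_path, out_dir,
                         band_counts_path = NULL, alpha = 0.05, digits = 1) {
  validation <- validate_inputs(tags_path, recaptures_path, band_counts_path)
  errs <- validation[validation$severity == "error", , drop = FALSE]
  if (nrow(errs))
    stop("input validation failed:\n",
         paste(sprintf("  %s row %s column %s: %s",
                       errs$file, errs$row, errs$column, errs$message),
               collapse = "\n"))
  for (i in seq_len(nrow(validation)))
    warning(sprintf("%s row %s column %s: %s", validation$file[i],
                    validation$row[i], validation$column[i],
                    validation$message[i]), call. = FALSE)

  registry <- read_vbgf_registry(params_path)
  tags <- read_tags(tags_path)
  recaptures <- read_recaptures(recaptures_path)
  band_counts <- if (!is.null(band_counts_path)) read_band_counts(band_counts_path)
                 else NULL
  if (nrow(recaptures) == 0L) warning("no recaptures: reports will be empty")

  records <- build_liberty_records(tags, recaptures, registry, band_counts)
  table1 <- build_table1(records, digits)
  table2 <- max_longevity_table(records)

  if (!dir.exists(out_dir)) dir.create(out_dir, recursive = TRUE)
  write_report_csv(table1, file.path(out_dir, "table1.csv"))
  table2_fmt <- data.frame(
    species = table2$species, sex = table2$sex,
    observed_max_direct = fmt_report(table2$observed_max_direct, digits),
    max_backtransformed = fmt_report(table2$max_backtransformed, digits),
    stringsAsFactors = FALSE)
  write_report_csv(table2_fmt, file.path(out_dir, "table2.csv"))

  summaries <- lapply(sort(unique(records$species)), function(sp)
    c(list(species = sp), summarize_liberty(records, sp)))

  comparison <- NULL
  has_pair <- nrow(records) > 0 &&
    any(!is.na(records$age_recap_bt) & !is.na(records$age_direct))
  if (has_pair) {
    comparison <- compare_age_estimates(records, alpha)
    write_report_csv(
      data.frame(tag_id = comparison$pairs$tag_id,
                 age_backtransformed = fmt_report(comparison$pairs$age_bt, digits),
                 age_direct = fmt_report(comparison$pairs$age_direct, digits),
                 difference = fmt_report(comparison$pairs$diff, digits),
                 stringsAsFactors = FALSE),
      file.path(out_dir, "comparison.csv"))
  }

  writeLines(render_summary(records, summaries, comparison, digits),
             file.path(out_dir, "summary.txt"))
  invisible(list(records = records, table1 = table1, table2 = table2,
                 summaries = summaries, comparison = comparison,
                 validation = validation))
}

write_report_csv <- function(df, path) {
  utils::write.csv(df, path, row.names = FALSE, quote = TRUE, eol = "\n")
  invisible(path)
}

# Plain-text study summary mirroring the quantities a results section reports.
render_summary <- function(records, summaries, comparison, digits = 1) {
  f <- function(x) fmt_report(x, digits)
  lines <- c("Tag-recapture longevity summary",
             "===============================", "")
  if (nrow(records) == 0L)
    return(c(lines, "No recaptures."))
  for (s in summaries) {
    lines <- c(lines, sprintf("%s: n = %d recaptures", s$species, s$n),
               sprintf("  years at liberty: %s to %s (mean +/- SD = %s +/- %s)",
                       f(s$min), f(s$max), f(s$mean), f(s$sd)))
    sel <- records$species == s$species & !is.na(records$growth_rate)
    for (i in which(sel))
      lines <- c(lines, sprintf(
        "  %s grew %s mm over %s years at liberty (%s mm/year)%s",
        records$tag_id[i], fmt_report(records$growth_mm[i], 0),
        f(records$years_at_liberty[i]), f(records$growth_rate[i]),
        if (records$recap_quality[i] == "angler_estimate")
          " [angler-estimated length]" else ""))
    lines <- c(lines, "")
  }
  nbt <- sum(!records$backtransformable)
  if (nbt > 0)
    lines <- c(lines, sprintf("%d record(s) non-backtransformable (length >= L_inf or no parameters).", nbt), "")
  if (!is.null(comparison)) {
    d <- comparison$differences
    lines <- c(lines, "Backtransformed vs direct age estimates:",
               sprintf("  n = %d pairs, mean difference %s years (range %s to %s)",
                       d$n, f(d$mean), f(d$min), f(d$max)))
    tt <- comparison$t_test
    if (!is.null(tt))
      lines <- c(lines, sprintf(
        "  paired t-test: t = %s, df = %d, two-sided P = %s (%s at alpha = %g)",
        formatC(round_half_up(tt$t, 2), format = "f", digits = 2), tt$df,
        formatC(round_half_up(tt$p, 3), format = "f", digits = 3),
        if (tt$significant) "significant" else "not significant", tt$alpha))
  }
  lines
}

#' Write a simulated study to CSV files
#'
#' Writes the tables from [simulate_population()] as `tags.csv`,
#' `recaptures.csv`, `band_counts.csv` and `truth.csv` under `out_dir`, ready
#' for [run_analysis()] (truth is for recovery checks only).
#'
#' @param sim Result of [simulate_population()].
#' @param out_dir Output directory (created if missing).
#' @return Invisibly, the four file paths.
#' @export
write_simulation <- function(sim, out_dir) {
  stopifnot(is.list(sim),
            all(c("truth", "tags", "recaptures", "band_counts") %in% names(sim)))
  if (!dir.exists(out_dir)) dir.create(out_dir, recursive = TRUE)
  paths <- c(tags = file.path(out_dir, "tags.csv"),
             recaptures = file.path(out_dir, "recaptures.csv"),
             band_counts = file.path(out_dir, "band_counts.csv"),
             truth = file.path(out_dir, "truth.csv"))
  utils::write.csv(sim$tags, paths["tags"], row.names = FALSE)
  utils::write.csv(sim$recaptures, paths["recaptures"], row.names = FALSE)
  utils::write.csv(sim$band_counts, paths["band_counts"], row.names = FALSE)
  utils::write.csv(sim$truth, paths["truth"], row.names = FALSE)
  invisible(paths)
}

#' Path to a packaged example data file
#'
#' The package ships the eight long-term shark recaptures of a South Carolina
#' longline tagging program as plain CSV fixtures, plus a synthetic VBGF
#' parameter registry (illustrative values only — the published growth-curve
#' fits for these species are external inputs and are not bundled).
#'
#' @param file File name under `extdata/`; `NULL` lists available files.
#' @return Full path to the file.
#' @examples
#' sharktag_example()
#' read_tags(sharktag_example("tags.csv"))
#' @export
sharktag_example <- function(file = NULL) {
  if (is.null(file))
    return(list.files(system.file("extdata", package = "sharktag")))
  path <- system.file("extdata", file, package = "sharktag")
  if (path == "") stop("no packaged file named '", file, "'")
  path
}
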
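test_that("days convert to years by the 365.25 convention", {
  expect_equal(years_at_liberty(5098), 5098 / 365.25)
  expect_equal(round_half_up(years_at_liberty(5098), 1), 14.0)
  expect_equal(round_half_up(years_at_liberty(4678), 1), 12.8)
  expect_equal(years_at_liberty(365), 365 / 365.25)
  expect_lt(years_at_liberty(365), 1)
  expect_error(years_at_liberty(0), "positive")
  expect_error(years_at_liberty(-3), "positive")
})

test_that("annualised growth rate divides growth by years at liberty", {
  expect_equal(annual_growth_rate(28, 4438 / 365.25), 28 * 365.25 / 4438)
  expect_equal(round_half_up(annual_growth_rate(28, 4438 / 365.25), 1), 2.3)
  expect_equal(round_half_up(annual_growth_rate(177, 4678 / 365.25), 1), 13.8)
  expect_equal(annual_growth_rate(0, 3), 0)
  expect_equal(annual_growth_rate(-10, 5), -2) # negative growth permitted
  expect_error(annual_growth_rate(10, 0), "positive")
})

test_that("backtransform_record derives ages, growth and liberty consistently", {
  p <- ref_params()
  rec <- backtransform_record(
    list(tag_id = "x1", species = p$species, sex = "male", fl_tag_mm = 700,
         quality = "measured"),
    list(tag_id = "x1", days_at_liberty = 4438, fl_recap_mm = 730,
         quality = "measured"),
    p)
  expect_equal(rec$age_tag_bt, age_at_length(p, 700))
  expect_equal(rec$age_recap_bt, rec$age_tag_bt + 4438 / 365.25)
  expect_equal(rec$growth_mm, 30)
  expect_equal(rec$growth_rate, 30 / (4438 / 365.25))
  expect_true(rec$backtransformable)
  expect_false(rec$negative_growth)

  # zero tagging length anchors the backtransformed age at t0
  rec0 <- backtransform_record(
    list(tag_id = "x2", species = p$species, sex = "male", fl_tag_mm = 0),
    list(tag_id = "x2", days_at_liberty = 100), p)
  expect_equal(rec0$age_tag_bt, p$t0)
})

test_that("lengths at or above L_inf flag the record instead of erroring", {
  p <- ref_params()
  expect_warning(
    rec <- backtransform_record(
      list(tag_id = "big", species = p$species, sex = "male", fl_tag_mm = 950),
      list(tag_id = "big", days_at_liberty = 100), p),
    "non-backtransformable")
  expect_false(rec$backtransformable)
  expect_true(is.na(rec$age_tag_bt) && is.na(rec$age_recap_bt))
  expect_equal(rec$years_at_liberty, 100 / 365.25) # liberty still derived
})

test_that("negative growth is flagged but retained", {
  p <- ref_params()
  expect_warning(
    rec <- backtransform_record(
      list(tag_id = "n", species = p$species, sex = "male", fl_tag_mm = 800),
      list(tag_id = "n", days_at_liberty = 400, fl_recap_mm = 790,
           quality = "angler_estimate"), p),
    "negative growth")
  expect_true(rec$negative_growth)
  expect_equal(rec$growth_mm, -10)
  expect_true(rec$backtransformable)
})

test_that("supplied days win over disagreeing date arithmetic, with a warning", {
  p <- ref_params()
  expect_warning(
    rec <- backtransform_record(
      list(tag_id = "d", species = p$species, sex = "male", fl_tag_mm = 700,
           date_tagged = "2000-01-01"),
      list(tag_id = "d", date_recaptured = "2001-01-01", days_at_liberty = 400),
      p),
    "disagrees")
  expect_equal(rec$days_at_liberty, 400)
  # dates alone are used when days are absent
  rec2 <- backtransform_record(
    list(tag_id = "d2", species = p$species, sex = "male", fl_tag_mm = 700,
         date_tagged = "2000-01-01"),
    list(tag_id = "d2", date_recaptured = "2001-01-01", days_at_liberty = NA),
    p)
  expect_equal(rec2$days_at_liberty, 366) # 2000 is a leap year
})

test_that("additivity: recapture age minus tagging age equals years at liberty", {
  set.seed(7)
  for (p in random_params(10, seed = 11)) {
    fl <- runif(1, 0, 0.95 * p$L_inf)
    days <- sample(100:6000, 1)
    rec <- backtransform_record(
      list(tag_id = "a", species = p$species, sex = "combined", fl_tag_mm = fl),
      list(tag_id = "a", days_at_liberty = days), p)
    expect_equal(rec$age_recap_bt - rec$age_tag_bt, rec$years_at_liberty,
                 tolerance = 1e-12)
  }
})

test_that("study build joins tags to recaptures and attaches direct ages", {
  rec <- fixture_records()
  expect_equal(nrow(rec), 8L)
  expect_equal(sum(rec$species == "R. terraenovae"), 5L)
  expect_equal(sum(rec$species == "C. acronotus"), 3L)
  expect_equal(rec$age_direct[rec$tag_id == "L5242"], 18.5)
  expect_equal(rec$age_direct[rec$tag_id == "L3384"], 20.5)
  expect_equal(sum(!is.na(rec$age_direct)), 4L)
  expect_true(all(rec$backtransformable))
})

test_that("recaptures without a tag record are skipped with a warning", {
  tags <- read_tags(fixture("tags.csv"))
  recs <- read_recaptures(fixture("recaptures.csv"))
  recs$tag_id[3] <- "GHOST"
  reg <- read_vbgf_registry(fixture("vbgf_params_synthetic.yaml"))
  expect_warning(out <- build_liberty_records(tags, recs, reg), "GHOST")
  expect_equal(nrow(out), 7L)
  expect_false("GHOST" %in% out$tag_id)
})

test_that("empty recapture input yields an empty record table", {
  tags <- read_tags(fixture("tags.csv"))
  empty <- read_recaptures(fixture("recaptures.csv"))[0, ]
  out <- build_liberty_records(tags, empty)
  expect_equal(nrow(out), 0L)
  expect_true(all(c("years_at_liberty", "age_recap_bt") %in% names(out)))
})

test_that("liberty summaries use unrounded years and the sample SD", {
  rec <- fixture_records()
  rt <- summarize_liberty(rec, "R. terraenovae")
  expect_equal(rt$n, 5L)
  expect_equal(rt$mean, mean(c(5098, 3237, 2937, 4438, 2806) / 365.25))
  expect_equal(rt$sd, sd(c(5098, 3237, 2937, 4438, 2806) / 365.25))
  one <- summarize_liberty(rec[rec$tag_id == "L5242", ])
  expect_equal(one$n, 1L)
  expect_equal(one$mean, 4438 / 365.25)
  expect_true(is.na(one$sd))
  expect_error(summarize_liberty(rec, "no such species"), "no liberty records")
})

test_that("report table marks angler estimates and renders missing cells", {
  t1 <- build_table1(fixture_records())
  expect_equal(nrow(t1), 8L)
  expect_equal(t1$recapture_fl_mm[t1$tag_id == "L2881"], "828*")
  expect_equal(t1$recapture_fl_mm[t1$tag_id == "L5242"], "830")
  expect_equal(t1$recapture_fl_mm[t1$tag_id == "L5173"], "-")
  expect_equal(t1$growth_mm[t1$tag_id == "L3384"], "-")
  expect_equal(t1$age_direct[t1$tag_id == "L2881"], "-")
  expect_equal(t1$growth_mm[t1$tag_id == "L5242"], "28")
  empty <- build_table1(fixture_records()[0, ])
  expect_equal(nrow(empty), 0L)
})

test_that("longevity maxima equal brute-force maxima per species-sex group", {
  rec <- fixture_records()
  t2 <- max_longevity_table(rec)
  for (i in seq_len(nrow(t2))) {
    sel <- rec$species == t2$species[i] & rec$sex == t2$sex[i]
    bf_dir <- suppressWarnings(max(rec$age_direct[sel], na.rm = TRUE))
    bf_bt <- suppressWarnings(max(rec$age_recap_bt[sel], na.rm = TRUE))
    if (is.finite(bf_dir)) expect_equal(t2$observed_max_direct[i], bf_dir)
    else expect_true(is.na(t2$observed_max_direct[i]))
    if (is.finite(bf_bt)) expect_equal(t2$max_backtransformed[i], bf_bt)
    else expect_true(is.na(t2$max_backtransformed[i]))
  }
  # single-record group returns its own values
  solo <- max_longevity_table(rec[rec$tag_id == "L1515", ])
  expect_equal(solo$observed_max_direct, 14.5)
  expect_equal(solo$max_backtransformed,
               rec$age_recap_bt[rec$tag_id == "L1515"])
})
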
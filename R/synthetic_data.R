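#' Configuration for a simulated tagging study
#'
#' Bundles and validates everything the mark-recapture simulator needs. The
#' defaults describe a long-running coastal shark longline tagging program:
#' low annual recapture probability (project recapture rates under 3%),
#' substantial dart-tag shedding (cumulative multi-year shedding reported as
#' high as 41-63%; parameterised here as an annual retention probability,
#' with cumulative shedding over y years equal to `1 - annual_retention^y`),
#' sharks tagged as juveniles, and two measurement regimes (precise survey
#' measurements vs angler estimates).
#'
#' @param n_sharks Number of sharks tagged (>= 1).
#' @param params [vbgf_params()] giving the population-mean growth curve.
#' @param cv_Linf,cv_k Coefficients of variation of individual `L_inf` and `k`
#'   (lognormal heterogeneity, mean-preserving); 0 disables heterogeneity.
#' @param cor_Linf_k Correlation between individual log-`L_inf` and log-`k`
#'   draws (default 0, independent).
#' @param sd_measured,sd_angler Gaussian fork-length measurement error SDs in
#'   mm for precise and angler-estimated measurements.
#' @param p_angler Probability a recapture measurement is angler-estimated.
#' @param annual_retention Probability per year that a tag is retained.
#' @param annual_recapture Probability per year that a tagged shark still
#'   carrying its tag is recaptured.
#' @param study_years Number of study years after tagging (>= 1).
#' @param age_at_tagging_range Two-element range (years) from which true ages
#'   at tagging are drawn.
#' @param winter_aligned If `TRUE` (default), ages at tagging are drawn from
#'   the winter grid (0.5, 1.5, 2.5, ... years) inside the range, so that band
#'   counts at recapture anniversaries invert exactly; if `FALSE`, birth date
#'   within the year is uniform (ages at tagging continuous).
#' @param seed Integer RNG seed; every simulator draw flows from it.
#' @return Object of class `simulation_config`.
#' @export
simulation_config <- function(n_sharks,
                              params,
                              cv_Linf = 0,
                              cv_k = 0,
                              cor_Linf_k = 0,
                              sd_measured = 5,
                              sd_angler = 30,
                              p_angler = 0.6,
                              annual_retention = 0.85,
                              annual_recapture = 0.02,
                              study_years = 20,
                              age_at_tagging_range = c(0.5, 5.5),
                              winter_aligned = TRUE,
                              seed = 1L) {
  stopifnot(inherits(params, "vbgf_params"))
  chk_prob <- function(x, nm) {
    if (!is.numeric(x) || length(x) != 1L || !is.finite(x) || x < 0 || x > 1)
      stop(sprintf("'%s' must be a probability in [0, 1]", nm))
  }
  chk_nonneg <- function(x, nm) {
    if (!is.numeric(x) || length(x) != 1L || !is.finite(x) || x < 0)
      stop(sprintf("'%s' must be a non-negative number", nm))
  }
  if (!is.numeric(n_sharks) || length(n_sharks) != 1L || n_sharks < 1 ||
      n_sharks != round(n_sharks))
    stop("'n_sharks' must be a positive integer")
  if (!is.numeric(study_years) || length(study_years) != 1L || study_years < 1 ||
      study_years != round(study_years))
    stop("'study_years' must be a positive integer")
  chk_nonneg(cv_Linf, "cv_Linf"); chk_nonneg(cv_k, "cv_k")
  chk_nonneg(sd_measured, "sd_measured"); chk_nonneg(sd_angler, "sd_angler")
  chk_prob(p_angler, "p_angler")
  chk_prob(annual_retention, "annual_retention")
  chk_prob(annual_recapture, "annual_recapture")
  if (!is.numeric(cor_Linf_k) || abs(cor_Linf_k) > 1)
    stop("'cor_Linf_k' must be in [-1, 1]")
  if (length(age_at_tagging_range) != 2L ||
      any(!is.finite(age_at_tagging_range)) ||
      age_at_tagging_range[1] < 0 ||
      age_at_tagging_range[2] < age_at_tagging_range[1])
    stop("'age_at_tagging_range' must be a non-decreasing non-negative pair of years")
  if (!is.numeric(seed) || length(seed) != 1L || !is.finite(seed))
    stop("'seed' must be a single integer")
  structure(
    list(n_sharks = as.integer(n_sharks), params = params,
         cv_Linf = cv_Linf, cv_k = cv_k, cor_Linf_k = cor_Linf_k,
         sd_measured = sd_measured, sd_angler = sd_angler, p_angler = p_angler,
         annual_retention = annual_retention, annual_recapture = annual_recapture,
         study_years = as.integer(study_years),
         age_at_tagging_range = as.numeric(age_at_tagging_range),
         winter_aligned = isTRUE(winter_aligned),
         seed = as.integer(seed)),
    class = "simulation_config"
  )
}

# Mean-preserving lognormal multipliers with given CVs and log-scale
# correlation. Returns an n x 2 matrix of multipliers for (L_inf, k).
lognormal_multipliers <- function(n, cv1, cv2, rho) {
  s1 <- sqrt(log(1 + cv1^2)); s2 <- sqrt(log(1 + cv2^2))
  z1 <- stats::rnorm(n); z2 <- stats::rnorm(n)
  z2 <- rho * z1 + sqrt(1 - rho^2) * z2
  cbind(exp(-s1^2 / 2 + s1 * z1), exp(-s2^2 / 2 + s2 * z2))
}

#' Simulate a tagged shark population
#'
#' Generates a complete synthetic tagging study with known truth. Per shark:
#' individual `L_inf` and `k` are the population means times mean-preserving
#' lognormal multipliers; true age at tagging is drawn from the configured
#' range (winter grid by default); fork length at tagging is the individual
#' growth curve plus Gaussian survey measurement error. Each subsequent year,
#' in order: the tag survives shedding with probability `annual_retention`
#' (a shed tag vanishes from the study — shedding is evaluated before the
#' recapture draw, so a shed tag is never reported); a retained tag is then
#' recaptured with probability `annual_recapture`. Recaptures occur on
#' tagging anniversaries, so days at liberty are exact multiples of 365.25.
#' Recapture lengths carry measured or angler error (quality Bernoulli
#' `p_angler`); band counts follow the deposition schedule
#' ([expected_band_count()]) at the true age, read unanimously by three
#' readers.
#'
#' Output is fully reproducible: the same config (including seed) gives
#' bit-identical tables.
#'
#' @param config A [simulation_config()].
#' @return A list of data frames: `truth` (per-shark ground truth), `tags`,
#'   `recaptures`, `band_counts` (shaped like the pipeline's CSV inputs; only
#'   non-shed, recaptured sharks appear in `recaptures`/`band_counts`).
#' @export
simulate_population <- function(config) {
  stopifnot(inherits(config, "simulation_config"))
  set.seed(config$seed)
  n <- config$n_sharks
  p <- config$params

  mult <- lognormal_multipliers(n, config$cv_Linf, config$cv_k, config$cor_Linf_k)
  L_inf_i <- p$L_inf * mult[, 1]
  k_i <- p$k * mult[, 2]

  rng <- config$age_at_tagging_range
  if (config$winter_aligned) {
    lo <- ceiling(rng[1] - 0.5); hi <- floor(rng[2] - 0.5)
    if (hi < lo) stop("age_at_tagging_range contains no winter-aligned age (m + 0.5)")
    age_tag <- 0.5 + sample(lo:hi, n, replace = TRUE)
  } else {
    age_tag <- stats::runif(n, rng[1], rng[2])
  }
  true_fl_tag <- L_inf_i * -expm1(-k_i * (age_tag - p$t0))
  obs_fl_tag <- true_fl_tag + stats::rnorm(n, 0, config$sd_measured)

  # Yearly shed-then-recapture process; first recapture removes the shark.
  active <- rep(TRUE, n)
  shed <- rep(FALSE, n)
  recap_year <- rep(NA_integer_, n)
  for (y in seq_len(config$study_years)) {
    u_ret <- stats::runif(n)
    u_rec <- stats::runif(n)
    lost <- active & (u_ret >= config$annual_retention)
    shed[lost] <- TRUE
    active[lost] <- FALSE
    caught <- active & (u_rec < config$annual_recapture)
    recap_year[caught] <- y
    active[caught] <- FALSE
  }

  recaptured <- !is.na(recap_year)
  age_recap <- ifelse(recaptured, age_tag + recap_year, NA_real_)
  true_fl_recap <- ifelse(recaptured,
                          L_inf_i * -expm1(-k_i * (age_recap - p$t0)),
                          NA_real_)
  band_recap <- rep(NA_integer_, n)
  band_recap[recaptured] <- expected_band_count(age_recap[recaptured])

  n_rec <- sum(recaptured)
  angler <- rep(NA, n)
  obs_fl_recap <- rep(NA_real_, n)
  if (n_rec > 0) {
    angler[recaptured] <- stats::runif(n_rec) < config$p_angler
    err_sd <- ifelse(angler[recaptured], config$sd_angler, config$sd_measured)
    obs_fl_recap[recaptured] <- true_fl_recap[recaptured] +
      stats::rnorm(n_rec, 0, err_sd)
  }

  tag_id <- sprintf("S%06d", seq_len(n))
  out_sex <- if (p$sex %in% c("male", "female")) p$sex else "unknown"

  truth <- data.frame(
    tag_id = tag_id,
    true_age_at_tagging = age_tag,
    L_inf_i = L_inf_i, k_i = k_i,
    true_fl_tag = true_fl_tag,
    shed = shed,
    recaptured = recaptured,
    recap_year = recap_year,
    true_age_at_recapture = age_recap,
    true_fl_recap = true_fl_recap,
    true_band_count = band_recap,
    stringsAsFactors = FALSE
  )
  tags <- data.frame(
    tag_id = tag_id,
    species = p$species,
    sex = out_sex,
    fl_tag_mm = obs_fl_tag,
    date_tagged = NA_character_,
    quality = "measured",
    stringsAsFactors = FALSE
  )
  ri <- which(recaptured)
  recaptures <- data.frame(
    tag_id = tag_id[ri],
    date_recaptured = rep(NA_character_, length(ri)),
    days_at_liberty = recap_year[ri] * 365.25,
    fl_recap_mm = obs_fl_recap[ri],
    quality = ifelse(angler[ri], "angler_estimate", "measured"),
    stringsAsFactors = FALSE
  )
  band_counts <- data.frame(
    tag_id = rep(tag_id[ri], each = 3L),
    reader_id = rep(1:3, times = length(ri)),
    count = rep(band_recap[ri], each = 3L),
    stringsAsFactors = FALSE
  )
  list(truth = truth, tags = tags, recaptures = recaptures,
       band_counts = band_counts)
}

#' Recovery experiment: estimated vs true ages at recapture
#'
#' Simulates a population, runs the full pipeline (growth-curve
#' backtransformation with the population-mean parameters, and band-count
#' ageing) on the simulated files, and measures how well each ageing route
#' recovers the true age at recapture. With zero heterogeneity and zero
#' measurement error the backtransform route is exact (bias and RMSE 0);
#' growth heterogeneity or measurement error induces bias because
#' backtransformation with the population-mean curve assigns each length the
#' average age-at-length, while individuals may be younger or older.
#'
#' @param config A [simulation_config()].
#' @return A list: `n_recaptured`, `n_backtransformable`, `bias_bt`,
#'   `rmse_bt` (backtransformed age at recapture vs truth), `bias_direct`,
#'   `rmse_direct` (direct vertebral age vs truth).
#' @export
recovery_experiment <- function(config) {
  stopifnot(inherits(config, "simulation_config"))
  sim <- simulate_population(config)
  if (nrow(sim$recaptures) == 0L)
    stop("no recaptures simulated: increase n_sharks, study_years, or probabilities")
  registry <- vbgf_registry(config$params)
  rec <- withCallingHandlers(
    build_liberty_records(sim$tags, sim$recaptures, registry, sim$band_counts),
    warning = function(w) invokeRestart("muffleWarning"))
  truth <- sim$truth[match(rec$tag_id, sim$truth$tag_id), ]

  bt <- rec$backtransformable
  err_bt <- rec$age_recap_bt[bt] - truth$true_age_at_recapture[bt]
  err_dir <- rec$age_direct - truth$true_age_at_recapture
  err_dir <- err_dir[!is.na(err_dir)]
  list(
    n_recaptured = nrow(rec),
    n_backtransformable = sum(bt),
    bias_bt = mean(err_bt),
    rmse_bt = sqrt(mean(err_bt^2)),
    bias_direct = if (length(err_dir)) mean(err_dir) else NA_real_,
    rmse_direct = if (length(err_dir)) sqrt(mean(err_dir^2)) else NA_real_
  )
}

#' Expected and simulated yield of long-liberty recaptures
#'
#' How many recaptures at liberty at least `min_years` does a study design
#' yield? Under the simulator's event ordering (shedding before recapture,
#' first recapture removes the shark), the probability that a shark is
#' recaptured exactly in year y is
#' \deqn{P_y = r^y \, (1 - c)^{y - 1} \, c}
#' with r = `annual_retention`, c = `annual_recapture`: the tag must survive y
#' shedding draws, escape recapture in years 1..y-1, and be caught in year y.
#' The analytic expectation is \eqn{n \sum_{y \ge \lceil m \rceil} P_y}
#' truncated at `study_years`; the simulated count is a binomial realisation
#' around it.
#'
#' @param config A [simulation_config()].
#' @param min_years Minimum years at liberty (recaptures occur on
#'   anniversaries, so a recapture counts when its year >= `min_years`).
#' @return A list: `expected` (analytic), `simulated` (count from one
#'   simulation under the config's seed), `p_long` (per-shark probability),
#'   `se` (binomial standard error of the simulated count).
#' @export
long_liberty_yield <- function(config, min_years) {
  stopifnot(inherits(config, "simulation_config"))
  if (!is.numeric(min_years) || length(min_years) != 1L || min_years < 0)
    stop("'min_years' must be a non-negative number of years")
  r <- config$annual_retention
  c_ <- config$annual_recapture
  y0 <- max(1, ceiling(min_years))
  years <- if (y0 > config$study_years) integer(0) else y0:config$study_years
  p_y <- r^years * (1 - c_)^(years - 1) * c_
  p_long <- sum(p_y)
  expected <- config$n_sharks * p_long

  sim <- simulate_population(config)
  simulated <- sum(!is.na(sim$truth$recap_year) & sim$truth$recap_year >= min_years)
  list(expected = expected, simulated = simulated, p_long = p_long,
       se = sqrt(config$n_sharks * p_long * (1 - p_long)))
}
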
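noise_free_config <- function(n = 200, seed = 1, ...) {
  simulation_config(
    n_sharks = n, params = ref_params(),
    cv_Linf = 0, cv_k = 0, sd_measured = 0, sd_angler = 0,
    annual_retention = 1, annual_recapture = 0.3,
    study_years = 15, seed = seed, ...)
}

test_that("invalid configurations are rejected before any sampling", {
  p <- ref_params()
  expect_error(simulation_config(0, p), "n_sharks")
  expect_error(simulation_config(10, p, annual_recapture = 1.2), "probability")
  expect_error(simulation_config(10, p, annual_retention = -0.1), "probability")
  expect_error(simulation_config(10, p, cv_Linf = -1), "non-negative")
  expect_error(simulation_config(10, p, age_at_tagging_range = c(3, 1)), "range")
  expect_error(simulation_config(10, p, study_years = 0), "study_years")
})

test_that("noise-free sharks sit exactly on the shared growth curve", {
  cfg <- noise_free_config()
  sim <- simulate_population(cfg)
  p <- cfg$params
  expect_equal(sim$tags$fl_tag_mm,
               length_at_age(p, sim$truth$true_age_at_tagging), tolerance = 1e-12)
  i <- match(sim$recaptures$tag_id, sim$truth$tag_id)
  expect_equal(sim$recaptures$fl_recap_mm,
               length_at_age(p, sim$truth$true_age_at_recapture[i]),
               tolerance = 1e-12)
  expect_true(all(sim$truth$true_fl_tag < sim$truth$L_inf_i))
})

test_that("certain retention and recapture catch every shark in year one", {
  cfg <- simulation_config(50, ref_params(), annual_retention = 1,
                           annual_recapture = 1, study_years = 5, seed = 3)
  sim <- simulate_population(cfg)
  expect_equal(nrow(sim$recaptures), 50L)
  expect_true(all(sim$truth$recap_year == 1L))
  expect_equal(sim$recaptures$days_at_liberty, rep(365.25, 50))
})

test_that("identical seeds give bit-identical output tables", {
  cfg <- simulation_config(500, ref_params(), cv_Linf = 0.1, cv_k = 0.1,
                           seed = 99)
  a <- simulate_population(cfg)
  b <- simulate_population(cfg)
  expect_identical(a, b)
  c2 <- simulate_population(simulation_config(500, ref_params(), cv_Linf = 0.1,
                                              cv_k = 0.1, seed = 100))
  expect_false(identical(a$truth, c2$truth))
})

test_that("one-year recapture fraction sits in the 3-sigma binomial band", {
  cfg <- simulation_config(10000, ref_params(), annual_retention = 1,
                           annual_recapture = 0.01, study_years = 1, seed = 5)
  sim <- simulate_population(cfg)
  frac <- nrow(sim$recaptures) / 10000
  expect_lt(abs(frac - 0.01), 3 * sqrt(0.01 * 0.99 / 10000))
})

test_that("band counts always follow the deposition schedule at true age", {
  cfg <- simulation_config(300, ref_params(), cv_Linf = 0.15, cv_k = 0.1,
                           annual_retention = 0.9, annual_recapture = 0.2,
                           winter_aligned = FALSE, seed = 21)
  sim <- simulate_population(cfg)
  rec <- sim$truth[sim$truth$recaptured, ]
  expect_gt(nrow(rec), 0)
  expect_identical(rec$true_band_count,
                   expected_band_count(rec$true_age_at_recapture))
})

test_that("noise-free recovery is exact for both ageing routes", {
  res <- recovery_experiment(noise_free_config(n = 300, seed = 8))
  expect_gt(res$n_recaptured, 0)
  expect_equal(res$n_backtransformable, res$n_recaptured)
  expect_lt(abs(res$bias_bt), 1e-9)
  expect_lt(res$rmse_bt, 1e-9)
  # winter-aligned tagging ages plus anniversary recaptures: band path exact
  expect_equal(res$bias_direct, 0)
  expect_equal(res$rmse_direct, 0)
})

test_that("growth heterogeneity induces backtransformation error, reproducibly", {
  cfg <- simulation_config(2000, ref_params(), cv_Linf = 0.1,
                           sd_measured = 0, sd_angler = 0,
                           annual_retention = 1, annual_recapture = 0.2,
                           study_years = 10, seed = 13)
  res1 <- recovery_experiment(cfg)
  res2 <- recovery_experiment(cfg)
  expect_identical(res1, res2)
  expect_gt(res1$rmse_bt, 0.05)
  expect_true(res1$bias_bt != 0)
})

test_that("zero recaptures raise an informative error", {
  cfg <- simulation_config(20, ref_params(), annual_recapture = 0, seed = 2)
  expect_error(recovery_experiment(cfg), "no recaptures")
})

test_that("long-liberty yield: degenerate probabilities give zero", {
  p <- ref_params()
  y0 <- long_liberty_yield(
    simulation_config(100, p, annual_recapture = 0, seed = 4), 1)
  expect_equal(y0$expected, 0)
  expect_equal(y0$simulated, 0L)
  y1 <- long_liberty_yield(
    simulation_config(100, p, annual_retention = 0, seed = 4), 2)
  expect_equal(y1$expected, 0)
  expect_equal(y1$simulated, 0L)
  beyond <- long_liberty_yield(
    simulation_config(100, p, study_years = 5, seed = 4), 6)
  expect_equal(beyond$expected, 0)
  expect_equal(beyond$simulated, 0L)
})

test_that("simulated long-liberty count agrees with the analytic expectation", {
  cfg <- simulation_config(100000, ref_params(), annual_retention = 0.85,
                           annual_recapture = 0.02, study_years = 20, seed = 6)
  y <- long_liberty_yield(cfg, 10)
  expect_lt(abs(y$simulated - y$expected), 3 * y$se)
  # the analytic form against brute-force enumeration of the yearly process
  r <- 0.85; cc <- 0.02
  brute <- sum(vapply(10:20, function(yy) r^yy * (1 - cc)^(yy - 1) * cc, 1.0))
  expect_equal(y$p_long, brute, tolerance = 1e-12)
})
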
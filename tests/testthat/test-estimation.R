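test_that("noise-free exponential growth is recovered exactly", {
  fit <- fit_growth_rate(exp_series(lam = 0.14, V0 = 500))
  expect_equal(fit$lam_hat, 0.14, tolerance = 1e-12)
  expect_equal(fit$V0_hat, 500, tolerance = 1e-9)
  expect_equal(fit$n_points, 11L)

  flat <- fit_growth_rate(data.frame(day = 0:6, volume_mm3 = 800))
  expect_equal(flat$lam_hat, 0, tolerance = 1e-12)
  expect_equal(flat$V0_hat, 800, tolerance = 1e-9)
})

test_that("the fitting window is taken relative to the first measurement", {
  # same animal observed from day 37 (treatment-start re-indexing upstream)
  shifted <- data.frame(day = 37 + 0:10,
                        volume_mm3 = 500 * exp(0.14 * (0:10)))
  fit <- fit_growth_rate(shifted, window_days = 10)
  expect_equal(fit$lam_hat, 0.14, tolerance = 1e-12)
  expect_equal(fit$n_points, 11L)

  # points beyond the window are excluded
  long <- exp_series(days = seq(0, 30, by = 2))
  expect_equal(fit_growth_rate(long, window_days = 10)$n_points, 6L)
})

test_that("degenerate series are rejected with informative classes", {
  expect_error(fit_growth_rate(data.frame(day = 0, volume_mm3 = 500)),
               class = "trtsim_insufficient_data")
  expect_error(fit_growth_rate(data.frame(day = c(0, 20),
                                          volume_mm3 = c(500, 900)),
                               window_days = 10),
               class = "trtsim_insufficient_data")
  expect_error(fit_growth_rate(data.frame(day = 0:3,
                                          volume_mm3 = c(500, -1, 600, 700))),
               class = "trtsim_invalid_input")
  expect_error(fit_growth_rate(data.frame(day = 0:3)),
               class = "trtsim_invalid_input")
})

test_that("log-linear slope is unbiased under multiplicative lognormal noise", {
  set.seed(7211)
  days <- seq(0, 10, by = 2) # 6 measurement days
  reps <- 400
  lam_hats <- vapply(seq_len(reps), function(i) {
    v <- 500 * exp(0.14 * days) * exp(rnorm(length(days), 0, 0.2))
    fit_growth_rate(data.frame(day = days, volume_mm3 = v))$lam_hat
  }, numeric(1))
  mc_se <- sd(lam_hats) / sqrt(reps)
  expect_lt(abs(mean(lam_hats) - 0.14), 3 * mc_se)
})

test_that("estimator precision improves with denser sampling", {
  set.seed(88)
  rmse <- function(days, reps = 300) {
    errs <- vapply(seq_len(reps), function(i) {
      v <- 500 * exp(0.14 * days) * exp(rnorm(length(days), 0, 0.2))
      fit_growth_rate(data.frame(day = days, volume_mm3 = v))$lam_hat - 0.14
    }, numeric(1))
    sqrt(mean(errs^2))
  }
  expect_lt(rmse(seq(0, 10, by = 1)), rmse(seq(0, 10, by = 5)))
})

test_that("cohort summaries use the sample SD and flag single-animal cohorts", {
  fits <- lapply(c(0.06, 0.14, 0.22), function(l) {
    fit_growth_rate(exp_series(lam = l), animal_id = paste0("m", l))
  })
  s <- summarize_cohort(fits)
  expect_equal(s$lam_mean, 0.14, tolerance = 1e-10)
  expect_equal(s$lam_sd, sd(c(0.06, 0.14, 0.22)), tolerance = 1e-10)
  expect_equal(s$n_animals, 3L)
  expect_false(s$degenerate)

  single <- summarize_cohort(fits[1])
  expect_equal(single$lam_sd, 0)
  expect_equal(single$V0_sd, 0)
  expect_true(single$degenerate)

  expect_error(summarize_cohort(list()), class = "trtsim_invalid_input")
})

test_that("tidy and glance views expose the fit as tibbles", {
  fit <- fit_growth_rate(exp_series(), animal_id = "m1")
  td <- tidy(fit)
  expect_s3_class(td, "tbl_df")
  expect_named(td, c("animal_id", "lam_hat", "V0_hat", "n_points",
                     "window_days"))
  set.seed(5)
  noisy <- exp_series()
  noisy$volume_mm3 <- noisy$volume_mm3 * exp(rnorm(11, 0, 0.05))
  gl <- glance(fit_growth_rate(noisy))
  expect_named(gl, c("r.squared", "sigma", "lam_se", "nobs"))
  expect_gt(gl$r.squared, 0.95)
  expect_equal(gl$nobs, 11L)
})

test_that("cohort-level fitting matches per-animal fitting", {
  cohort <- generate_cohort(cohort_spec(n_per_group = 4, activities = c(0, 1),
                                        seed = 31))
  fits <- fit_growth_cohort(cohort)
  expect_equal(nrow(fits), 8L)
  expect_true(all(c("animal_id", "activity_mbq", "lam_hat", "V0_hat") %in%
                    names(fits)))
  one <- cohort[cohort$animal_id == fits$animal_id[1], ]
  expect_equal(fit_growth_rate(one)$lam_hat, fits$lam_hat[1],
               tolerance = 1e-12)
})
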
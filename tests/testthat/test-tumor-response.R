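test_that("dose-impaired regrowth rate follows lam / (1 + D^(1/4))", {
  expect_equal(lambda_mod(0.14, 0), 0.14)
  expect_equal(lambda_mod(0.14, 1), 0.07)
  expect_equal(lambda_mod(0.14, 9.7), 0.14 / (1 + 9.7^0.25), tolerance = 1e-12)
  expect_equal(lambda_mod(0.14, 9.7), 0.0506, tolerance = 1e-3)
  D <- seq(0, 30, by = 0.5)
  expect_true(all(diff(lambda_mod(0.14, D)) < 0))
  expect_error(lambda_mod(0.14, -1), class = "trtsim_invalid_input")
})

test_that("without dose the cell model grows exponentially below saturation", {
  p <- tumor_params(Nm = Inf)
  out <- simulate_cells_basic(p, dose = NULL, t_grid = seq(0, 10, by = 0.5))
  expect_equal(out$N, p$N0 * exp(p$lam * out$t_day), tolerance = 1e-8)
  expect_equal(out$N[out$t_day == 10], 2e9 * exp(1.4), tolerance = 1e-8)
})

test_that("narrow pulses converge to the impulse-survival law exp(-b D)", {
  p <- tumor_params(Nm = Inf)
  for (D in c(1, 5, 9.7, 20)) {
    # convergence as the pulse narrows at fixed total dose
    errs <- vapply(c(1e-1, 1e-2, 1e-3), function(w_day) {
      pu <- dose_pulse(D, width_h = w_day * 24)
      out <- simulate_cells_basic(p, pu, t_grid = c(0, w_day, 2 * w_day))
      abs(out$N[2] / p$N0 / exp(-p$b * D) - 1)
    }, numeric(1))
    expect_true(all(diff(errs) < 0))
    expect_lt(errs[3], 1e-3)
  }
})

test_that("halving the dose while doubling the kill coefficient preserves impulse survival", {
  w <- 1e-3
  grid <- c(0, w)
  s1 <- simulate_cells_basic(tumor_params(b = 0.3, Nm = Inf),
                             dose_pulse(10, width_h = w * 24), t_grid = grid)
  s2 <- simulate_cells_basic(tumor_params(b = 0.6, Nm = Inf),
                             dose_pulse(5, width_h = w * 24), t_grid = grid)
  expect_equal(s1$N[2], s2$N[2], tolerance = 1e-9)
})

test_that("regrowth after the dose is complete runs at the control rate", {
  p <- tumor_params(Nm = Inf)
  dp <- dose_profile(default_rates(), Q = 1, t_grid = c(0, 96))
  out <- simulate_cells_basic(p, dp, t_grid = seq(0, 20, by = 0.1))
  late <- out[out$t_day >= 10, ]
  slope <- unname(coef(lm(log(N) ~ t_day, data = late))[2])
  expect_equal(slope, p$lam, tolerance = 0.01)
})

test_that("the full model reduces to its stated limits", {
  p <- tumor_params(Nm = Inf)
  grid <- seq(0, 10, by = 0.25)

  # control limit: exact exponential volume growth
  ctrl <- simulate_full(p, dose = NULL, t_grid = grid)
  expect_equal(ctrl$V, p$V0 * exp(p$lam * grid), tolerance = 1e-6)
  expect_true(all(ctrl$N_D == 0) || max(ctrl$N_D) < 1e-6 * p$N0)

  # initial condition
  expect_equal(ctrl$V[1], p$V0)
  expect_equal(ctrl$V_D[1], 0)

  # both flags off: basic cell model scaled by the single-cell volume
  dp <- dose_profile(default_rates(), Q = 1, t_grid = c(0, 96))
  plain <- simulate_full(p, dp, t_grid = grid,
                         use_lambda_mod = FALSE, use_delay = FALSE)
  basic <- simulate_cells_basic(p, dp, t_grid = grid)
  expect_equal(plain$V, p$v * basic$N, tolerance = 1e-10)
})

test_that("volume decomposes as live plus damaged at every output point", {
  p <- tumor_params()
  dp <- dose_profile(default_rates(), Q = 1, t_grid = c(0, 96))
  out <- simulate_full(p, dp, t_grid = seq(0, 40, by = 0.5))
  expect_equal(out$V, out$V_L + out$V_D, tolerance = 1e-12)
  expect_true(all(as.matrix(out[, c("N", "N_D", "V_L", "V_D", "V")]) >= 0))
  # cumulative dose carried in the trajectory reaches the closed-form total
  expect_equal(out$cum_dose_gy[nrow(out)], total_dose(default_rates(), 1),
               tolerance = 1e-6)
})

test_that("dose-impaired regrowth sets the long-time log-slope", {
  p <- tumor_params(Nm = Inf)
  dp <- dose_profile(default_rates(), Q = 1, t_grid = c(0, 96))
  out <- simulate_full(p, dp, t_grid = seq(0, 60, by = 0.2),
                       use_lambda_mod = TRUE)
  late <- out[out$t_day >= 40, ]
  slope <- unname(coef(lm(log(N) ~ t_day, data = late))[2])
  expect_equal(slope, lambda_mod(p$lam, attr(dp, "total_gy")),
               tolerance = 1e-4)
})

test_that("literal and continuous damaged-volume forms agree on timing, not detail", {
  p <- tumor_params()
  dp <- dose_profile(default_rates(), Q = 1, t_grid = c(0, 96))
  grid <- seq(0, 40, by = 0.5)
  lit <- simulate_full(p, dp, t_grid = grid, delay_form = "literal")
  con <- simulate_full(p, dp, t_grid = grid, delay_form = "continuous")
  # same damaged pool, same long-run clearance; modest transient differences
  expect_equal(con$N, lit$N, tolerance = 1e-8)
  expect_lt(max(abs(con$V_D - lit$V_D)) / max(lit$V_D), 0.05)
})

test_that("day-40 volume is non-increasing in injected activity", {
  sc <- run_scenarios(c(0, 0.02, 0.1, 0.4, 1, 2), horizon_days = 40,
                      step_days = 0.5)
  v40 <- sc$V[sc$t_day == 40]
  expect_length(v40, 6)
  expect_true(all(diff(v40) <= 1e-8 * v40[-length(v40)]))
})

test_that("higher activity delays the volume nadir", {
  sc <- run_scenarios(c(0.1, 1), horizon_days = 40, step_days = 0.1)
  nadir <- function(Q) {
    tr <- sc[sc$activity_mbq == Q, ]
    tr$t_day[which.min(tr$V)]
  }
  expect_gt(nadir(1), nadir(0.1))
})

test_that("caliper-to-volume conversion treats the tumor as an oblate ellipsoid", {
  expect_equal(ellipsoid_volume(10, 10), pi / 6 * 1000)
  expect_equal(ellipsoid_volume(10, 10), 523.6, tolerance = 1e-3)
  d <- 7.3
  expect_equal(ellipsoid_volume(d, d), pi * d^3 / 6)
  expect_equal(ellipsoid_volume(2 * 12, 2 * 8), 8 * ellipsoid_volume(12, 8))
  expect_error(ellipsoid_volume(8, 10), class = "trtsim_invalid_input")
  expect_error(ellipsoid_volume(8, 0), class = "trtsim_invalid_input")
})

test_that("simulation grids must start at day zero", {
  expect_error(simulate_full(tumor_params(), NULL, t_grid = seq(1, 5)),
               class = "trtsim_invalid_input")
})
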
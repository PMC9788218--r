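test_that("delivery_rates derives the decay constant from the half-life", {
  r <- delivery_rates()
  expect_equal(r$y, log(2) / 7.21, tolerance = 1e-12)
  expect_equal(delivery_rates(half_life_h = 10)$y, log(2) / 10,
               tolerance = 1e-12)
  expect_error(delivery_rates(a21 = -1), class = "trtsim_invalid_input")
  expect_error(delivery_rates(half_life_h = 0), class = "trtsim_invalid_input")
  expect_error(delivery_rates(half_life_h = Inf), class = "trtsim_invalid_input")
})

test_that("numeric solution honours the bolus initial condition and zero input", {
  traj <- solve_compartments(default_rates(), Q = 1, t_grid = c(0, 1, 2))
  expect_equal(unlist(traj[1, c("R1", "R2", "R3", "R4")]),
               c(R1 = 1, R2 = 0, R3 = 0, R4 = 0))

  zero <- solve_compartments(default_rates(), Q = 0, t_grid = c(0, 5, 10))
  expect_true(all(as.matrix(zero[, c("R1", "R2", "R3", "R4", "RT")]) == 0))
})

test_that("total activity follows pure physical decay (mass balance)", {
  r <- default_rates()
  traj <- solve_compartments(r, Q = 1, t_grid = seq(0, 10, by = 0.5))
  expect_equal(traj$RT[traj$t_h == 10], exp(-r$y * 10), tolerance = 1e-8)
  expect_equal(traj$RT, exp(-r$y * traj$t_h), tolerance = 1e-8)
})

test_that("mass balance, non-negativity and excretion monotonicity hold for random rates", {
  set.seed(421)
  grid <- seq(0, 48, by = 0.25)
  for (i in 1:20) {
    r <- random_rates()
    traj <- solve_compartments(r, Q = 1, t_grid = grid)
    expect_equal(traj$RT, exp(-r$y * grid), tolerance = 1e-8)
    expect_true(all(as.matrix(traj[, c("R1", "R2", "R3", "R4")]) >= 0))
    # decay-corrected excretion can only accumulate
    expect_true(all(diff(traj$R4 * exp(r$y * grid)) >= -1e-10))
  }
})

test_that("closed-form no-return solution matches its stated limits", {
  r <- no_return_rates()
  at0 <- analytic_no_return(r, Q = 1, t = 0)
  expect_equal(unlist(at0[1, c("R1", "R2", "R3", "R4")]),
               c(R1 = 1, R2 = 0, R3 = 0, R4 = 0))

  # decay-corrected tumor activity plateaus at a12 / B
  B <- r$a12 + r$a13 + r$a14
  late <- analytic_no_return(r, Q = 1, t = 200)
  expect_equal(late$R2 * exp(r$y * 200), r$a12 / B, tolerance = 1e-6)
  expect_equal(r$a12 / B, 0.33 / 1.83, tolerance = 1e-12)

  # stored return coefficients are ignored by construction
  with_returns <- analytic_no_return(default_rates(), Q = 1, t = c(0, 3, 24))
  plain <- analytic_no_return(r, Q = 1, t = c(0, 3, 24))
  expect_equal(as.data.frame(with_returns), as.data.frame(plain))

  expect_error(analytic_no_return(delivery_rates(a12 = 0, a13 = 0, a14 = 0),
                                  Q = 1, t = 1),
               class = "trtsim_degenerate_model")
})

test_that("numeric solver reproduces the closed form when return paths vanish", {
  r <- no_return_rates()
  grid <- seq(0, 48, by = 0.1)
  num <- solve_compartments(r, Q = 1, t_grid = grid)
  ana <- analytic_no_return(r, Q = 1, t = grid)
  for (col in c("R1", "R2", "R3", "R4")) {
    expect_lt(max(abs(num[[col]] - ana[[col]])), 1e-6)
  }
})

test_that("decay-corrected tumor fraction rises monotonically to its plateau", {
  r <- default_rates()
  B <- r$a12 + r$a13 + r$a14
  expect_equal(renormalized_tumor_fraction(r, 0), 0)
  expect_equal(renormalized_tumor_fraction(r, 24), 0.33 / 1.83 *
                 (1 - exp(-1.83 * 24)), tolerance = 1e-12)
  # plateau nearly reached by 24 h
  expect_equal(renormalized_tumor_fraction(r, 24), 0.1803,
               tolerance = 1e-3)
  frac <- renormalized_tumor_fraction(r, seq(0, 100, 0.5))
  expect_true(all(diff(frac) >= 0))
  expect_true(all(frac <= r$a12 / B + 1e-15))
  expect_error(renormalized_tumor_fraction(r, -1),
               class = "trtsim_invalid_input")
})

test_that("invalid grids and activities are rejected", {
  r <- default_rates()
  expect_error(solve_compartments(r, Q = -1, t_grid = c(0, 1)),
               class = "trtsim_invalid_input")
  expect_error(solve_compartments(r, Q = 1, t_grid = c(1, 2)),
               class = "trtsim_invalid_input")
  expect_error(solve_compartments(r, Q = 1, t_grid = c(0, 2, 1)),
               class = "trtsim_invalid_input")
  expect_error(analytic_no_return(r, Q = 1, t = -3),
               class = "trtsim_invalid_input")
})
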
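#' Solve the four-compartment delivery model numerically
#'
#' Integrates the linear ODE system for the activity in blood (`R1`), tumor
#' (`R2`), body organs (`R3`), and excretion (`R4`) after a bolus intravenous
#' injection of activity `Q` into blood at time 0:
#' \deqn{dR_1/dt = -(a_{12}+a_{13}+a_{14}+y) R_1 + a_{21} R_2 + a_{31} R_3}
#' \deqn{dR_2/dt = a_{12} R_1 - (a_{21}+y) R_2}
#' \deqn{dR_3/dt = a_{13} R_1 - (a_{31}+y) R_3}
#' \deqn{dR_4/dt = a_{14} R_1 - y R_4}
#' The total activity `RT = R1+R2+R3+R4` decays as `Q * exp(-y*t)`, which the
#' solver is required to honour to high accuracy (mass balance).
#'
#' Activities are carried in the same unit as `Q` (MBq); the number of atoms
#' is proportional to activity, and the proportionality constant cancels in
#' every downstream use.
#'
#' @param rates A [delivery_rates()] object.
#' @param Q Injected activity in MBq (non-negative scalar).
#' @param t_grid Reporting time grid in hours: strictly increasing, starting
#'   at 0. Default 0 to 48 h in 0.01 h steps.
#' @param rtol,atol Relative and absolute solver tolerances passed to
#'   [deSolve::lsoda()]. Numerical undershoot below `-atol` is an error;
#'   values in `[-atol, 0)` are clamped to 0.
#'
#' @return A tibble of class `compartment_trajectory` with columns `t_h`,
#'   `R1`, `R2`, `R3`, `R4` (MBq) and the total `RT`.
#' @seealso [analytic_no_return()] for the closed form without return paths.
#' @examples
#' traj <- solve_compartments(delivery_rates(), Q = 1, t_grid = seq(0, 48, 0.5))
#' head(traj)
#' @export
solve_compartments <- function(rates, Q = 1,
                               t_grid = seq(0, 48, by = 0.01),
                               rtol = 1e-10, atol = 1e-12) {
  assert_delivery_rates(rates)
  check_activity(Q)
  check_time_grid(t_grid)

  if (Q == 0) {
    return(new_compartment_trajectory(t_grid, 0 * t_grid, 0 * t_grid,
                                      0 * t_grid, 0 * t_grid))
  }

  y <- rates$y
  deriv <- function(t, state, parms) {
    R1 <- state[1]; R2 <- state[2]; R3 <- state[3]; R4 <- state[4]
    with(rates, list(c(
      -(a12 + a13 + a14 + y) * R1 + a21 * R2 + a31 * R3,
      a12 * R1 - (a21 + y) * R2,
      a13 * R1 - (a31 + y) * R3,
      a14 * R1 - y * R4
    )))
  }
  out <- deSolve::lsoda(
    y = c(R1 = Q, R2 = 0, R3 = 0, R4 = 0),
    times = t_grid, func = deriv, parms = NULL,
    rtol = rtol, atol = atol
  )
  R <- lapply(c("R1", "R2", "R3", "R4"), function(nm) {
    clamp_negatives(out[, nm], atol = atol, what = nm)
  })
  new_compartment_trajectory(t_grid, R[[1]], R[[2]], R[[3]], R[[4]])
}

#' Closed-form compartment activities without return paths
#'
#' Evaluates the analytic solution of the delivery model when both return
#' coefficients (`a21`, `a31`) are zero. With `A = a12 + a13 + a14 + y` (total
#' loss rate from blood) and `B = a12 + a13 + a14` (transfer only):
#' \deqn{R_1(t) = Q e^{-A t}, \qquad
#'       R_i(t) = Q \frac{a_{1i}}{B} (1 - e^{-B t}) e^{-y t}, \quad i = 2,3,4.}
#' Any non-zero `a21`/`a31` stored in `rates` is ignored by construction; the
#' closed form is the no-return model.
#'
#' @inheritParams solve_compartments
#' @param t Evaluation times in hours (vector, non-negative).
#'
#' @return A tibble of class `compartment_trajectory` with columns `t_h`,
#'   `R1`..`R4`, `RT`.
#' @examples
#' analytic_no_return(delivery_rates(), Q = 1, t = c(0, 3, 24))
#' @export
analytic_no_return <- function(rates, Q = 1, t) {
  assert_delivery_rates(rates)
  check_activity(Q)
  if (any(!is.finite(t)) || any(t < 0)) {
    abort("`t` must be non-negative and finite.", class = "trtsim_invalid_input")
  }
  s <- rate_sums(rates)
  if (s$B == 0) {
    abort("Degenerate model: a12 + a13 + a14 == 0, no transfer out of blood.",
          class = "trtsim_degenerate_model")
  }
  R1 <- Q * exp(-s$A * t)
  grow <- (1 - exp(-s$B * t)) * exp(-rates$y * t) / s$B
  new_compartment_trajectory(
    t, R1,
    Q * rates$a12 * grow,
    Q * rates$a13 * grow,
    Q * rates$a14 * grow
  )
}

#' Decay-corrected tumor uptake fraction
#'
#' Ratio of the tumor activity to the pure physical-decay curve of the
#' radionuclide, `R2(t) / (Q * exp(-y*t))`, using the no-return closed form
#' (the injected activity `Q` cancels):
#' \deqn{f(t) = \frac{a_{12}}{B}\,(1 - e^{-B t}).}
#' The fraction rises monotonically from 0 towards the plateau `a12 / B`,
#' the asymptotic share of transferred material that ends up in the tumor.
#'
#' @inheritParams analytic_no_return
#' @return A numeric vector, one dimensionless fraction per time point.
#' @examples
#' renormalized_tumor_fraction(delivery_rates(), t = c(0, 3, 24))
#' @export
renormalized_tumor_fraction <- function(rates, t) {
  assert_delivery_rates(rates)
  if (any(!is.finite(t)) || any(t < 0)) {
    abort("`t` must be non-negative and finite.", class = "trtsim_invalid_input")
  }
  s <- rate_sums(rates)
  if (s$B == 0) {
    abort("Degenerate model: a12 + a13 + a14 == 0, no transfer out of blood.",
          class = "trtsim_degenerate_model")
  }
  rates$a12 / s$B * (1 - exp(-s$B * t))
}

new_compartment_trajectory <- function(t, R1, R2, R3, R4) {
  out <- tibble(t_h = as.numeric(t), R1 = R1, R2 = R2, R3 = R3, R4 = R4,
                RT = R1 + R2 + R3 + R4)
  class(out) <- c("compartment_trajectory", class(out))
  out
}

check_activity <- function(Q, arg = "Q") {
  if (!is.numeric(Q) || length(Q) != 1L || is.na(Q) || Q < 0 || !is.finite(Q)) {
    abort(sprintf("`%s` must be a single non-negative activity in MBq.", arg),
          class = "trtsim_invalid_input")
  }
  invisible(Q)
}

check_time_grid <- function(t_grid, start_at = 0, unit = "hours") {
  if (!is.numeric(t_grid) || length(t_grid) < 2L || any(!is.finite(t_grid))) {
    abort("`t_grid` must be a finite numeric vector with at least 2 points.",
          class = "trtsim_invalid_input")
  }
  if (t_grid[1] != start_at) {
    abort(sprintf("`t_grid` must start at %g %s.", start_at, unit),
          class = "trtsim_invalid_input")
  }
  if (any(diff(t_grid) <= 0)) {
    abort("`t_grid` must be strictly increasing.",
          class = "trtsim_invalid_input")
  }
  invisible(t_grid)
}

# tolerate (and zero) solver undershoot within -atol; larger undershoot is a bug
clamp_negatives <- function(x, atol, what) {
  if (any(x < -atol)) {
    abort(sprintf("Solver produced %s < -atol (min %.3g); integration failed.",
                  what, min(x)),
          class = "trtsim_solver_failure")
  }
  pmax(x, 0)
}
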
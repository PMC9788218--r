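#' Dose-impaired regrowth rate
#'
#' The tumor growth rate after irradiation, reduced by the cumulative dose
#' received so far:
#' \deqn{\lambda_{mod}(D) = \frac{\lambda}{1 + D^{1/4}}.}
#' Equal to `lam` at zero dose and strictly decreasing in `D`; the quarter
#' power makes the impairment saturate slowly, so even large doses leave a
#' residual growth capacity.
#'
#' @param lam Unirradiated growth rate, per day.
#' @param D Cumulative absorbed dose in Gy (vector, non-negative).
#' @return Modified growth rate(s), per day.
#' @examples
#' lambda_mod(0.14, c(0, 1, 9.7))
#' @export
lambda_mod <- function(lam, D) {
  if (any(!is.finite(D)) || any(D < 0)) {
    abort("`D` must be non-negative and finite.",
          class = "trtsim_invalid_input")
  }
  lam / (1 + D^0.25)
}

#' Simulate proliferating-cell numbers under irradiation (basic model)
#'
#' Integrates the logistic growth-with-kill equation
#' \deqn{dN/dt = (\lambda - b\,d(t))\,N\,(1 - N/N_m),}
#' where `d(t)` is the tumor dose rate in Gy/day derived from the dose
#' profile (supplied per hour by the dosimetry layer and converted at this
#' module boundary). With no dose and `N` well below `Nm` this reduces to
#' exponential growth at rate `lam`. The saturation bracket multiplies the
#' whole net-rate term, kill included, as the model is written.
#'
#' @param p A [tumor_params()] object.
#' @param dose A `dose_profile` (from [dose_profile()], [dose_pulse()] or
#'   [superpose_schedule()]), or `NULL` for an untreated control. The profile
#'   is zero-extended after its last point.
#' @param t_grid Reporting grid in days, starting at 0.
#' @param rtol,atol Solver tolerances.
#' @return A tibble with columns `t_day`, `N`, and `cum_dose_gy`.
#' @examples
#' simulate_cells_basic(tumor_params(), dose = NULL, t_grid = seq(0, 10, 0.5))
#' @export
simulate_cells_basic <- function(p, dose = NULL, t_grid = seq(0, 20, by = 0.1),
                                 rtol = 1e-10, atol = 1e-10) {
  traj <- simulate_full(p, dose = dose, t_grid = t_grid,
                        use_lambda_mod = FALSE, use_delay = FALSE,
                        rtol = rtol, atol = atol)
  tibble(t_day = traj$t_day, N = traj$N, cum_dose_gy = traj$cum_dose_gy)
}

#' Simulate tumor cell numbers and volume under a radiation dose profile
#'
#' The full tumor-response model. Proliferating cells `N` follow logistic
#' growth with a radiation kill term,
#' \deqn{dN/dt = (\lambda_{eff}(t) - b\,d(t))\,N\,(1 - N/N_m),}
#' with \eqn{\lambda_{eff}} either the constant `lam` or the dose-impaired
#' [lambda_mod()] of the cumulative dose `D(t)` (flag `use_lambda_mod`).
#' Cells killed by radiation accumulate in a damaged, non-proliferating pool
#' \deqn{dN_D/dt = b\,d(t)\,N,}
#' whose volume is cleared slowly: in the default (literal) form
#' \deqn{V_D(t) = v\,N_D(t)\,e^{-c (t - t_0)},}
#' valid because the irradiation (well under a day for astatine-211) is much
#' shorter than the clearance time `1/c` (about 10 days). The alternative
#' `delay_form = "continuous"` integrates `dV_D/dt = v b d N - c V_D` instead,
#' which ages each damaged cohort from its own creation time; it is provided
#' for sensitivity checks. Live volume is `V_L = v N` and the measured tumor
#' volume is `V = V_L + V_D` (with `use_delay = FALSE`, `V_D` is dropped and
#' `V = V_L`).
#'
#' @inheritParams simulate_cells_basic
#' @param use_lambda_mod Apply the dose-dependent regrowth impairment
#'   [lambda_mod()]?
#' @param use_delay Track the damaged-cell volume pool `V_D`? With both flags
#'   off the model is the basic kill model scaled to volume by `v`.
#' @param delay_form `"literal"` (closed-form decay of the damaged pool,
#'   the model as written) or `"continuous"` (ODE form, see Details).
#' @return A tibble of class `tumor_trajectory` with columns `t_day`, `N`,
#'   `N_D`, `V_L`, `V_D`, `V` (mm3), and `cum_dose_gy`.
#' @examples
#' dp <- dose_profile(delivery_rates(), Q = 1, t_grid = c(0, 96))
#' simulate_full(tumor_params(), dp, t_grid = seq(0, 40, 2))
#' @export
simulate_full <- function(p, dose = NULL, t_grid = seq(0, 40, by = 0.1),
                          use_lambda_mod = TRUE, use_delay = TRUE,
                          delay_form = c("literal", "continuous"),
                          rtol = 1e-10, atol = 1e-10) {
  assert_tumor_params(p)
  check_time_grid(t_grid, unit = "days")
  delay_form <- match.arg(delay_form)
  df <- dose_fn_per_day(dose)

  lam <- p$lam; b <- p$b; Nm <- p$Nm; v <- p$v
  sat <- if (is.finite(Nm)) function(N) 1 - N / Nm else function(N) 1
  deriv <- function(t, state, parms) {
    N <- state[1]
    d <- df$rate(t)
    D <- state[3]
    lam_eff <- if (use_lambda_mod) lam / (1 + max(D, 0)^0.25) else lam
    dN <- (lam_eff - b * d) * N * sat(N)
    dND <- b * d * N
    dD <- d
    derivs <- c(dN, dND, dD)
    if (delay_form == "continuous") {
      derivs <- c(derivs, v * b * d * N - p$c * state[4])
    }
    list(derivs)
  }

  state0 <- c(N = p$N0, ND = 0, D = 0)
  if (delay_form == "continuous") state0 <- c(state0, VD = 0)
  out <- integrate_segments(deriv, state0, t_grid, breaks = df$breaks,
                            rtol = rtol, atol = atol)

  N <- pmax(out[, "N"], 0)
  ND <- pmax(out[, "ND"], 0)
  D <- pmax(out[, "D"], 0)
  V_L <- v * N
  V_D <- if (!use_delay) {
    rep(0, length(t_grid))
  } else if (delay_form == "literal") {
    v * ND * exp(-p$c * (t_grid - p$t0))
  } else {
    pmax(out[, "VD"], 0)
  }
  res <- tibble(t_day = as.numeric(t_grid), N = N, N_D = ND,
                V_L = V_L, V_D = V_D, V = V_L + V_D, cum_dose_gy = D)
  class(res) <- c("tumor_trajectory", class(res))
  res
}

#' Run the dose-response scenario family
#'
#' Simulates one tumor trajectory per injected activity with shared
#' parameters, reproducing the dose-response curve family (control plus
#' treated groups, including extrapolated activities outside the experimental
#' range).
#'
#' @param activities Injected activities in MBq (non-negative vector); the
#'   experimental groups were 0, 0.1, 0.4 and 1 MBq, with 0.02 and 2 MBq as
#'   model extrapolations.
#' @param rates A [delivery_rates()] object.
#' @param conv A [dose_conversion()] object.
#' @param p A [tumor_params()] object.
#' @param horizon_days Simulation horizon in days.
#' @param step_days Reporting step in days.
#' @param ... Further arguments passed to [simulate_full()] (flags,
#'   tolerances).
#' @return A tibble of class `trt_scenarios`: the row-bound trajectories with
#'   a leading `activity_mbq` column.
#' @examples
#' sc <- run_scenarios(c(0, 0.1, 1), horizon_days = 20, step_days = 1)
#' dplyr::filter(sc, t_day == 20)
#' @export
run_scenarios <- function(activities = c(0, 0.02, 0.1, 0.4, 1, 2),
                          rates = delivery_rates(),
                          conv = dose_conversion(),
                          p = tumor_params(),
                          horizon_days = 40, step_days = 0.1, ...) {
  if (any(!is.finite(activities)) || any(activities < 0)) {
    abort("`activities` must be non-negative and finite.",
          class = "trtsim_invalid_input")
  }
  t_grid <- seq(0, horizon_days, by = step_days)
  out <- purrr::map_dfr(activities, function(Q) {
    dose <- if (Q > 0) {
      dose_profile(rates, Q = Q, conv = conv, t_grid = c(0, 96))
    } else {
      NULL
    }
    traj <- simulate_full(p, dose = dose, t_grid = t_grid, ...)
    dplyr::bind_cols(tibble(activity_mbq = Q), traj)
  })
  class(out) <- c("trt_scenarios", class(out))
  out
}

#' Tumor volume from caliper measurements (oblate ellipsoid)
#'
#' Converts two-axis caliper measurements to a volume assuming an oblate
#' ellipsoid with the long axis duplicated:
#' \deqn{V = \frac{\pi}{6} L^2 W.}
#' For `L = W = d` this is the volume of a sphere of diameter `d`; a 10 mm
#' tumor is about 524 mm3, the scale at which treatment started in the
#' xenograft experiment.
#'
#' @param length_mm Longest tumor axis, mm (vector).
#' @param width_mm Perpendicular axis, mm; must not exceed `length_mm`.
#' @return Tumor volume(s) in mm3.
#' @examples
#' ellipsoid_volume(10, 10) # ~523.6 mm3
#' @export
ellipsoid_volume <- function(length_mm, width_mm) {
  if (any(!is.finite(length_mm)) || any(!is.finite(width_mm)) ||
      any(width_mm <= 0)) {
    abort("Axes must be finite and `width_mm` positive.",
          class = "trtsim_invalid_input")
  }
  if (any(width_mm > length_mm)) {
    abort("`width_mm` must not exceed `length_mm` (length is the long axis).",
          class = "trtsim_invalid_input")
  }
  pi / 6 * length_mm^2 * width_mm
}

# Dose rate in Gy/day as a function of time in days, plus the times (days)
# where the rate is non-smooth (pulse edges, injection times). The dosimetry
# layer works in hours; this boundary converts once: d_day(t) = 24 * d_h(24 t).
dose_fn_per_day <- function(dose) {
  if (is.null(dose)) {
    return(list(rate = function(t) 0, breaks = numeric(0), total = 0))
  }
  if (!inherits(dose, "dose_profile")) {
    abort("`dose` must be a `dose_profile` (or NULL for an untreated control).",
          class = "trtsim_invalid_input")
  }
  rate_h <- attr(dose, "rate_fn_h")
  if (is.null(rate_h)) {
    rate_h <- approxfun(dose$t_h, dose$dose_rate_gy_h, yleft = 0, yright = 0)
  }
  breaks_h <- attr(dose, "breaks_h") %||% numeric(0)
  list(
    rate = function(t) 24 * rate_h(24 * t),
    breaks = breaks_h / 24,
    total = attr(dose, "total_gy") %||% NA_real_
  )
}

# lsoda restarted at each non-smooth point of the forcing so sharp pulses are
# never stepped over by the adaptive integrator.
integrate_segments <- function(deriv, state0, t_grid, breaks = numeric(0),
                               rtol, atol) {
  t_end <- t_grid[length(t_grid)]
  breaks <- breaks[breaks > 0 & breaks < t_end]
  edges <- sort(unique(c(t_grid[1], breaks, t_end)))
  rows <- matrix(state0, nrow = 1,
                 dimnames = list(NULL, names(state0)))
  out_t <- t_grid[1]
  state <- state0
  for (i in seq_len(length(edges) - 1L)) {
    a <- edges[i]; bnd <- edges[i + 1L]
    inner <- t_grid[t_grid > a & t_grid < bnd]
    times <- unique(c(a, inner, bnd))
    seg <- deSolve::lsoda(y = state, times = times, func = deriv,
                          parms = NULL, rtol = rtol, atol = atol)
    state <- setNames(as.numeric(seg[nrow(seg), -1]), names(state0))
    keep <- seg[-1, , drop = FALSE]
    keep <- keep[keep[, "time"] %in% t_grid, , drop = FALSE]
    if (nrow(keep)) {
      rows <- rbind(rows, keep[, -1, drop = FALSE])
      out_t <- c(out_t, unname(keep[, "time"]))
    }
  }
  stopifnot(isTRUE(all.equal(as.numeric(out_t), as.numeric(t_grid))))
  rows
}

`%||%` <- function(a, b) if (is.null(a)) b else a
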
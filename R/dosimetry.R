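#' Activity-to-dose-rate conversion for the tumor
#'
#' Conversion constant turning tumor activity (MBq) into absorbed dose rate
#' (Gy/h). The default, 5.45 Gy per hour per MBq for a 1.5 g tumor, is the
#' published calibration for astatine-211 in this xenograft system and is
#' treated as a configuration value, not derived from alpha-particle energies.
#'
#' @param gy_per_h_per_mbq Dose rate in the tumor per unit tumor activity
#'   (Gy/h/MBq, positive).
#' @param tumor_mass_g Tumor mass the constant refers to, in grams
#'   (informational only).
#' @return An object of class `dose_conversion`.
#' @examples
#' dose_conversion()
#' @export
dose_conversion <- function(gy_per_h_per_mbq = 5.45, tumor_mass_g = 1.5) {
  if (!is.numeric(gy_per_h_per_mbq) || length(gy_per_h_per_mbq) != 1L ||
      is.na(gy_per_h_per_mbq) || gy_per_h_per_mbq <= 0) {
    abort("`gy_per_h_per_mbq` must be a single positive number.",
          class = "trtsim_invalid_input")
  }
  if (!is.numeric(tumor_mass_g) || length(tumor_mass_g) != 1L ||
      is.na(tumor_mass_g) || tumor_mass_g <= 0) {
    abort("`tumor_mass_g` must be a single positive number.",
          class = "trtsim_invalid_input")
  }
  structure(list(gy_per_h_per_mbq = gy_per_h_per_mbq,
                 tumor_mass_g = tumor_mass_g),
            class = "dose_conversion")
}

#' @export
print.dose_conversion <- function(x, ...) {
  cat(sprintf("<dose_conversion> %g Gy/h per MBq in a %g g tumor\n",
              x$gy_per_h_per_mbq, x$tumor_mass_g))
  invisible(x)
}

assert_dose_conversion <- function(conv) {
  if (!inherits(conv, "dose_conversion")) {
    abort("`conv` must be created with `dose_conversion()`.",
          class = "trtsim_invalid_input")
  }
  invisible(conv)
}

#' Time-integrated tumor activity
#'
#' Closed-form integral of the no-return tumor activity curve over all time,
#' \deqn{\int_0^\infty R_2(t)\,dt = Q\,\frac{a_{12}}{B}
#'   \left(\frac1y - \frac1A\right) = \frac{Q\,a_{12}}{y\,A},}
#' in MBq·h. This is the quantity that, multiplied by the dose-rate
#' conversion constant, gives the total absorbed dose in the tumor.
#'
#' @inheritParams solve_compartments
#' @return Time-integrated activity in MBq·h (scalar).
#' @examples
#' integrated_tumor_activity(delivery_rates(), Q = 1) # ~1.78 MBq h
#' @export
integrated_tumor_activity <- function(rates, Q = 1) {
  assert_delivery_rates(rates)
  check_activity(Q)
  s <- rate_sums(rates)
  if (rates$y <= 0) {
    abort("Divergent integral: decay rate `y` must be positive.",
          class = "trtsim_degenerate_model")
  }
  Q * rates$a12 / (rates$y * s$A)
}

#' Total absorbed dose in the tumor
#'
#' Total dose (Gy) delivered to the tumor over all time for a single bolus
#' injection: the closed-form time-integrated tumor activity multiplied by
#' the activity-to-dose-rate conversion constant. With the default transfer
#' coefficients and conversion this gives 9.7 Gy for 1 MBq of astatine-211.
#'
#' @inheritParams solve_compartments
#' @param conv A [dose_conversion()] object.
#' @return Total absorbed dose in Gy (scalar).
#' @examples
#' total_dose(delivery_rates(), Q = 1) # 9.7 Gy
#' total_dose(delivery_rates(), Q = 0.1) # 0.97 Gy
#' @export
total_dose <- function(rates, Q = 1, conv = dose_conversion()) {
  assert_dose_conversion(conv)
  conv$gy_per_h_per_mbq * integrated_tumor_activity(rates, Q)
}

#' Tumor dose-rate and cumulative-dose profile
#'
#' Computes the absorbed dose rate in the tumor,
#' `d(t) = gy_per_h_per_mbq * R2(t)`, and its running integral `D(t)` on a
#' reporting grid. By default `R2` is the no-return closed form and `D(t)` is
#' its exact partial integral; `method = "numeric"` instead solves the full
#' four-box model (return paths included) and integrates by the trapezoid
#' rule.
#'
#' @inheritParams total_dose
#' @param t_grid Reporting grid in hours, starting at 0.
#' @param method `"analytic"` (no-return closed form, exact cumulative
#'   integral) or `"numeric"` (full ODE solution, trapezoid cumulative).
#' @return A tibble of class `dose_profile` with columns `t_h`,
#'   `dose_rate_gy_h`, and `cum_dose_gy`. The attribute `total_gy` holds the
#'   closed-form dose at infinite time; attributes `rate_fn_h` and `cum_fn_h`
#'   hold vectorised functions of time (hours) used by the tumor-response
#'   simulator.
#' @examples
#' dp <- dose_profile(delivery_rates(), Q = 1, t_grid = seq(0, 48, 0.5))
#' attr(dp, "total_gy")
#' @export
dose_profile <- function(rates, Q = 1, conv = dose_conversion(),
                         t_grid = seq(0, 48, by = 0.01),
                         method = c("analytic", "numeric")) {
  assert_delivery_rates(rates)
  assert_dose_conversion(conv)
  check_activity(Q)
  check_time_grid(t_grid)
  method <- match.arg(method)
  k <- conv$gy_per_h_per_mbq
  total <- k * integrated_tumor_activity(rates, Q)

  if (method == "analytic") {
    s <- rate_sums(rates)
    if (s$B == 0) {
      abort("Degenerate model: a12 + a13 + a14 == 0, no transfer out of blood.",
            class = "trtsim_degenerate_model")
    }
    rate_fn <- function(t) {
      out <- numeric(length(t))
      pos <- t >= 0
      tp <- t[pos]
      out[pos] <- k * Q * rates$a12 / s$B *
        (exp(-rates$y * tp) - exp(-s$A * tp))
      out
    }
    # exact partial integral of (e^{-yt} - e^{-At})
    cum_fn <- function(t) {
      out <- numeric(length(t))
      pos <- t >= 0
      tp <- t[pos]
      out[pos] <- k * Q * rates$a12 / s$B *
        ((1 - exp(-rates$y * tp)) / rates$y - (1 - exp(-s$A * tp)) / s$A)
      out
    }
    d <- rate_fn(t_grid)
    D <- cum_fn(t_grid)
  } else {
    traj <- solve_compartments(rates, Q = Q, t_grid = t_grid)
    d <- k * traj$R2
    D <- cum_trapezoid(t_grid, d)
    rate_fn <- approxfun(t_grid, d, yleft = 0, yright = 0)
    cum_fn <- approxfun(t_grid, D, yleft = 0, yright = D[length(D)])
  }
  new_dose_profile(t_grid, d, D,
                   rate_fn_h = rate_fn, cum_fn_h = cum_fn,
                   total_gy = total, breaks_h = numeric(0))
}

#' Idealised rectangular dose pulse
#'
#' A dose profile that delivers a fixed total dose at constant rate over a
#' short window. Used to study the impulse limit of the kill model: as the
#' width shrinks at fixed total dose, the surviving fraction of proliferating
#' cells converges to `exp(-b * dose_gy)`.
#'
#' @param dose_gy Total dose delivered by the pulse (Gy, non-negative).
#' @param width_h Pulse duration in hours (positive).
#' @param onset_h Start of the pulse in hours (non-negative).
#' @param t_grid Optional reporting grid (hours); defaults to a grid that
#'   resolves the pulse.
#' @return A `dose_profile` tibble (see [dose_profile()]).
#' @examples
#' dose_pulse(5, width_h = 0.024) # 5 Gy over ~1.4 min
#' @export
dose_pulse <- function(dose_gy, width_h, onset_h = 0, t_grid = NULL) {
  if (!is.numeric(dose_gy) || length(dose_gy) != 1L || is.na(dose_gy) ||
      dose_gy < 0) {
    abort("`dose_gy` must be a single non-negative dose in Gy.",
          class = "trtsim_invalid_input")
  }
  if (!is.numeric(width_h) || length(width_h) != 1L || is.na(width_h) ||
      width_h <= 0) {
    abort("`width_h` must be a single positive duration in hours.",
          class = "trtsim_invalid_input")
  }
  if (!is.numeric(onset_h) || length(onset_h) != 1L || is.na(onset_h) ||
      onset_h < 0) {
    abort("`onset_h` must be a single non-negative time in hours.",
          class = "trtsim_invalid_input")
  }
  rate <- dose_gy / width_h
  t_on <- onset_h
  t_off <- onset_h + width_h
  rate_fn <- function(t) ifelse(t >= t_on & t < t_off, rate, 0)
  cum_fn <- function(t) rate * pmin(pmax(t - t_on, 0), width_h)
  if (is.null(t_grid)) {
    t_grid <- sort(unique(c(seq(0, t_off * 2 + 1, length.out = 201L),
                            t_on, t_off)))
  } else {
    check_time_grid(t_grid)
  }
  new_dose_profile(t_grid, rate_fn(t_grid), cum_fn(t_grid),
                   rate_fn_h = rate_fn, cum_fn_h = cum_fn,
                   total_gy = dose_gy, breaks_h = c(t_on, t_off))
}

#' Dose profile for a multi-injection schedule
#'
#' Linear superposition of single-injection dose profiles, one per row of the
#' schedule, each time-shifted to its injection time. Linearity of the
#' delivery ODE makes the superposition exact; the total dose is the sum of
#' the single-injection totals.
#'
#' @param schedule A data frame with columns `time_h` (injection times, hours,
#'   non-negative) and `activity_mbq` (injected activities, MBq,
#'   non-negative). Rows are sorted internally by time.
#' @inheritParams dose_profile
#' @return A `dose_profile` tibble covering `t_grid`, with attribute
#'   `total_gy` equal to the summed single-injection totals.
#' @examples
#' sched <- data.frame(time_h = c(0, 240), activity_mbq = c(1, 1))
#' dp <- superpose_schedule(sched, delivery_rates(), dose_conversion(),
#'                          t_grid = seq(0, 480, 1))
#' attr(dp, "total_gy") # twice the single-injection dose
#' @export
superpose_schedule <- function(schedule, rates, conv = dose_conversion(),
                               t_grid = seq(0, 480, by = 0.1)) {
  assert_delivery_rates(rates)
  assert_dose_conversion(conv)
  check_time_grid(t_grid)
  if (!is.data.frame(schedule) ||
      !all(c("time_h", "activity_mbq") %in% names(schedule)) ||
      nrow(schedule) < 1L) {
    abort("`schedule` must be a data frame with columns `time_h` and `activity_mbq`.",
          class = "trtsim_invalid_input")
  }
  if (any(!is.finite(schedule$time_h)) || any(schedule$time_h < 0)) {
    abort("Injection times must be non-negative and finite.",
          class = "trtsim_invalid_input")
  }
  if (any(!is.finite(schedule$activity_mbq)) || any(schedule$activity_mbq < 0)) {
    abort("Injected activities must be non-negative and finite.",
          class = "trtsim_invalid_input")
  }
  schedule <- schedule[order(schedule$time_h), , drop = FALSE]

  parts <- purrr::pmap(
    list(schedule$time_h, schedule$activity_mbq),
    function(t0, Q) {
      single <- dose_profile(rates, Q = Q, conv = conv,
                             t_grid = c(0, max(t_grid) + 1))
      list(
        rate = function(t) attr(single, "rate_fn_h")(t - t0),
        cum = function(t) attr(single, "cum_fn_h")(pmax(t - t0, 0)),
        total = attr(single, "total_gy"),
        t0 = t0
      )
    }
  )
  rate_fn <- function(t) Reduce(`+`, lapply(parts, function(p) p$rate(t)))
  cum_fn <- function(t) Reduce(`+`, lapply(parts, function(p) p$cum(t)))
  new_dose_profile(t_grid, rate_fn(t_grid), cum_fn(t_grid),
                   rate_fn_h = rate_fn, cum_fn_h = cum_fn,
                   total_gy = sum(purrr::map_dbl(parts, "total")),
                   breaks_h = sort(unique(schedule$time_h)))
}

new_dose_profile <- function(t_h, d, D, rate_fn_h, cum_fn_h, total_gy,
                             breaks_h) {
  out <- tibble(t_h = as.numeric(t_h), dose_rate_gy_h = d, cum_dose_gy = D)
  class(out) <- c("dose_profile", class(out))
  attr(out, "rate_fn_h") <- rate_fn_h
  attr(out, "cum_fn_h") <- cum_fn_h
  attr(out, "total_gy") <- total_gy
  attr(out, "breaks_h") <- breaks_h
  out
}

cum_trapezoid <- function(t, y) {
  c(0, cumsum(diff(t) * (head(y, -1) + tail(y, -1)) / 2))
}
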
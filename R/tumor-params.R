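#' Tumor growth and radiation-response parameters
#'
#' Parameters of the tumor-response model, in day/Gy/mm3 units:
#' exponential/logistic growth rate `lam` (per day), radiation kill
#' coefficient `b` (per Gy), damaged-volume clearance rate `c` (per day) with
#' reference time `t0` (days), initial proliferating-cell count `N0`,
#' carrying-capacity count `Nm`, and initial tumor volume `V0` (mm3). The
#' apparent single-cell volume `v = V0 / N0` ties cell counts to volume, and
#' the volume carrying capacity is `Vm = v * Nm`.
#'
#' Defaults are the values used for the astatine-211 thyroid-cancer xenograft
#' analysis: `lam = 0.14`/day (cohort mean of the control regression),
#' `b = 0.3`/Gy, `c = 0.1`/day, `t0 = 0`, `N0 = 2e9`, `Nm = 4e10`, and
#' `V0 = 577` mm3 (cohort mean initial volume). `Nm = Inf` switches off the
#' logistic saturation (pure exponential regime).
#'
#' @param lam Tumor growth rate, per day (non-negative).
#' @param b Kill coefficient, per Gy (non-negative).
#' @param c Damaged-volume clearance rate, per day (non-negative); volume of
#'   non-proliferating cells decays as `exp(-c*(t - t0))`.
#' @param t0 Reference time for the volume-loss delay, days.
#' @param N0 Initial number of proliferating cells (positive).
#' @param Nm Carrying-capacity cell count (`N0 <= Nm`; may be `Inf`).
#' @param V0 Initial tumor volume, mm3 (positive).
#' @param v Apparent single-cell volume, mm3; defaults to `V0 / N0` so that
#'   `V = v * N` holds at time 0.
#' @return An object of class `tumor_params` with the fields above plus the
#'   derived `Vm = v * Nm`.
#' @examples
#' tumor_params()
#' tumor_params(Nm = Inf) # exponential-growth limit
#' @export
tumor_params <- function(lam = 0.14, b = 0.3, c = 0.1, t0 = 0,
                         N0 = 2e9, Nm = 4e10, V0 = 577, v = V0 / N0) {
  scalars <- list(lam = lam, b = b, c = c, t0 = t0, N0 = N0, Nm = Nm,
                  V0 = V0, v = v)
  for (nm in names(scalars)) {
    x <- scalars[[nm]]
    if (!is.numeric(x) || length(x) != 1L || is.na(x)) {
      abort(sprintf("`%s` must be a single number.", nm),
            class = "trtsim_invalid_input")
    }
  }
  if (lam < 0 || b < 0 || c < 0) {
    abort("`lam`, `b` and `c` must be non-negative.",
          class = "trtsim_invalid_input")
  }
  if (N0 <= 0 || N0 > Nm) {
    abort("Cell counts must satisfy 0 < N0 <= Nm.",
          class = "trtsim_invalid_input")
  }
  if (V0 <= 0 || v <= 0) {
    abort("`V0` and `v` must be positive.", class = "trtsim_invalid_input")
  }
  if (abs(V0 - v * N0) > 1e-9 * V0) {
    abort("`V0` must equal `v * N0` (volume and cell count must be consistent).",
          class = "trtsim_invalid_input")
  }
  structure(list(lam = lam, b = b, c = c, t0 = t0, N0 = N0, Nm = Nm,
                 V0 = V0, v = v, Vm = v * Nm),
            class = "tumor_params")
}

#' @export
print.tumor_params <- function(x, ...) {
  cat("<tumor_params>\n")
  cat(sprintf("  growth lam = %g /day, kill b = %g /Gy, clearance c = %g /day (t0 = %g d)\n",
              x$lam, x$b, x$c, x$t0))
  cat(sprintf("  cells N0 = %.3g, Nm = %.3g; volume V0 = %g mm3, Vm = %.4g mm3\n",
              x$N0, x$Nm, x$V0, x$Vm))
  invisible(x)
}

assert_tumor_params <- function(p) {
  if (!inherits(p, "tumor_params")) {
    abort("`p` must be created with `tumor_params()`.",
          class = "trtsim_invalid_input")
  }
  invisible(p)
}
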
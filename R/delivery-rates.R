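#' Transfer coefficients of the four-compartment delivery model
#'
#' Bundles the first-order transfer coefficients of the four-box model of
#' radiopharmaceutical delivery (blood, tumor, body organs, excretion) together
#' with the physical decay rate of the radionuclide. The decay rate `y` is
#' always derived from the physical half-life as `log(2) / half_life_h`.
#'
#' The defaults are the coefficients used for \[211At\]NaAt in a thyroid-cancer
#' xenograft mouse: `a12 = 0.33` (blood to tumor), `a13 = 1` (blood to body
#' organs), `a14 = 0.5` (blood to excretion), `a21 = 0.1` and `a31 = 0.5`
#' (return paths to blood), all per hour, with the 7.21 h half-life of
#' astatine-211.
#'
#' @param a12,a13,a14 Forward transfer coefficients out of blood into tumor,
#'   body organs, and excretion (per hour, non-negative).
#' @param a21,a31 Return coefficients from tumor and body organs back into
#'   blood (per hour, non-negative). Set both to 0 for the no-return model
#'   that admits a closed-form solution.
#' @param half_life_h Physical half-life of the radionuclide in hours
#'   (finite, positive).
#'
#' @return An object of class `delivery_rates`: a list with fields `a12`,
#'   `a13`, `a14`, `a21`, `a31`, `half_life_h` and the derived decay rate `y`
#'   (per hour).
#' @examples
#' rates <- delivery_rates()
#' rates$y # log(2) / 7.21 = 0.0961 per hour
#'
#' # no-return variant used by the analytic solution
#' delivery_rates(a21 = 0, a31 = 0)
#' @export
delivery_rates <- function(a12 = 0.33, a13 = 1, a14 = 0.5,
                           a21 = 0.1, a31 = 0.5,
                           half_life_h = 7.21) {
  coefs <- c(a12 = a12, a13 = a13, a14 = a14, a21 = a21, a31 = a31)
  for (nm in names(coefs)) {
    x <- coefs[[nm]]
    if (!is.numeric(x) || length(x) != 1L || is.na(x) || x < 0) {
      abort(sprintf("`%s` must be a single non-negative number, not %s.",
                    nm, format(x)),
            class = "trtsim_invalid_input")
    }
  }
  if (!is.numeric(half_life_h) || length(half_life_h) != 1L ||
      is.na(half_life_h) || half_life_h <= 0 || !is.finite(half_life_h)) {
    abort("`half_life_h` must be a single finite positive number.",
          class = "trtsim_invalid_input")
  }
  structure(
    list(a12 = a12, a13 = a13, a14 = a14, a21 = a21, a31 = a31,
         half_life_h = half_life_h, y = log(2) / half_life_h),
    class = "delivery_rates"
  )
}

#' @export
print.delivery_rates <- function(x, ...) {
  cat("<delivery_rates> (per hour)\n")
  cat(sprintf("  blood -> tumor     a12 = %g\n", x$a12))
  cat(sprintf("  blood -> organs    a13 = %g\n", x$a13))
  cat(sprintf("  blood -> excretion a14 = %g\n", x$a14))
  cat(sprintf("  tumor -> blood     a21 = %g\n", x$a21))
  cat(sprintf("  organs -> blood    a31 = %g\n", x$a31))
  cat(sprintf("  decay y = log(2)/%g = %.5g\n", x$half_life_h, x$y))
  invisible(x)
}

# A = total loss rate from blood (transfer + decay), B = transfer only.
rate_sums <- function(rates) {
  B <- rates$a12 + rates$a13 + rates$a14
  list(A = B + rates$y, B = B)
}

assert_delivery_rates <- function(rates) {
  if (!inherits(rates, "delivery_rates")) {
    abort("`rates` must be created with `delivery_rates()`.",
          class = "trtsim_invalid_input")
  }
  invisible(rates)
}
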
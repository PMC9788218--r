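# shared fixtures: published parameter set and small reporting grids
default_rates <- function() delivery_rates()

no_return_rates <- function() delivery_rates(a21 = 0, a31 = 0)

coarse_hours <- function() seq(0, 48, by = 0.5)

# exact exponential control series for the estimation tests
exp_series <- function(lam = 0.14, V0 = 500, days = 0:10) {
  data.frame(day = days, volume_mm3 = V0 * exp(lam * days))
}

# random non-negative rate sets for property-style PK tests
random_rates <- function() {
  delivery_rates(
    a12 = runif(1, 0, 2), a13 = runif(1, 0, 2), a14 = runif(1, 0, 2),
    a21 = runif(1, 0, 1), a31 = runif(1, 0, 1),
    half_life_h = runif(1, 1, 24)
  )
}
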
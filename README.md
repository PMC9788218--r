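# trtsim

Simulation and analysis of tumor response to **targeted radionuclide therapy
(TRT)** with the alpha emitter astatine-211 (²¹¹At, half-life 7.21 h) in an
implanted mouse tumor, for preclinical modellers who want to predict
dose–response before (or beyond) an animal experiment.

The package chains three deterministic models:

1. **Drug delivery** — a four-compartment linear ODE system (blood → tumor /
   body organs / excretion, with return paths) for the activity `R1..R4`
   after a bolus injection `Q`, with the closed-form solution
   `R₂(t) = Q (α₁₂/B)(1−e^(−Bt)) e^(−yt)` when the return paths are dropped
   (`A = α₁₂+α₁₃+α₁₄+y`, `B = A − y`). Total activity always decays as
   `Q e^(−yt)` (mass balance).
2. **Dosimetry** — tumor dose rate `d(t) = k·R₂(t)` with
   `k = 5.45 Gy h⁻¹ MBq⁻¹` (1.5 g tumor); total dose in closed form,
   `D(∞) = kQα₁₂/(yA)` = **9.7 Gy per MBq** under the defaults; exact linear
   superposition for multi-injection schedules.
3. **Tumor response** — logistic growth with a radiation kill term,
   `dN/dt = (λ_eff − b·d(t)) N (1 − N/N_m)`, plus a damaged-cell volume pool
   `V_D = v·N_D·e^(−ct)` that delays visible shrinkage, and a dose-impaired
   regrowth rate `λ_mod = λ/(1 + D(t)^(1/4))`. Defaults: `λ = 0.14`/day,
   `b = 0.3`/Gy, `c = 0.1`/day, `N0 = 2×10⁹`, `Nm = 4×10¹⁰`.

Around the models: per-animal log-linear growth-rate estimation with cohort
summaries (`fit_growth_rate()`, `summarize_cohort()`), a reproducible
synthetic-cohort generator (`generate_cohort()`), ggplot2 `autoplot()`
methods, and a `trt-sim` command-line wrapper (`inst/cli/trt-sim`) with
subcommands `pk`, `dose`, `simulate`, `fit-growth`, `make-fixtures`.

## Worked example

```r
library(trtsim)

rates <- delivery_rates()     # α12=0.33, α13=1, α14=0.5, α21=0.1, α31=0.5 /h
rates$y                       # 0.0961 /h  (= log(2)/7.21)

total_dose(rates, Q = 1)      # 9.713 Gy — total tumor dose for 1 MBq

dp <- dose_profile(rates, Q = 1, t_grid = seq(0, 96, 0.1))
attr(dp, "cum_fn_h")(24) / attr(dp, "total_gy")
#> 0.895  — ~90% of the dose is delivered within a day

sc <- run_scenarios(c(0, 0.1, 0.4, 1), horizon_days = 40, step_days = 0.5)
dplyr::filter(sc, t_day == 40)[, c("activity_mbq", "V", "cum_dose_gy")]
#>   activity_mbq       V cum_dose_gy
#> 1          0.0 10782.4      0.0000
#> 2          0.1  4582.3      0.9713
#> 3          0.4  1682.2      3.8850
#> 4          1.0   256.5      9.7125
```

Day-40 tumor volume (mm³) falls monotonically with injected activity: the
control grows towards its carrying capacity, while 1 MBq (9.7 Gy) knocks the
tumor down to ~250 mm³ and leaves regrowth impaired
(`lambda_mod(0.14, 9.7)` ≈ 0.051/day instead of 0.14/day).

A synthetic dose–response experiment and its control-growth analysis:

```r
cohort <- generate_cohort(cohort_spec(seed = 1))   # 6 animals × {0, 0.1, 0.4, 1} MBq
summarize_cohort(fit_growth_cohort(dplyr::filter(cohort, activity_mbq == 0)))
#>   lam_mean lam_sd V0_mean V0_sd n_animals degenerate
#> 1    0.154  0.081     789   453         6      FALSE
```

Six noisy control animals recover the generating growth-rate scale
(mean 0.14/day, SD 0.08/day, initial volumes ~577 ± 372 mm³); the spread in
`V0_hat` reflects the built-in between-animal heterogeneity.

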
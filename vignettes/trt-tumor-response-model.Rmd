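---
title: "Modelling tumor response to targeted alpha therapy with astatine-211"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modelling tumor response to targeted alpha therapy with astatine-211}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(trtsim)
library(dplyr)
```

trtsim simulates the tumor response of an implanted (xenograft) mouse tumor
to a single or repeated intravenous injection of an alpha-emitting
radiopharmaceutical, with defaults calibrated to \[^211^At\]NaAt treatment of a
NIS-expressing thyroid-carcinoma model. The pipeline has three layers —
drug delivery, tumor dosimetry, tumor response — plus an estimation layer for
control growth rates and a synthetic-cohort generator that stands in for the
animal experiment.

## Drug delivery: the four-compartment model

Injected activity enters the blood (compartment 1) and is transferred to the
tumor (2), the remaining body organs (3), and excretion (4) with first-order
coefficients $\alpha_{1i}$ (per hour), with return paths $\alpha_{21},
\alpha_{31}$ back to blood. Every compartment also loses activity by physical
decay at rate $y = \ln 2 / T_{1/2}$. In matrix-free form:

$$
\begin{aligned}
\dot R_1 &= -(\alpha_{12}+\alpha_{13}+\alpha_{14}+y) R_1
            + \alpha_{21} R_2 + \alpha_{31} R_3,\\
\dot R_2 &= \alpha_{12} R_1 - (\alpha_{21}+y) R_2,\\
\dot R_3 &= \alpha_{13} R_1 - (\alpha_{31}+y) R_3,\\
\dot R_4 &= \alpha_{14} R_1 - y R_4,
\end{aligned}
$$

with $R_1(0) = Q$ (injected MBq) and the rest zero. Summing the equations
shows the total activity obeys $R_T(t) = Q e^{-yt}$ exactly — the mass-balance
invariant the numerical solution is tested against. With the return paths
dropped ($\alpha_{21} = \alpha_{31} = 0$) the system solves in closed form
with $A = \alpha_{12}+\alpha_{13}+\alpha_{14}+y$ and $B = A - y$:

$$
R_1 = Q e^{-At}, \qquad
R_i = Q \tfrac{\alpha_{1i}}{B}\left(1-e^{-Bt}\right) e^{-yt},\quad i=2,3,4.
$$

`solve_compartments()` integrates the full system (lsoda); `analytic_no_return()`
evaluates the closed form. Since the default return coefficient out of the
tumor is small ($\alpha_{21} = 0.1$/h), the closed form tracks the full
solution closely in the tumor, and all dosimetry uses it. The decay-corrected
tumor fraction `renormalized_tumor_fraction()`,
$f(t) = \frac{\alpha_{12}}{B}(1-e^{-Bt})$, plateaus at
$\alpha_{12}/B = 0.33/1.83 \approx 0.180$ under the defaults. (The earlier
biodistribution study reported 23 %ID/g at 3 h and 12 %ID/g at 24 h; how that
unit maps onto this dimensionless fraction is not defined, so the package
asserts only its own closed form.)

```{r pk}
rates <- delivery_rates()
analytic_no_return(rates, Q = 1, t = c(1, 3, 24))
renormalized_tumor_fraction(rates, c(3, 24))
```

## Dosimetry

The tumor dose rate is proportional to the tumor activity,
$d(t) = k\,R_2(t)$ with $k = 5.45$ Gy h$^{-1}$ MBq$^{-1}$ for a 1.5 g tumor.
This constant is the published calibration for astatine-211 in this system
and is treated as configuration: attempting to re-derive it from the mean
alpha energy per decay ($\approx 6.7$ MeV) and a 1.5 g mass gives roughly
2.6 Gy/h, so the printed value evidently absorbs additional factors and we do
not second-guess it. The time-integrated tumor activity has the closed form

$$
\int_0^\infty R_2\,dt = \frac{Q\,\alpha_{12}}{y\,A},
$$

so the total dose is $D(\infty) = k Q \alpha_{12}/(yA)$ — 9.71 Gy for
$Q = 1$ MBq, matching the published 9.7 Gy. "Infinity" always means this
closed form, never a truncated quadrature. The running dose $D(t)$ uses the
exact partial integral of the closed-form $R_2$ (trapezoid integration only
for the numeric-solver path). About 90 % of the dose is delivered within
24 h, a consequence of the 7.21 h half-life.

```{r dose}
total_dose(rates, Q = 1)
dp <- dose_profile(rates, Q = 1, t_grid = seq(0, 96, 0.1))
attr(dp, "cum_fn_h")(24) / attr(dp, "total_gy")
```

`superpose_schedule()` builds the dose profile of a repeated-administration
protocol by linear superposition of time-shifted single-injection profiles,
which the linearity of the delivery ODE makes exact.

## Tumor response

Proliferating tumor cells $N$ grow logistically and are killed in proportion
to the instantaneous dose rate:

$$
\frac{dN}{dt} = \left(\lambda_{\mathrm{eff}}(t) - b\,d(t)\right)
                N \left(1 - \frac{N}{N_m}\right).
$$

The saturation bracket multiplies the whole net-rate term, kill included,
exactly as the model is written — fidelity to the source model was preferred
over the more conventional growth-only bracket. Defaults: $\lambda = 0.14$/day
(control cohort mean), $b = 0.3$/Gy, $N_0 = 2\times10^9$,
$N_m = 4\times10^{10}$.

Two refinements reproduce the shape of measured volume curves:

* **Volume-loss delay.** Cells killed by radiation stop proliferating at
  once but lose volume slowly. A damaged pool accumulates as
  $dN_D/dt = b\,d\,N$ and its volume is cleared as
  $V_D(t) = v\,N_D(t)\,e^{-c(t - t_0)}$ with $c = 0.1$/day and $t_0 = 0$,
  justified because irradiation (< 1 day) is much shorter than the clearance
  time $1/c \approx 10$ days. The measured volume is $V = V_L + V_D$ with
  $V_L = vN$ and $v = V_0/N_0$ the apparent single-cell volume. A
  `delay_form = "continuous"` variant integrates
  $dV_D/dt = v\,b\,d\,N - c\,V_D$ instead, ageing each damaged cohort from
  its own creation time; it is offered for sensitivity analysis only and
  agrees with the literal form to within a few percent for single-injection
  profiles.
* **Impaired regrowth.** The growth rate after irradiation is reduced by the
  cumulative dose received: $\lambda_{mod}(t) = \lambda / (1 + D(t)^{1/4})$.
  (The source typography is ambiguous about the placement of the quarter
  power; this reading is the one that makes $\lambda_{mod} \to \lambda$ as
  $D \to 0$ and reproduces the described slower regrowth after high dose,
  and is adopted as a design decision.) For a 1 MBq injection (9.7 Gy) the
  regrowth slope drops from 0.14 to $\approx 0.051$/day.

Useful limits, all enforced as tests: with no dose and $N \ll N_m$ the model
is exponential growth at $\lambda$; an idealised instantaneous dose $D$
leaves a surviving fraction $e^{-bD}$ (the package's narrowing-pulse
simulations converge to this law); with the regrowth impairment disabled the
post-treatment log-slope returns exactly to $\lambda$.

```{r response}
dp <- dose_profile(rates, Q = 1, t_grid = c(0, 96))
traj <- simulate_full(tumor_params(), dp, t_grid = seq(0, 40, 0.5))
traj[traj$t_day %in% c(0, 10, 20, 40), ]
```

`run_scenarios()` sweeps injected activities (the experimental groups 0, 0.1,
0.4, 1 MBq and the extrapolations 0.02 and 2 MBq) with shared parameters;
day-40 volume is monotone non-increasing in activity, and the volume nadir
arrives later at higher activity.

## Units and numerics

* The delivery/dosimetry layers work in **hours** (the decay constant is
  printed per hour); the tumor layer works in **days**. The dose rate crosses
  the boundary once, as $d_{\mathrm{day}}(t) = 24\,d_{\mathrm{h}}(24t)$, and a
  round-trip test confirms the cumulative dose carried inside the tumor
  trajectory equals the closed-form total.
* lsoda is used throughout with rtol $10^{-10}$ (atol $10^{-12}$ for the PK
  system, $10^{-10}$ for the tumor system). These are deliberately two
  orders below the tightest property tolerances asserted on the results
  (mass balance at $10^{-8}$ relative, control-limit equivalence at
  $10^{-6}$), so tests measure the model, not the solver's error floor.
  Tolerances are arguments, not constants.
* Dose profiles carry their non-smooth points (pulse edges, injection
  times); the tumor integrator restarts at each of them, so an adaptive step
  can never straddle a discontinuous forcing. This is what makes the
  narrowing-pulse limit ($10^{-3}$ day pulses) accurate to $<10^{-3}$
  relative.
* Solver undershoot of a non-negative state is clamped to zero only within
  the absolute tolerance; anything below $-\mathrm{atol}$ raises an error.
* Caliper pairs convert to volume as an oblate ellipsoid with the long axis
  duplicated, $V = \frac{\pi}{6}L^2W$; the sphere limit of a 10 mm tumor
  ($\approx 524$ mm³) matches the volume scale at which treatment started.
  The original work does not print its formula, so this choice is a
  documented assumption.

## Growth-rate estimation

`fit_growth_rate()` fits $V = V_0 e^{\lambda t}$ by ordinary least squares of
$\log V$ on time over the first 10 days (day 0 = the animal's first
measurement), the standard reading of "regression analysis" for exponential
early growth: it is exactly invertible on clean data and unbiased on the log
scale under multiplicative noise. `summarize_cohort()` reports the arithmetic
mean and $n-1$ sample SD across animals; a single-animal cohort reports SD 0
with a `degenerate` flag rather than an error. Fitting the response
parameters ($b$, $c$, the regrowth exponent) to treated trajectories is out
of scope: in the source analysis they were hand-tuned, and this package keeps
them as configuration.

## The synthetic cohort

No per-animal measurement table was deposited with the original experiment,
so `generate_cohort()` emulates one from the model's own dynamics:

* per-animal growth rate $\lambda_i \sim \mathcal N(0.14, 0.08^2)$/day
  truncated below at 0.01 (rejection sampling) — note the truncation raises
  the true mean of the generating distribution to 0.1490/day, the value
  parameter-recovery checks must compare against;
* per-animal initial volume $V_{0,i}$ lognormal, moment-matched to mean
  577 mm³ / SD 372 mm³ so volumes are always positive;
* group structure: `n_per_group` animals per injected activity (default
  control, 0.1, 0.4, 1 MBq), treated at their own day 0 (re-indexing to the
  treatment day mirrors treating each animal when its tumor reached size);
* measurements every 2 days to day 30 with i.i.d. multiplicative lognormal
  noise, log-SD 0.15 — a fixture knob chosen to resemble the published
  scatter, not a measured quantity;
* deterministic for a fixed seed, and the true per-animal parameters are
  attached as the `truth` attribute for recovery studies.

The generator's default `tumor_params` template uses $N_m = \infty$: the
emulated observation window is the early-growth regime in which the cohort
growth rates are defined, and imposing the finite default carrying capacity
there would build a downward bias into every growth-rate round-trip (at
$V_0 = 577$ mm³ the window already spans $V/V_m \approx 0.05$–0.2). Callers
wanting saturated controls pass a finite-$N_m$ template.

What passing tests on this cohort do **not** show about real data: the
generator draws from the fitted model itself, so round-trip successes
demonstrate estimator correctness and internal consistency, not biological
adequacy; real cohorts add caliper schedule irregularities, ethical-endpoint
censoring, occasional non-regrowing cures (one 1 MBq animal in the original
data), and model misspecification that no self-generated fixture can expose.

## Problem sizes

The shipped tests run the PK solver on 0–48 h grids (up to 4801 points, 20
random rate sets), pulse-limit sweeps at four doses, a 100-animal noisy
control cohort for parameter recovery, Monte-Carlo unbiasedness checks at
300–400 replicates, and a six-activity scenario sweep over 40 days — sizes
chosen so the full suite completes in well under a minute while Monte-Carlo
error stays several times below the asserted tolerances.

## Known limitations

* The kill term is saturated by the same logistic bracket as growth; at
  $N \to N_m$ radiation has no net effect on $N$, a direct consequence of
  the model as published.
* Dosimetry is a single scalar conversion: no organ dosimetry, S-values,
  microdosimetry, or RBE weighting; repeated administration assumes identical
  kinetics for every injection.
* The delivery topology is fixed to the four-box structure (coefficients are
  configurable, the graph is not), and transfer coefficients are taken as
  given rather than fitted to biodistribution data.
* The model is deterministic; no stochastic birth–death, cell-cycle, hypoxia,
  immune, or stem-cell effects.
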
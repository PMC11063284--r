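# cartrt

Simulation, calibration and schedule optimization for combined **targeted
radionuclide therapy (TRT)** and **CAR T-cell therapy** in a preclinical
multiple myeloma model.

Dosing and timing of radio-immunotherapy combinations are hard to optimize
experimentally: radiation delivered too close to a CAR-T infusion kills the
CAR-T cells, while therapies spaced too far apart let the tumor regrow.
`cartrt` implements a three-compartment ODE model of this interaction and
the machinery around it — simulated survival endpoints, parameter
calibration from longitudinal bioluminescence-style cohorts, a synthetic
cohort generator, and in-silico dosing/timing scans.

## Model

States are continuous cell counts: unirradiated tumor cells `N_T`,
irradiated tumor cells `N_R`, CAR-T cells `N_C`:

    dN_T/dt = rho*N_T − kRx_T(t)*N_T − k1*N_T*N_C
    dN_R/dt = kRx_T(t)*N_T − k1*N_R*N_C − k_cl*N_R
    dN_C/dt = k2*(N_T+N_R)*N_C − kRx_C(t)*N_C − theta*N_C

Each TRT injection turns on a linear-quadratic dose-rate kill term
`kRx_i(t) = alpha_i * R0 * exp(−lam*(t−t_TRT))` (+ a quadratic
sublethal-damage term, zero for alpha therapy) with initial dose rate
`R0 = eta * activity`. CAR-T infusions are instantaneous boluses.
Endpoints: overall survival (burden reaching 1e11 cells),
progression-free survival (last return of the burden to its
treatment-start size before the survival endpoint) and time to minimum
burden. Defaults reproduce the benchmarked global parameter set for
^225^Ac-daratumumab + CS1 CAR-T in MM.1S-bearing mice.

## Worked example

```r
library(cartrt)

p <- cartrt_params()                  # benchmarked global parameter set
sch <- combo_schedule(trt_day = 7, trt_kbq = 7.4,
                      cart_day = 25, cart_cells = 1e6)
tr <- simulate_therapy(p, sch, t_end = 365)
survival_metrics(tr)
#> Simulated survival metrics
#>   baseline: day 7, burden 2.144e+07 cells
#>   PFS  : 40.09 days
#>   OS   : 94.85 days
#>   t_min: 26.32 days
```

The tumor (5e6 cells engrafted at day 0) has grown to 2.14e7 cells when
TRT starts on day 7; the combination keeps the burden below that baseline
for 40.1 days, the minimum burden occurs 26.3 days after treatment start,
and the simulated animal reaches the 1e11-cell endpoint 94.9 days after
inoculation (an untreated animal reaches it at `ln(1e11/5e6)/0.208 ≈ 47.6`
days).

Scanning the infusion day shows the timing window:

```r
sc <- scan_cart_timing(p, cart_days = 8:50)
sc$argmax_set                         # infusion days tied for maximal PFS
#> [1] 25 26 27 28 29 30
scan_dose(p, "cart")$min_effective_dose
#> [1] 7e+05
```

Calibration round-trip on a synthetic six-group cohort:

```r
coh <- generate_experiment_suite(cartrt_params(), seed = 7)
fit <- fit_tumor_model(coh)
summary(fit)
```

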
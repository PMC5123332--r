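# copolsim

Monte Carlo simulation of correlated exposure measurement error in
**copollutant Poisson time-series models** of air pollution and daily
health counts.

## The problem

Air-pollution epidemiology usually assigns exposure from a central monitor.
For locally sourced pollutants (CO, NOx, elemental carbon) that surrogate
carries large, spatially structured error; for regional pollutants (PM2.5,
sulfate, O3) much less. In a two-pollutant ("copollutant") Poisson
regression the errors of the two exposure series are correlated with each
other and with the concentrations, which can attenuate the real effect and
manufacture false-positive associations for the null copollutant — a
pattern outside classical/Berkson error theory. `copolsim` quantifies these
effects by simulation, end to end and fully synthetic.

## The model

Three exposure metrics per pollutant and ZIP code — central-site `CS`
(shared across ZIPs each day), spatially refined `AQ`, population exposure
`PE` — define three error components:
`delta_spatial = AQ − CS`, `delta_population = PE − AQ`,
`delta_total = PE − CS`. Metrics are linked by ZIP-specific linear
calibrations with additive and multiplicative bias,

```
AQ_kt = theta_k1 + theta_k2 · CS_kt + eps_kt ,
```

with residuals correlated across pollutants. Each Monte Carlo iteration
draws (theta_1, theta_2) per ZIP from their asymptotic bivariate normal and
day-level joint residuals from the empirical residual covariance to build
"true" (error-free) exposures, simulates counts from

```
log mu = X·B + log(RR1)·true1/IQR1 + log(RR2)·true2/IQR2 ,
```

(`RR1 = 1.05` per IQR for the main pollutant, `RR2 = 1` for the
copollutant, by default), and fits the health model — ZIP, day-of-week,
holiday, hospital, monthly-knot cubic time spline, temperature, dew-point
and season terms — twice on the same counts: with the true exposures and
with the error-prone unrefined ones. Summaries across iterations are the
mean RR `exp(mean(beta))`, percent attenuation
`100·(RR1 − meanRR_noisy)/(RR1 − 1)`, RMSE and the noisy/true RMSE ratio,
power / type I error at |z| > 1.96 with binomial SE, and 95% CI coverage.

## Worked example

```r
library(copolsim)

cfg    <- default_scenario()                      # 15 ZIPs x 730 days, N = 200
panel  <- generate_exposure_panel(cfg)
design <- build_design_matrix(generate_covariates(cfg))

B0 <- default_baseline_coefficients(design, cfg$baseline_rate)
set.seed(cfg$seed + 2L)
B  <- fit_baseline_coefficients(design, simulate_counts(design, B0))

calib <- fit_calibrations(panel, "spatial")
res   <- run_scenario(cfg, panel, calib, B, "CO", "O3", design = design)
summarize_scenario(res)
```

Selected columns of the result (about two minutes on one core):

```
 pol1 pol2 error_type main_true_mean_rr main_noisy_mean_rr pct_attenuation
   CO   O3    spatial            1.0507             1.0251            49.9
 main_rmse_ratio co_rmse_ratio co_noisy_power_or_type1 main_true_coverage95
            2.57          1.09                    0.06                 0.92
```

Read: with error-free exposure the fitted CO relative risk averages 1.0507,
recovering the assumed 1.05; substituting the central-site exposure
attenuates it to 1.0251 — about half the excess risk gone — while the CO
log-RR's root-mean-square error grows 2.6-fold. The null copollutant (O3)
stays essentially unbiased, with a noisy-fit type I error of 0.06 against
the nominal 0.05 and true-fit CI coverage near 0.95.

`run_grid()` executes every ordered pollutant pair × error type and
`report()` renders the attenuation table (min–max ranges across
copollutants), the RMSE-ratio table, and the RR and type-I-error figures
from the stored per-scenario CSVs. A thin CLI with `generate`, `calibrate`,
`run`, `grid` and `report` subcommands lives at `inst/cli/copolsim.R`.

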
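# bnfcurve

Seasonal dynamics of biological nitrogen fixation (BNF) in soybean,
quantified from stem ureide assays.

## The problem

Soybean draws nitrogen from two sources: soil mineral N and symbiotic
fixation by rhizobia. The balance between them shifts through the season
and with fertiliser management, and fixation carries a metabolic cost
(6–7 g C per g N, versus ~4 for mineral N uptake) that the crop must
absorb somewhere — growth, harvest index, or seed composition. This
package implements a complete, testable pipeline for the standard field
approach to that question:

1. **Fixation proxy.** The relative abundance of ureides in stem tissue,

   RAU (%) = 100 · 4U / (4U + N),

   where U is the ureide concentration and N the nitrate concentration
   (ureides carry four N atoms each). `compute_rau()` is unit-invariant
   and strict about its domain.

2. **Developmental clock.** Cumulative thermal time,
   TT = Σ max(0, (Tmax + Tmin)/2 − Tb) with Tb = 8 °C, anchored at the V2
   stage (`accumulate_thermal_time()`, `thermal_clock()`,
   `stage_thermal_times()`), so that trials spanning maturity groups 0–IV
   share one time axis.

3. **Seasonal trajectory.** The three-parameter beta growth function

   RAU(t) = RAU_max · (1 + (t_max − t)/(t_max − t_m)) · (t/t_max)^(t_max/(t_max − t_m)),

   fitted by bounded Levenberg–Marquardt least squares (`fit_beta()`),
   with closed-form derived traits: the maximum fixation rate at t_m
   (`max_rate()`), the half-rise point t₀.₅ (`t_half()`), and the area
   under the seasonal curve (`auc_beta()`). Treatment effects on whole
   curves are tested with small-sample AICc, shared vs separate fits
   (`compare_fits_aicc()`).

4. **Cost of fixation.** Because maturity group confounds traits with
   phenology, seed yield, harvest index and seed oil are first de-trended
   against thermal time to R6 with a continuous bilinear (broken-stick)
   model (`fit_bilinear()`), and the residuals are regressed on RAU at R6
   at the mean (`residual_mean_regression()`) and at the 0.01/0.99
   boundary quantiles (`residual_quantile_regression()`, an exact
   check-loss minimiser).

A calibrated synthetic generator (`simulation_spec()`,
`simulate_trials()`) emulates the 23-site × 4-treatment × 3-block US
Midwest trial structure this workflow was designed for, so every stage of
the pipeline is testable end-to-end without field data, and injected
effects (e.g. a yield cost of −13 kg ha⁻¹ per % RAU_R6) can be recovered
as a validation of the whole chain.

## Worked example

Derived traits of a fitted high-BNF control curve
(RAU_max = 90%, t_m = 397 °Cd, t_max = 1117 °Cd):

```r
library(bnfcurve)
max_rate(90, 397, 1117)
#> [1] 0.1162111        # % per degree-day, the peak fixation rate
t_half(90, 397, 1117)
#> [1] 473.4108         # degCd at which RAU reaches 45 = RAU_max/2
```

Simulate a trial network at a common thermal season, refit the high-BNF
control curve from the raw assays, and compare control vs flowering-stage
fertilisation:

```r
spec <- simulation_spec(seed = 42, tt_r6_range = c(1150, 1150))
sim <- simulate_trials(spec)
obs <- sim$observations
obs$group <- sim$truth$group[match(obs$site_id, sim$truth$site_id)]

fit_beta(obs$t[obs$group == "high" & obs$treatment == "control"],
         obs$rau[obs$group == "high" & obs$treatment == "control"])
#> Beta growth-function fit (seasonal RAU)
#>   rau_max = 90.71 (SE 2.33) %
#>   t_m     = 382.8 (SE 36.4) degCd
#>   t_max   = 1108.4 (SE 16.3) degCd
#>   derived: max rate 0.1181 %/degCd, t0.5 465 degCd, AUC 100279 %*degCd
#>   n = 72, R2 = 0.902, Syx = 10.38, converged = TRUE

compare_fits_aicc(
  obs[obs$group == "high" & obs$treatment == "control", c("t", "rau")],
  obs[obs$group == "high" & obs$treatment == "N_R2",    c("t", "rau")])
#> AICc comparison: shared 733.43 vs separate 718.71 -> prefer separate (evidence ratio 1571.9)
```

The generating parameters (90, 397, 1117) are recovered within their
standard errors, and the −15% peak-RAU shift injected for the N-at-R2
treatment is resolved as a separate curve.

The full pipeline — quartile grouping on control RAU_R6, twelve pooled
curve fits, AICc comparisons, phenology de-trending and residual
regressions, site summaries — runs from one seeded configuration:

```r
report <- run_full_pipeline(list(sim = simulation_spec(seed = 42)))
report
#> Seasonal BNF analysis: 23 sites (6 low / 11 medium / 6 high), 12 curve fits
#>   yield residual slope vs RAU_R6: -12.7 kg/ha per % (p = 1.21e-20)
```

The injected cost of fixation (−13 kg ha⁻¹ per % RAU_R6) is recovered by
the de-trending pathway. `midwest_site_means()` and
`midwest_curve_params()` expose the bundled published summaries of the
23-site network (per-site treatment means; fitted group-curve
parameters) used for calibration and reproduction checks.

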
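# emdcast

Hybrid forecasting of monthly health-service demand: **empirical mode
decomposition + per-component neural networks initialized by particle swarm
optimization**.

Monthly outpatient-visit counts are nonlinear and nonstationary — a strong
annual cycle (January–February peak, July dip), a slow growth trend, and
noise. Hospital administrators who staff clinics and allocate budgets need
month-ahead forecasts of such series; a single model fitted to the raw
series must capture every time scale at once and usually fails at the
seasonal extremes. `emdcast` is for analysts of such series (hospital
planning, public-health surveillance, any seasonal monthly count data).

## The method

1. **Decompose.** Empirical mode decomposition (EMD) sifts the series
   *x(t)* into intrinsic mode functions (IMFs) *g₁..g_m* and a residue
   *r_m*, with *x(t) = Σᵢ gᵢ(t) + r_m(t)*. Each IMF carries one
   characteristic frequency; the residue carries the trend.
2. **Normalize.** Each component is min-max scaled to [−1, 1].
3. **Optimize.** A three-layer network (3 lagged inputs, 14 tanh hidden
   units, 1 linear output; *H_j = tanh(Σᵢ ω_ij xᵢ − b_j)*) forecasts each
   component one step ahead. Its 71 weights and thresholds
   (*n_h + n₀ + n_i·n_h + n_h·n₀*) are encoded as a particle, and a swarm of
   40 minimizes the training MSE over 200 iterations with linearly
   decreasing inertia (0.9 → 0.3) and time-varying learning factors
   (c₁ 2.5 → 0.5, c₂ 0.5 → 2.5), velocities clamped to [−1, 1].
4. **Refine.** The best particle seeds resilient-backpropagation training
   (goal MSE 0.01, ≤ 1000 epochs).
5. **Forecast & superpose.** Component forecasts are denormalized and
   summed into the final forecast.

Evaluation: Pearson **R**, **RMSE**, **MAPE** (as a fraction), **SSE**, plus
seasonal fluctuation indices (SFI₁ by calendar month, SFI₂ by horizon step)
and per-step relative error to relate forecast error to seasonality.

## Worked example

```r
library(emdcast)

x <- simulate_outpatient_series(seed = 1)   # 108 months, Jan 2005 - Dec 2013
dec <- emd(x)
glance(dec)
#>   n_imfs n_obs reconstruction_error
#> 1      4   108             2.50e-16

fit <- hybrid_fit(x, last_train_month = "2012-11", mode = "emd_pso_bpann", seed = 1)
report <- predict(fit, scheme = "one_step_ahead")
glance(report)
#>       R  RMSE   MAPE       SSE     n scheme         mode
#> 1 0.926 1667. 0.0408 36139876.    13 one_step_ahead emd_pso_bpann
```

The series decomposes into 4 IMFs plus a residue that reconstruct it to
machine precision. Forecasting the 13 held-out months (December 2012 –
December 2013) one step ahead, the hybrid attains a correlation of 0.93
with the observations and a mean absolute percentage error of about 4 % —
roughly 1700 visits on a ~35000-visit month. The same split with a plain
network on the raw series (no decomposition, no swarm) is much worse:

```r
compare_methods(x, "2012-11", methods = c("emd_pso_bpann", "bpann"), seeds = 1)
#>   method         seed     R  RMSE   MAPE        SSE     n
#> 1 emd_pso_bpann     1 0.926 1667. 0.0408  36139876.    13
#> 2 bpann             1 0.434 5526. 0.107  397012669.    13
```

`autoplot(dec)`, `autoplot(report)` and `plot_seasonal_error(report)` give
the standard figures; `tidy()`/`glance()` return tibbles at every stage.

A thin command-line front end ships in `inst/cli/emdcast.R`:

```sh
Rscript inst/cli/emdcast.R simulate --years 9 --seed 1 --out series.csv
Rscript inst/cli/emdcast.R forecast --input series.csv --split 2012-11 \
    --mode emd_pso_bpann --seed 1 --out results/
```

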
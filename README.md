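# oncoctrl

Ensemble optimal control of adaptive cancer-therapy schedules in R.

## The problem

Continuous maximum-tolerated-dose (MTD) chemotherapy wipes out
drug-sensitive tumor cells quickly — and with them the competition that was
keeping the resistant clone in check. For tumors harboring a pre-existing
resistant subpopulation, the schedule that maximizes cell kill is not the
schedule that maximizes time to progression. `oncoctrl` is for researchers
in mathematical oncology who want to simulate, compare and *optimize*
dosing schedules under this trade-off, while acknowledging that the
patient-specific parameters of the resistant clone are never known exactly.

The model is the non-dimensional two-population Lotka–Volterra system

```
s' = (1 − s − r)(1 − d̂_D u) s − d̂_T s
r' = r̂_R (1 − s − r) r − d̂_T r
```

with sensitive fraction `s`, resistant fraction `r`, burden `n = s + r`,
and normalized dose `u(τ) ∈ [0,1]`. Parameter uncertainty is expressed as a
finite ensemble of tumors `θ = (d̂_D, d̂_T, r̂_R, f̂_0)`; the reference grid
has 1225 members spanning `r̂_R ∈ [0.5, 0.98]` and `f̂_0 ∈ [0.002, 0.098]`.
Schedules are scored by time to progression (TTP: burden reaching 120% of
baseline) and optimized by projected gradient descent,
`u ← Π_[0,1][u − η ∇J]`, on integral burden costs — averaged over the
ensemble or against the worst case — with gradients from the exact discrete
adjoint of the Euler scheme. See the methods vignette
(`vignettes/ensemble-control-methods.Rmd`) for every numerical convention.

## Worked example

```r
library(oncoctrl)

# 1225-tumor ensemble at 50% initial burden, three protocols, 1000 days
ens <- theta_grid(0.5)
ttp_summary(ttp_ensemble(ens, "mtd",       1000))
ttp_summary(ttp_ensemble(ens, "on_off_at", 1000))
ttp_summary(ttp_ensemble(ens, "off_on_at", 1000), "ttp_prime")
```

```
  metric    max_days min_days mean_days mean_days_raw n_censored
1 ttp            593      155       270          270.          0
1 ttp            764      155       285          286.          0
1 ttp_prime      822      167       306          306.          0
```

Continuous dosing progresses after 270 days on average; On-Off adaptive
therapy (treat to half burden, pause to baseline) buys 15 days; Off-On
adaptive therapy (surveil to the progression threshold first) buys 36 —
the initial drug-free phase lets sensitive cells suppress the resistant
clone through resource competition.

Optimizing a schedule directly:

```r
fit <- optimize_schedule(ens, "hyperbolic", horizon_days = 1000)  # ~1 min
ttp_summary(schedule_ttp(fit), "ttp_prime")
#   metric    max_days min_days mean_days mean_days_raw n_censored
# 1 ttp_prime      900       15       334          335.          0
autoplot(fit)             # dose profile: off-phase, then ramped treatment
autoplot(fit, "history")  # functional value per iteration
```

The asymmetric (hyperbolic) cost discovers the same strategy as Off-On
adaptive therapy — let the tumor grow toward the threshold before
treating — and lifts the ensemble-mean TTP′ to 334 days, at the price of a
short worst-case tail. A single tumor can be inspected with
`simulate_tumor()` / `plot_trajectory()`, and a shell front end is
installed at `inst/exec/oncoctrl` (`simulate`, `optimize`, `tables`,
`fixture` subcommands).

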
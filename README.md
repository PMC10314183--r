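# flicrhythm

Circadian feeding-rhythm analysis for FLIC capacitance monitors.

The Fly Liquid-food Interaction Counter (FLIC) measures the capacitance
between a *Drosophila* and its liquid food at millisecond resolution,
twelve wells per Drosophila Feeding Monitor (DFM). Every contact with the
food deflects the signal; buried in the drifting, noisy trace are the
questions chronobiologists actually ask: how many feeding events per fly,
when in the day they happen, and whether feeding free-runs with a circadian
period in constant darkness. `flicrhythm` is a scriptable, fully tested
pipeline for those questions — from the raw monitor CSV to a per-well
periodogram table — for researchers who want the analysis reproducible from
a config file rather than clicked through a GUI.

The stages, each an ordinary tibble-in/tibble-out function:

1. **Read & organise** — `read_flic_csv()` (FLIC dialect, monitor number
   from the file name), `trim_by_date()`, `assign_conditions()`.
2. **Baseline** — `baseline_table()` with a 5-min running median or
   asymmetric least squares (Whittaker smoother with asymmetric weights:
   minimise `Σ wᵢ(yᵢ−zᵢ)² + λ Σ (Δ²zᵢ)²`, `wᵢ = p` above the baseline,
   `1−p` below).
3. **Call events** — `call_all_events()` with the four FLIC parameters
   (feeding minimum, feeding threshold, consecutive licks, gap): threshold
   interaction samples, run-length encode, qualify runs, merge across
   short gaps.
4. **Summarise** — `bin_events()`, `normalize_wells()`,
   `individual_totals()`, `group_stats()`, `events_per_day()`,
   `flag_outliers()` (Tukey fences), `split_day_night()`,
   `daily_profile()`.
5. **Circadian analysis** — `periodogram()`: autocorrelation power
   `r_k = Σ(xₜ−x̄)(xₜ₊ₖ−x̄)/Σ(xₜ−x̄)²` per candidate period `kΔ` in 16–32 h,
   peak period and power per well, one-sided per-lag significance
   threshold `z₁₋α/√N` and p-value `1 − Φ(r·√N)`; `periodogram_summary()`
   for condition-average curves and peak-power outlier flags.

A synthetic-data module (`simulate_experiment()`, `rate_flat()`,
`rate_sinusoidal()`, `rate_bimodal()`, `rate_step()`) generates
FLIC-format recordings with known ground-truth bouts — drifting baseline,
Gaussian noise, inhomogeneous-Poisson feeding bouts with circadian rate
profiles — so every stage is validated without hardware data.

Results objects print as tibbles, support `tidy()`/`glance()` and
`autoplot()`, and every output table writes to CSV. A thin CLI
(`exec/flicrhythm`) drives the whole pipeline from a YAML config:
`flicrhythm simulate -c config.yaml`, `flicrhythm run -c config.yaml`,
with any key overridable as `--events.feeding_minimum=10`.

## Worked example

Simulate the classic design in silico — twelve wells, three 12:12 LD days
then four DD days, lights 09:00/21:00; wells 1–6 a "wild-type" with
feeding peaks anticipating the light transitions, wells 7–12 an arrhythmic
"clock-mutant" — then run the analysis:

```r
library(flicrhythm)

sim <- simulate_experiment(simulation_params(
  n_wells = 12, n_ld_days = 3, n_dd_days = 4, sample_interval_ms = 1000,
  bout_rate_profile = c(rep(list(rate_bimodal(10, 40, 0.75)), 6),
                        rep(list(rate_flat(9)), 6)),
  bout_duration_s = 2, seed = 42
))
conds <- assign_conditions(list(
  list(monitor = 1, wells = 1:6,  condition = "wild-type"),
  list(monitor = 1, wells = 7:12, condition = "clock-mutant")
))

b  <- baseline_table(sim$signals, method = "rm")
ev <- call_all_events(b, event_params(5, 15, 2, gap = "5 samples"),
                      conditions = conds)

group_stats(individual_totals(ev))
#> # A tibble: 2 × 5
#>   condition        n  mean    sd   sem
#>   <chr>        <int> <dbl> <dbl> <dbl>
#> 1 clock-mutant     6 1516.  43.6  17.8
#> 2 wild-type        6 2605   52.5  21.4

pg <- periodogram(bin_events(ev, 30),
                  dd_start = "2021-07-04", dd_end = "2021-07-07")
tidy(pg)
#> # A tibble: 12 × 8
#>    monitor  well condition    peak_period_h peak_power  p_value signif_threshold
#>  1       1     1 wild-type             24       0.614  2.22e-16            0.119
#>  2       1     2 wild-type             24       0.598  2.22e-16            0.119
#>  ...
#>  8       1     8 clock-mutant          31       0.0847 1.20e- 1            0.119
#> 10       1    10 clock-mutant          23.5     0.166  1.07e- 2            0.119
#>  ...
```

The wild-type wells each make ~2600 feeding events over the week versus
~1500 for the mutants, and every wild-type well shows a clean 24.0 h
period with power around 0.6 — five times the significance line at
α = 0.05. The mutant peak powers hover around the line at scattered
periods: that is exactly the behaviour of a *per-lag* threshold under a
null rhythm (the peak over ~33 candidate lags exceeds a per-lag cutoff far
more often than α), which is why group rhythmicity is judged on the
condition-average periodogram instead:

```r
summ <- periodogram_summary(pg)
max(summ$mean_curve$mean_power[summ$mean_curve$condition == "clock-mutant"])
#> [1] 0.07917638   # vs signif_threshold 0.1187071
autoplot(summ)
```

The averaged mutant curve stays well below threshold while the wild-type
peak stands clear of it. `daily_profile(bin_events(ev, 60))` shows the
anticipation peaks at the 09:00 and 21:00 bins, and
`split_day_night(ev, light_schedule("09:00", "21:00"))` gives the per-well
day/night totals.

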
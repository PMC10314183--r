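---
title: "Models and methods: from raw FLIC signals to feeding rhythms"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods: from raw FLIC signals to feeding rhythms}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

The Fly Liquid-food Interaction Counter (FLIC) records the capacitance
between a fly and its liquid food at millisecond resolution, twelve wells
per Drosophila Feeding Monitor (DFM). Each contact with the food raises the
signal briefly; the interesting biology — how much a fly eats, when it eats,
and whether its feeding free-runs with a circadian period in constant
darkness — has to be distilled from a slowly drifting, noisy capacitance
trace. `flicrhythm` implements that distillation as a chain of small,
separately testable stages:

raw CSV → baselining → event calling → summaries → circadian periodogram,

with a synthetic-signal simulator standing in for hardware data wherever a
ground truth is needed.

```{r setup, message = FALSE}
library(flicrhythm)
```

## The signal model and the simulator

The simulator generates exactly the structure the downstream stages assume a
real recording has:

* a **sensor baseline** (default 100 a.u.) plus a **slow drift**, modelled as
  a Gaussian random walk on hourly knots, spline-interpolated to sample
  resolution and scaled so a day of increments has standard deviation
  `drift_amplitude` (default 20 a.u./day). Placing the knots an hour apart
  keeps all drift power at timescales well above one hour, so both
  baseline estimators (5-minute running median, asymmetric least squares)
  can remove it;
* **feeding bouts**: rectangular plateaus of `bout_amplitude` (default
  40 a.u.) whose onsets follow an inhomogeneous Poisson process with a
  per-well, time-of-day dependent rate profile, thinned against the
  profile's maximum; durations are exponential with mean `bout_duration_s`
  and overlapping bouts are dropped. The rectangular shape is the simplest
  one compatible with the event caller's threshold semantics;
* **read noise**: i.i.d. Gaussian with `noise_sd` (default 2 a.u.), then
  integer quantisation.

The default bout amplitude sits 20 noise standard deviations above the
floor. That is deliberately comfortable: the simulator's job is to provide
unambiguous ground truth for validating the machinery, not to probe the
detection limit. What simulated data cannot tell you is how the pipeline
behaves on the hardware's real failure modes — electrical interference,
grooming touches, multi-fly boards, evaporation steps. Passing tests here
certify the arithmetic, not the biology of edge cases.

Rate profiles come in four families: `rate_flat()` (arrhythmic),
`rate_sinusoidal()` (smooth circadian modulation), `rate_bimodal()`
(Gaussian peaks of feeding centred exactly at lights-on and lights-off, the
classic anticipatory phenotype) and `rate_step()` (distinct day/night
rates, i.e. light-driven masking without a clock). A well may use different
profiles for the light-dark (LD) and constant-darkness (DD) segments,
which is how a "clock mutant" is modelled: elevated night feeding under LD
as a direct light response, flat in DD because there is no clock to carry
the rhythm.

```{r}
sim <- simulate_experiment(simulation_params(
  n_wells = 2, n_ld_days = 1, n_dd_days = 1, sample_interval_ms = 1000,
  bout_rate_profile = rate_bimodal(4, 20, 1), seed = 1
))
sim
```

## Baselining

Two estimators of the drifting floor are provided; both subtract their
estimate, leaving deflections on a zero baseline (negative values are kept,
not clipped — the event thresholds handle sign).

**Running median (RM).** The window is given in minutes (default 5) and
converted to an odd sample count; the median of the centred window is
subtracted, with truncated windows at the recording edges (a shrinking
window avoids the phantom deflections a padded one would create). RM is
exactly invariant to adding a constant to an integer signal.

**Asymmetric least squares (ALS).** The baseline `z` minimises

$$\sum_i w_i (y_i - z_i)^2 + \lambda \sum_i (\Delta^2 z_i)^2,
\qquad w_i = \begin{cases} p & y_i > z_i \\ 1 - p & y_i \le z_i \end{cases}$$

iterated until the weights reach a fixed point. With `p = 0.01` the fit
pays ~100 times more for dipping below the data than for sitting above it,
which pins the baseline under feeding peaks so they survive subtraction.
ALS needs no per-recording window choice, which is its appeal; the cost is
two global parameters. Since no canonical values exist for FLIC data we fix
`lambda = 1e8` at the nominal 5 Hz sampling and `p = 0.01`: the resulting
smoothing timescale (`lambda^(1/4)` samples, about 20 s) sits well above
the bout timescale and well below the drift timescale, which is the only
requirement the decomposition imposes. Because the penalty acts on
per-sample differences, the equivalent `lambda` scales with the fourth
power of the sampling rate (`als_lambda_default()`).

Numerical choices worth knowing about:

* the normal equations have condition number growing with `lambda`
  (~1e12 at the default), so each solve uses a sparse Cholesky
  factorisation followed by two steps of iterative refinement, and the
  signal is centred first so accuracy does not depend on the sensor's
  absolute level;
* residuals within `1e-6` of the signal range count as "on the baseline"
  in the weight update. Without this tie rule the weight signs chase
  floating-point noise on flat stretches and the iteration never
  stabilises; with it the fixed point is deterministic and independent of
  the starting weights (property-tested against a dense solver);
* long recordings are processed in 24 h chunks. Each chunk is extended by
  twice the overlap (one RM window, or 10 min for ALS): the outer half is
  a discarded margin that absorbs boundary effects, the inner half a
  linear cross-fade. For RM the chunked result is *exactly* the unchunked
  one; for ALS the difference is below `1e-6` of the signal range.

Which method to use? On simulated data the binned event series downstream
of RM and ALS correlate at r > 0.99 per well, so for clean recordings the
choice is immaterial; the package defaults to RM and leaves ALS as a
per-case option.

## Event calling

Four parameters turn a baselined trace into feeding events, with the
pinned algorithm: (1) mark interaction samples (`value >= feeding_minimum`);
(2) run-length encode maximal interaction runs; (3) qualify runs of at
least `consecutive_licks` samples whose peak (default) or every sample
(`threshold_mode = "all"`) reaches `feeding_threshold`; (4) merge qualified
events separated by at most `gap`. Both comparisons are inclusive, so ties
are deterministic. The "peak" default reflects the usual tasting-versus-
licking reading of the threshold; merge-then-qualify was rejected because
the gap is defined between *events*, which only exist after qualification.
The gap takes an explicit unit — `"5 samples"` (the historical FLIC
convention, and the worked-example value) or `"1.0 s"`.

One subtlety the test suite documents: because merging happens after
qualification, event counts are *not* algebraically monotone in the
thresholds. Raising `feeding_minimum` can split one interaction run into
two qualified runs, or removing a middle run can split a merge group —
`[15, 5, 15]` with one required lick and a one-sample gap yields one event
at minimum 5 but two at minimum 6. On realistic signals (well-separated
bout plateaus) stricter parameters do call fewer events, and that is the
form in which the property is asserted; only monotonicity in the gap is
exact for arbitrary series. The event caller itself is verified against an
independent brute-force enumerator on the complete universe of series of
length ≤ 12 over `{0, minimum, threshold}` plus a thousand random series.

```{r}
call_feeding_events(c(6, 16, 16, 6),
                    params = event_params(5, 15, 2, "5 samples"),
                    sample_interval_ms = 200)
```

## Summaries

Events are binned on a half-open grid anchored at the midnight preceding
the recording start (zeitgeber-time display offsets are a presentation
concern, not a storage one). `sum` reports counts; `mean` divides by the
nominal samples per bin, giving a per-sample rate. One-minute bins are
supported but warned against on multi-day data — they mostly add noise.

Normalisation divides each well by its total (`sum` mode, the default) or
its maximum (`max` mode); the two conventions coexist in FLIC practice,
and both are offered with `sum` as default since comparing *fractions* of
a fly's feeding across the day is the more common goal. Zero-total wells
stay zero and are flagged. Once normalised, downstream stages (profile,
periodogram) consume the normalised series as-is.

Group statistics use the sample SD (n − 1) and SEM = SD/√n, with both
reported missing for single-well groups. Outliers are flagged with Tukey
fences (1.5 IQR beyond the hinges, quartiles as Tukey hinges via
`fivenum()`, matching boxplot-whisker convention), and only within
conditions of at least four wells. The day/night split assigns an event by
its *onset* time of day, day being the half-open `[lights_on, lights_off)`
— an event starting exactly at lights-off is a night event. Events
spanning the transition are therefore counted where they began; with
bouts of seconds against phases of hours, the alternative any-overlap rule
would change almost nothing but cost determinism.

The daily profile folds complete days onto one 24 h cycle. All (well, day)
observations in a condition are pooled per time-of-day bin and averaged;
the error bar (SEM or SD) is computed over that pool. Pooling, rather than
averaging days first and wells second, keeps the single-well case (where
the error must come from across-day variation) and the multi-well case
under one rule. Partial days are excluded; a recording without one
complete day has no profile and says so.

## The circadian periodogram

Rhythmicity is assessed in the DD window (trimmed whole-day inclusive,
like all date trims here). For a binned series $x_1 \dots x_N$ the power at
candidate period $k\Delta$ is the autocorrelation coefficient

$$r_k = \frac{\sum_{t \le N-k} (x_t - \bar x)(x_{t+k} - \bar x)}
             {\sum_t (x_t - \bar x)^2},$$

exactly the `stats::acf()` estimator; the peak of $r_k$ over the candidate
range (default 16–32 h, covering the circadian band around 24 h) estimates
the free-running period, ties resolving to the shorter period. The ACF is
scale-free, so normalisation upstream does not change it. Significance
uses the large-lag white-noise approximation $r_k \sim N(0, 1/N)$: the
one-sided per-lag threshold is $z_{1-\alpha}/\sqrt N$ (rhythm = positive
autocorrelation) and the peak's p-value is $1 - \Phi(r_{peak}\sqrt N)$,
floored at machine epsilon. Default inputs are 30-minute binned counts;
default $\alpha = 0.05$. A DD window under five days triggers a warning —
four days of 30-minute bins gives only 192 points, and period estimates
get visibly unstable.

Two honest caveats about this significance rule, both consequences of its
per-lag construction:

* **Calibration regime.** `acf()` divides an $(N-k)$-term numerator by the
  full $N$-term denominator, so $\mathrm{Var}(r_k) \approx (N-k)/N^2$: at
  short $N$ the nominal threshold is conservative at large lags. The null
  calibration test therefore uses long series (N = 8000 bins), the regime
  the normal approximation targets, where the per-lag exceedance lands on
  $\alpha$ within Monte-Carlo error.
* **Peak versus per-lag.** The threshold controls the exceedance of a
  *single* lag. The *peak* over the ~33 lags of the 16–32 h band exceeds a
  per-lag threshold far more often than $\alpha$ — on flat-rate (null)
  wells roughly half clear it. A single-well peak near the line is
  therefore weak evidence; group rhythmicity should be judged on the
  condition-average periodogram (`periodogram_summary()`), where
  well-to-well noise averages out and an arrhythmic group's curve sits
  clearly below the line while a rhythmic group's peak stands clear of it.
  The per-well table keeps the per-lag threshold because that is the
  convention FLIC analyses report; this paragraph is the required health
  warning.

## Validation scenarios and problem sizes

The package's end-to-end checks run on simulated study conditions chosen
once, as a power analysis, before any results were inspected:

* **Period recovery**: 100 wells with sinusoidal bout rate (mesor 60,
  amplitude 54 events/h — a high-count regime so the Poisson noise floor
  does not dominate the ACF), phase drawn uniformly per well so no
  alignment between rhythm and sampling grid is privileged, 4 DD days,
  full pipeline at a 1 s sample interval, 30-min bins. At these conditions
  ≥ 90% of wells recover 24 ± 0.5 h.
* **Use case**: 12 wells over 3 LD + 4 DD days, lights 09:00/21:00; wells
  1–6 bimodal (base 10, peaks +40 events/h, σ = 0.75 h) in LD and DD,
  wells 7–12 step (day 6 / night 12) in LD and flat 9 in DD. The wild-type
  profile peaks within one hour of both light transitions, all six wells
  show significant ~24 h periods, the mutant group's average periodogram
  stays below threshold, and the mutant night-feeding fraction exceeds the
  wild type's.
* Simulations for these scenarios use a 1 s sample interval rather than
  the hardware's 200 ms: every assertion operates on binned counts whose
  statistics are set by the bout process, not the sample rate, and the
  coarser grid keeps multi-well, multi-day experiments comfortably in
  memory.

## Known limitations

* Per-event microstructure (lick counts, durations, intensities) is
  retained in the event table but deliberately unused by the summaries;
  the analysis currency is event counts.
* No inferential statistics between groups are computed — export the CSVs
  to your statistics environment of choice.
* The significance rule is the stated normal approximation; numerical
  parity with other periodogram implementations is not guaranteed beyond
  that approximation.
* Food-choice (two-well) designs and real capacitance physics are out of
  scope for the simulator.
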
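# resthrv

Resting heart-rate variability (HRV) from wearable interbeat intervals, and
its within/between-person association with repeatedly measured health
variables.

Consumer wearables (smartwatches, chest straps, smartrings) emit interbeat
intervals (IBIs): the milliseconds between consecutive heartbeats. Resting
HRV computed from them — during sleep or upon waking — is a candidate
general-health biomarker. Analysing it against intensive longitudinal
health measures (daily stress, mood, behaviour, plus person-level baselines
and diagnoses) raises three problems this package solves end to end:

1. **Preprocessing.** Nocturnal windowing ([00:00, 05:00)), 5-minute
   segmentation, completeness screening (≥ 70% IBI coverage, inclusive),
   exclusion of segments with *any* recorded steps, spurious-beat filtering
   (absolute range 300–2000 ms plus a 25% running-median rule), cubic-spline
   tachogram interpolation at 4 Hz, and per-segment metrics — RMSSD, SDNN,
   and Welch-based HF/LF/VLF band powers — aggregated to person-night
   records.
2. **Two-level correlation.** With days *j* nested in persons *i*,
   `(x_ij, y_ij)' = μ + b_i + w_ij` with `b_i ~ N(0, Σ_B)`,
   `w_ij ~ N(0, Σ_W)`. The between-person correlation (off-diagonal of
   `Σ_B`, association of latent person means) and the within-person
   correlation (off-diagonal of `Σ_W`, association of daily deviations) are
   estimated by full maximum likelihood, with between-level age/gender
   adjustment, biserial correlations for binary person-level variables, and
   the variance-components intraclass correlation
   `ICC = Var(BP) / (Var(BP) + Var(WP))` via REML.
3. **Design analysis.** Seeded Monte Carlo power for both correlation
   tests in person × day designs, built on synthetic-data generators
   (IBI series with controllable RMSSD and artifacts; two-level panels
   with known correlation/ICC structure) that give every stage a ground
   truth.

## Worked example

Simulate a five-hour night with gaps, spurious beats and two movement
minutes; preprocess it; then estimate the two-level association between a
daily stress rating and nightly RMSSD on a simulated 300-person panel:

```r
library(resthrv)

sim <- simulate_ibi(ibi_config(duration = 18000, target_rmssd = 40,
                               gap_fraction = 0.05, spurious_rate = 2,
                               movement_minutes = c(30, 31), seed = 5))
night <- process_night(sim$series, sim$steps)
night$record
#>   person_id day_index context    rmssd     sdnn      hf       lf      vlf
#> 1        p1         1   night 41.07603 34.58098 494.476 458.2699 1672.571
#>       lf_hf n_valid_segments
#> 1 0.9764476               58
table(night$segments$status)
#>             kept low_completeness         movement
#>               58                1                1
```

The realized nightly RMSSD (41.1 ms) recovers the generator's 40 ms target;
of 60 nocturnal segments, one fell below the 70% completeness threshold
(gaps) and one overlapped the stepped minutes.

```r
psim <- simulate_panel(panel_config(300, 8, icc = 0.5,
  between_corr = matrix(c(1, .4, .4, 1), 2),
  within_corr  = matrix(c(1, -.15, -.15, 1), 2), seed = 9))
names(psim$panel)[5:6] <- c("stress", "rmssd")

multilevel_corr(psim$panel, "stress", "rmssd", covariates = c("age", "gender"))
#> Two-level correlation: stress ~ rmssd  [ml_latent]
#>   within   r = -0.172 (se 0.021), p = 4.93e-16  [small]
#>   between  r =  0.425 (se 0.055), p = 1.977e-14  [medium]
#>   n = 300 persons, 2400 observations; between level adjusted for age, gender

variance_components(psim$panel, "rmssd")
#> Variance components for 'rmssd': Var(BP) = 0.4589, Var(WP) = 0.4758, ICC = 0.491
#> n = 300 persons, 2400 observations
```

Both generating correlations (−0.15 within, 0.40 between) and the
generating ICC (0.5) are recovered within sampling error; the effect-size
labels use the conventional 0.10 / 0.30 / 0.50 thresholds.

Power for detecting a between-person correlation of 0.30 with 100
participants and 9 nights each:

```r
estimate_power(power_config(n_persons = 100, n_obs_per_person = 9,
                            true_between_r = 0.30, n_reps = 1000, seed = 1))
#> Power (between-level r, n = 100 x 9, true rB = 0.30, rW = 0.00, alpha = 0.050):
#>   0.808 (MC se 0.0125, 1000 reps, 0 degenerate)
```

A YAML-configured command-line wrapper over the same functions lives in
`inst/cli/resthrv.R` (subcommands `simulate`, `preprocess`, `associate`,
`power`).

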
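---
title: "Resting HRV from wearables: preprocessing, two-level correlations, and power"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Resting HRV from wearables: preprocessing, two-level correlations, and power}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(resthrv)
```

## The problem

Consumer wearables (wrist smartwatches, chest straps, smartrings) record
interbeat intervals (IBIs) — the time in milliseconds between consecutive
heartbeats — from which heart rate variability (HRV) can be computed.
Resting HRV, measured while asleep or immediately upon waking, is a
candidate general-health biomarker: it limits confounding by movement,
posture and daytime stimulants. Relating resting HRV to repeatedly measured
health variables (daily stress ratings, mood, behaviour) and to stable
person-level measures (diagnoses, questionnaires, biomarkers) requires three
methodological layers, each implemented here:

1. **IBI preprocessing** — turning a noisy beat stream into clean,
   analysis-ready five-minute segments and per-night metric records;
2. **two-level correlation estimation** — separating within-person
   (day-to-day) from between-person (average-level) association, which a
   pooled correlation conflates;
3. **design analysis** — Monte Carlo power for both kinds of correlation in
   person × day panel designs.

Because real study datasets of this kind are typically restricted, the
package ships seeded synthetic-data generators whose ground truth every
downstream stage is tested against.

## IBI preprocessing

A nocturnal recording is processed as:

* **Windowing.** Beats outside the half-open clock window [00:00, 05:00) are
  discarded, and the first interval after the boundary with them (its
  predecessor beat is unobserved). The window is a parameter
  (`window_h`).
* **Segmentation.** The window is tiled with contiguous half-open 300 s
  segments; a beat exactly on a boundary belongs to the later segment.
* **Completeness.** A segment is kept when its IBI coverage —
  the summed duration of valid intervals divided by 300 s — is at least
  0.70, inclusive. Coverage time was chosen over expected-beat-count
  because it does not depend on heart rate; the threshold and its
  inclusivity are parameters (`completeness_min`).
* **Movement.** Any segment overlapping a minute with a positive step count
  is dropped (reason `movement`): during movement, optical pulse detection
  is unreliable, and *any* steps disqualify the segment. Minutes missing
  from the step table are kept by default with a logged warning
  (`missing_policy`).
* **Artifact filtering.** Two rules, both exposed as parameters: an
  absolute physiological range of [300, 2000] ms (20–200 bpm), and a
  relative rule rejecting intervals deviating more than 25% from a running
  5-beat median. The relative rule catches the two dominant wearable
  artifact classes: split beats (one interval falsely detected as two short
  ones) and missed beats (two intervals merged into one double-length one).
  Rejected intervals are blanked, never re-invented: the beat grid only
  shrinks through the pipeline. If more than half of a segment's intervals
  are rejected the whole segment is invalidated (`artifact_burst`) — a
  burst that dense indicates the recording, not individual beats, is bad.
  Every segment ends in exactly one state: kept, low completeness,
  movement, or artifact burst.
* **Interpolation.** Spectral metrics need an evenly sampled series, so the
  valid (timestamp, IBI) pairs are interpolated with a natural cubic spline
  and sampled at 4 Hz (1200 samples per segment). Cubic splines at 4 Hz are
  the common choice for short-term HRV; both the method's rate and the
  spline are deliberate, declared choices rather than estimates of any
  particular vendor's behaviour.

Morning chest-strap recordings (2 or 5 minutes, taken seated upon waking)
skip windowing and segmentation: the recording is one segment.

### HRV metrics

Per kept segment: RMSSD (root mean square of successive differences — the
primary metric, closely tied to parasympathetic activity), SDNN (sample
standard deviation of intervals, n−1 denominator), and Welch-based band
powers HF [0.15, 0.40) Hz, LF [0.04, 0.15) Hz, VLF [0.0033, 0.04) Hz plus
the LF/HF ratio. Band limits follow the conventional short-term standards
and are overridable. The Welch estimator uses Hann-tapered windows of up to
512 samples (128 s) with 50% overlap and per-window linear detrending;
normalisation is checked against Parseval in the test suite (total spectral
power within 5% of tachogram variance). VLF is suppressed for recordings
under five minutes — the band's lowest period does not even complete once in
a shorter recording.

Segment metrics are aggregated to a person-night by unweighted mean across
valid segments (pooling all beats instead is a selectable alternative;
averaging was chosen as the default because it weights each 5-minute
window equally rather than each beat, making nights with variable coverage
comparable). Right-skewed metrics can be log-transformed (natural log),
stored alongside the raw values.

## Two-level correlations

With days *j* nested in persons *i*, each pair of variables is modelled as

$$\begin{pmatrix} x_{ij} \\ y_{ij}\end{pmatrix} = \mu + b_i + w_{ij},
\qquad b_i \sim N(0, \Sigma_B), \quad w_{ij} \sim N(0, \Sigma_W),$$

giving a **between-person correlation** (off-diagonal of $\Sigma_B$; the
correlation of latent person means) and a **within-person correlation**
(off-diagonal of $\Sigma_W$; the correlation of daily deviations). The
default estimator maximises the exact Gaussian likelihood. Implementation
choices that matter:

* The likelihood is evaluated from per-cluster sufficient statistics
  (cluster means and within-cluster cross-products), which makes a fit cost
  linear in the number of persons and independent of observations per
  person — fast enough for thousand-replicate power runs.
* The two means are profiled out by generalised least squares at each
  candidate covariance, reducing the optimisation to six parameters.
* Variances are optimised on the log scale and correlations on the
  atanh scale (BFGS, moment-based starting values), keeping every iterate
  inside the parameter space.
* Standard errors come from the observed information (numerical Hessian of
  the profile likelihood). The reported test is a Wald z of the correlation
  divided by its delta-method standard error. The test is computed on the
  correlation scale, not the atanh scale: as $|\hat r| \to 1$ the atanh-scale
  standard error diverges faster than the estimate grows, so a z-scale Wald
  statistic collapses for near-perfect correlations while the r-scale
  statistic behaves correctly; at moderate $|r|$ the two agree closely.
* Degenerate inputs are guarded, not mis-fit: fewer than 3 persons — no
  between estimate; no person with 2 paired days, or zero day-level
  variance — no within estimate; single-observation panels are flagged as
  carrying no within-person information.

A method-of-moments estimator (`estimator = "moments"`) is kept for
transparency: person-centered Pearson correlation at the within level and a
Pearson correlation of observed person means at the between level. The
latter is attenuated when persons contribute few days (observed means are
noisy versions of latent means), which is exactly why the latent ML route
is the default; with many observations per person the two agree to ~0.02
and the test suite checks this.

**Covariate adjustment.** Between-person correlations are adjusted for age
and gender by residualizing both variables on the person-constant
covariates before fitting. Because the covariates are constant within
person, ordinary least-squares residualization removes only between-level
variance, leaving the within-person estimate untouched — the adjusted
between-person correlation is a partial correlation at that level.

**Binary variables.** Person-level binary measures (diagnoses, status
codes) use the biserial correlation, which estimates the latent-normal
correlation under the assumption that the dichotomy cuts an underlying
normal variable. Small-sample estimates can exceed 1 in magnitude and are
clipped with a flag. Day-level binary variables are out of scope and
guarded against by construction (binary variables in the generator are
person-level).

**ICC.** The intraclass correlation
$\mathrm{ICC} = \mathrm{Var}(BP) / (\mathrm{Var}(BP) + \mathrm{Var}(WP))$
is computed from a one-way random-intercept model fitted by REML (lme4);
REML bounds the between component at zero so no negative variance or
out-of-range ICC can be reported. Effect sizes are labelled by the
conventional |r| thresholds 0.10 / 0.30 / 0.50 (inclusive). p-values are
reported raw; no multiple-comparisons adjustment is applied anywhere.

Lagged designs ("health measure today, HRV the following night or next
morning") are expressed with `align_lag()`, which joins on a shifted day
index and drops (and counts) unmatched boundary days.

## The synthetic-data generators

**IBI generator.** Intervals follow a sinusoidal
respiratory-sinus-arrhythmia term plus AR(1) Gaussian noise, shifted to the
mean interval. This model was chosen because its expected RMSSD is
available in closed form — the sinusoid contributes
$2A^2\sin^2(\pi f \Delta)$ to the mean squared successive difference and
the AR(1) term $2\sigma_e^2(1-\phi)$ — so the innovation variance can be
solved exactly for a requested RMSSD, and an amplitude too large for the
target is an explicit configuration error. Artifacts are then injected with
known counts: contiguous missing-beat gaps, split beats, missed beats, and
positive step counts in chosen minutes. Defaults (900 ms mean interval,
40 ms RMSSD, 0.25 Hz respiration, 5 h duration) describe a healthy adult's
night.

What the generator does *not* emulate — and therefore what passing
recovery tests do and do not show about real data: circadian sleep
architecture and stage transitions, device-specific noise signatures and
their autocorrelation, non-sinusoidal or drifting respiration, and
correlated gap/movement processes. Tests against it demonstrate that the
pipeline computes what it claims on data with known truth, not that any
wearable meets its nominal accuracy.

**Panel generator.** Variables are generated as person effect + day effect
with configurable between/within correlation matrices (validated symmetric
PSD with unit diagonal; the offending eigenvalue is named otherwise) and
per-variable ICC, unit total variance per variable. Age (uniform, default
18–65) and gender (Bernoulli(½)) act on the between level only, so
covariate adjustment can be tested against a known partial correlation.
Binary variables threshold the latent person-level value at the quantile
matching the requested marginal probability. Truth objects store every
generating parameter plus the realized latent person means.

## Power simulation

`estimate_power()` wraps the generate → estimate → test loop: panels from
the generator, the target-level correlation estimated by the two-level ML
estimator, rejection recorded at two-sided α. Defaults mirror the reference
design for sample-size guidance in this literature: 100 persons × 9
observations, ICC 0.5 for both variables, α = 0.05, the non-target level's
correlation set to 0, 1000 replicates. The Monte Carlo standard error
$\sqrt{\hat p(1-\hat p)/n_{\mathrm{reps}}}$ is reported with every result
(±1.3 percentage points at 1000 replicates); replicates that cannot be
estimated are counted and more than 5% of them is an error. Under this
design the between-person test at r = 0.30 and the within-person test at
r = 0.10 both sit at approximately 80% power — the basis for the "at
least 100 participants / 900 observations" guidance; power at these exact
design points is near the boundary, so individual 1000-replicate runs
scatter within about ±1.5 points of 80%.

## Problem sizes and numerical tolerances

The test suite runs everything at desk scale, chosen to keep Monte Carlo
noise well below the assertion tolerances: parameter-recovery panels use
1000 persons × 10 observations (estimates asserted within 3 model standard
errors; ICC within ±0.03); power and type-I calibration runs use 1000
replicates (assertions within 3 binomial MC standard errors); formula
oracles compare against brute-force loop implementations at 1e−9 on 1000
random inputs. Time-domain hand examples are asserted exactly; spectral
assertions allow 5% (Parseval, sinusoid amplitude) reflecting taper
leakage.

## Known limitations

* The ML estimator assumes joint normality and complete (x, y) pairs per
  person-day; pairs are formed by inner join and incomplete days dropped.
* Biserial standard errors use Soper's large-sample approximation; for
  very small n or extreme splits, prefer the clipped-estimate flag as a
  warning sign.
* Week-level designs are handled by reading `day_index` as a week index;
  no calendar alignment is attempted.
* The IBI generator's spectral content is controlled at the respiratory
  peak only; out-of-band power follows from the AR(1) term rather than
  being independently settable.
* No beat detection from raw PPG/ECG, no sleep staging, no time-zone
  arithmetic: timestamps are milliseconds on one local clock.
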
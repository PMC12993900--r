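---
title: "Methods: CGM signal repair, excursion detection and agreement analysis"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: CGM signal repair, excursion detection and agreement analysis}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(glyco)
```

## The problem

Continuous glucose monitoring (CGM) sensors read interstitial glucose
every 5 minutes in free-moving animals. In growing pigs the raw readings
cannot be taken at face value: the occasional sample is dropped as
off-scale (`NaN`), the signal carries autocorrelated sensor noise, the
sensor trails blood glucose by a physiological interstitial delay, and —
because porcine erythrocytes are impermeable to glucose — CGM readings
systematically over-estimate plasma glucose. `glyco` packages the full
analysis chain needed to turn such traces into interpretable glycemic
metrics: signal repair and smoothing, classical variability indices,
baseline-band excursion detection over night/day/postprandial windows,
CGM-versus-blood alignment and agreement, a cohort statistics layer, and
a synthetic-cohort generator that stands in for undeposited sensor data.

## Signal repair and smoothing

A trace enters as a 5-min series with a missingness flag per sample.
`repair_missing()` fills isolated single gaps by linear interpolation of
the two neighbours and reconstructs runs of two or more consecutive gaps
with a shape-preserving piecewise cubic Hermite interpolant
(Fritsch–Carlson, via `stats::splinefun(method = "monoH.FC")`), fitted to
all observed samples. Shape preservation matters: an ordinary cubic
spline can overshoot through a gap and fabricate a spurious excursion,
which the detector downstream would then count. No extrapolation is ever
attempted — traces with leading or trailing gaps are rejected.

`smooth_savgol()` applies Savitzky–Golay least-squares polynomial
smoothing. The filter's defining property — exact reproduction of
polynomials up to the fitted order — is what makes it the standard choice
for CGM work: it denoises without flattening the rounded top of a
postprandial peak the way a moving average would. The reference study's
exact parameters are not recoverable (they defer to an inaccessible
source), so the defaults here are **window = 9 samples (45 min), order
= 3**, chosen as the mildest setting that visibly suppresses AR(1)
sensor noise on synthetic traces while leaving meal-peak amplitude
essentially intact; both are arguments and config keys, and no test
depends on the specific default. Edges use truncated-window refits so
length and timestamps are preserved.

`resample_minutely()` interpolates (not smooths) a repaired trace onto a
1-min grid with a cubic spline, preserving original samples exactly. It
exists because 5-min sampling is too coarse for the cross-correlation
lag search: the Nyquist limit of the native grid would quantize the lag
estimate to multiples of 5 min.

## Variability metrics

* **MAGE** (`compute_mage()`): alternating turning points of the trace
  are enumerated (plateaus compressed to their first sample, endpoints
  included); swings between consecutive extrema qualify when their
  absolute amplitude exceeds one sample SD (n−1) of the window. `mage`
  is the mean qualifying amplitude, split into `mage_up`/`mage_down` by
  direction, and is reported `NA` — deliberately not 0 — when nothing
  qualifies. Whether the original study's software computed MAGE on
  smoothed or raw values is unknowable; the package convention is the
  unsmoothed repaired trace, pinned by a brute-force oracle in the test
  suite, with smoothing available by composition.
* **CONGA(n)** (`compute_conga()`): the sample SD of differences
  `g(t) − g(t − n h)` over all valid `t` on the uniform grid. Note that
  on a finite window the differences need not have zero mean, so CONGA
  on a pure sinusoid converges to the textbook `√2·A·|sin(πn/24)|` limit
  only as the window grows; the tests therefore check the exact
  finite-window closed form.
* **Time-in-range** (`compute_time_in_range()`): per-sample
  classification against the euglycemic range, default 70–180 mg/dL,
  with the asymmetric clinical convention `< 70` hypoglycemic and
  `≥ 180` hyperglycemic. The three fractions always partition.

## Baseline band and excursions

Each animal is its own reference: `compute_baseline()` takes the mean ±
one sample SD of observed glucose over a stated window. The package
default ties the analysis of a day (and of its postprandial window) to
the **preceding night's** band — the fasted nocturnal state — which is
the convention that makes "peaks after the morning meal" meaningful.
(The source protocol is self-contradictory on this point, naming both
the following day and the night before; the night-before reading is the
one its results actually use, and `compute_baseline()` accepts any
window, so the other convention is a one-line change.)

"Above/below the baseline" is interpreted as strictly outside the ±1 SD
band, not merely off the mean — otherwise the SD in the definition would
do nothing. `detect_excursions()` finds maximal runs of consecutive
samples strictly above the upper edge (peaks) or below the lower edge
(nadirs). Each run carries:

* **duration** — minutes between its first and last sample (a
  single-sample excursion has duration 0, mirroring a first-to-last
  definition),
* **extremum** — highest (peak) or lowest (nadir) value and its time,
* **AUC** — trapezoidal integral of the excess beyond the *crossed band
  edge*, over the run samples only, in mg/dL·min. The reference level is
  a genuine modelling choice (edge vs band mean vs zero); the crossed
  edge keeps "no excursion ⇒ zero area" exact and makes the toy-trace
  oracle integral exact, at the price of AUC magnitudes that are not
  comparable to conventions integrating from zero.

`summarize_period()` aggregates a window: counts, total durations and
AUCs by kind, window max/min, the sharpest peak (highest extremum,
earliest on ties) and nadir (lowest), band-time fractions, and the
relative range `100·(max − min)/max`. The denominator of that percentage
is undefined in the source material; the window maximum is the package's
documented choice.

`resolve_windows()` turns clock-time windows into calendar intervals:
night 21:00–06:55 (wrapping midnight, labelled by its starting day), day
07:00–20:55, postprandial 08:45–13:00 on meal-test days (from the first
blood draw 15 min before the 09:00 test meal to the end of the sampling
schedule). Windows are endpoint-inclusive on the 5-min grid — a sample
at exactly 06:55 is nocturnal — giving 120 night samples per night.

## Alignment and agreement

`estimate_lag()` mean-centers both 1-min series and computes the
normalized cross-correlation by FFT, scanning integer lags in
`[−max_lag, +max_lag]` (default 60 min). Per-lag normalization uses the
overlapping segments, so identical inputs score exactly r = 1 at lag 0.
**Sign convention: positive lag = the CGM trails blood glucose**, i.e.
`cgm(t) ≈ blood(t − lag)` — the physiological interstitial delay. There
is no sub-minute parabolic refinement: the estimate is an index on the
1-min grid converted to a time difference. A flat correlation peak is
the real accuracy limit here — smooth glucose dynamics plus
autocorrelated noise move the argmax by a minute or two on short
windows, which is why the recovery tests run on full-length multi-day
traces.

`shift_trace(trace, lag)` translates values by `lag` samples on the
fixed time grid, padding vacated positions with the first (or last)
original value; aligning a trailing CGM trace therefore means
`shift_trace(cgm, -estimated_lag)`, which is what `estimate_lag()`
returns ready-made.

`plasma_to_blood()` maps plasma to whole-blood-equivalent glucose by the
plasma-fraction model `blood = plasma × (1 − hematocrit)`: since porcine
red cells carry no glucose, whole-blood glucose is confined to the
plasma volume. The factor form is an argument (`factor = "identity"`
disables it) because the source describes only "applying the hematocrit
value as a conversion factor"; the impermeable-erythrocyte rationale
selects the plasma-fraction reading.

`bland_altman()` reports bias (mean of A − B), the sample SD of
differences, and 95% limits of agreement `bias ± 1.96·SD` — the n−1
convention throughout, like every SD in this package.

## Statistics layer

* `rm_correlation()` — repeated-measures correlation: subject-mean-center
  both variables, pool, Pearson-correlate, `df = N − k − 1` (N
  observations, k subjects), two-sided t-test. Exactly invariant to
  per-subject additive offsets; reduces to ordinary Pearson for one
  subject.
* `spearman_screen()` — every night metric against every postprandial
  metric across matched animals, flagged `significant` (p ≤ 0.05) /
  `trend` (p ≤ 0.10) / `ns`. Deliberately **uncorrected** (it mirrors an
  exploratory screen and is labelled as such); Benjamini–Hochberg flags
  are available behind `adjust = "BH"`.
* `diet_anova()` — one-way fixed-effects ANOVA. With a single factor
  there is no Type-I/III distinction, so the night-vs-day comparison
  reuses the same routine with period as the factor.
* `variance_f_test()` — two-sided variance-ratio F test, used to compare
  inter-individual spread of a metric between periods.
* `pca_metrics()` — columns standardized to unit sample SD, SVD, no
  rotation; explained-variance fractions sum to 1, constant columns are
  an error naming the column.

## The synthetic cohort: what it emulates, and what it does not

Because no raw sensor data are deposited, every stage is exercised
against `simulate_study()`. Its defaults state one fixed world, chosen
once from the magnitudes the study context reports, and are not tuned to
tests:

| parameter | default | rationale |
|---|---|---|
| cohort | 8 animals × 5 days, 5-min grid | the pilot design |
| basal glucose | 100 mg/dL | normoglycemic growing pig |
| circadian amplitude | 8 mg/dL, peak mid-afternoon | mild infra-day drift |
| meals | 08:30 and 16:00; 09:00 test meal on days 2 and 5 | husbandry schedule |
| meal amplitude | 60 (HS) → 35 (HF) mg/dL, linear in the mix | peak readings ≈154 vs ≈128 mg/dL over a ~100 baseline |
| time-to-peak | HS 35–55 min, HF 20–155 min, per animal | the reported onset spread |
| decay half-life | 45 min | postprandial return within ~3 h |
| nocturnal wavelets | Poisson(2)/night, ±15–35 mg/dL, 30–90 min | ~1.5–2.3 nocturnal peaks and nadirs per night |
| sensor | +20 mg/dL bias, AR(1) noise SD 5 (φ = 0.7), 14-min lag | over-reading, correlated error, interstitial delay |
| missingness | 0.5% of interior samples | "extremely rare" dropped readings |
| hematocrit | 0.42 | typical for this age |
| assay noise | SD 2 mg/dL | duplicate colorimetric assay |

The generator is deterministic per `(seed, animal)` with independent
sub-streams for meals, wavelets, sensor noise and assay noise, and
`simulate_study()` retains a truth record (lags, amplitudes, wavelet
times) for parameter-recovery tests.

What it does **not** emulate — and therefore what a green test does not
establish: insulin–glucose feedback dynamics (meal responses superpose
linearly), sensor drift and day-one insertion artefacts, compression
lows, animals tearing sensors off, behavioural feeding variation, or any
dependence of noise on glucose level. Green tests establish that the
pipeline recovers what was injected into this stylized world, not that
the biology is this simple.

## Numerical conventions and degenerate inputs

* All SDs and variances use the n−1 (sample) convention.
* All internal computation is in minutes since trace start; timestamps
  are absolute POSIXct (UTC by default) so calendar windows resolve.
* Units are mg/dL internally; mmol/L is converted (×18.016) at the
  reader boundary only.
* A degenerate baseline band (SD = 0) warns and proceeds — every
  off-mean sample then opens an excursion — rather than erroring, so a
  constant reference night does not kill a whole animal.
* MAGE with no qualifying swing, and sharpest-excursion fields of an
  excursion-free window, are `NA`, never 0.
* Ties for the sharpest excursion go to the earlier run; plateaus in the
  turning-point scan take the first plateau sample.
* Per-animal pipeline failures are caught and logged; the run only fails
  when every animal fails.

## Limitations

The package computes per-trace lags and reports their cohort mean;
whether a single global lag would be more appropriate is left to the
analyst. AUC magnitudes depend on the band-edge reference convention and
are not comparable across conventions. The Spearman screen at n = 6–8
animals is exploratory by construction: with dozens of metric pairs and
no correction, isolated "significant" flags are expected under the null.
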
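---
title: "Circadian actigraphy analysis: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Circadian actigraphy analysis: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(actirhythm)
```

## The problem

Implantable accelerometer tags record a rodent's locomotor activity (counts
per fixed bin, typically 5 min) and core body temperature continuously for
weeks, under a 12:12 light-dark (LD) cycle and/or constant darkness (DD).
Three questions recur in studies that compare genotypes with such data:

1. **Phase**: when does the consolidated active phase start and end each day
   (activity onset, offset, midpoint, peak), and do groups differ in these?
2. **Period**: what is each animal's endogenous free-running period τ in DD,
   and do groups differ by minutes per cycle?
3. **Masking response**: how quickly do activity and temperature rise after
   the lights-off transition, and is one group hypersensitive to it?

`actirhythm` implements one defensible, fully specified pipeline for all
three, plus a synthetic cohort generator so every stage can be validated
without animal data.

## Time conventions

Zeitgeber time (ZT) is anchored at lights-on: ZT0 = lights-on, ZT12 =
lights-off under 12:12. Internally all computation uses seconds since the
start of the recording; ZT appears only at presentation boundaries, which
avoids wall-clock ambiguities. Light intervals are half-open, `[on, off)`:
the lights-off instant itself belongs to the dark phase, so the first bin
aligned to a lights-off transition is the first dark bin. In DD, the ZT
frame keeps ticking at 24 h/day from the last LD anchor; free-running
markers therefore drift through ZT, which is exactly what makes the drift
measurable as clock times.

## Phase markers (`detect_markers`)

Per ZT day, activity onset is the first time in a ZT6-to-ZT6-next-day search
window at which a 3-h centred moving average of activity rises above a 24-h
centred moving average; offset is the first subsequent fall below. The
crossing time is the start time of the first bin on the new side. The
midpoint is the earliest time at which cumulative activity from onset
reaches half of the total over a fixed 16-h span from onset; the peak is the
earliest maximum of a 1-h moving average within `[onset, offset]`.

Design notes:

* **Crossing direction.** The source method for onset detection is sometimes
  stated with the long and short averages interchanged; we define onset as
  the *short* average rising above the *long* one, which is the standard
  convention (the long average is the day's midline; the short average
  tracks the current bout). The direction is exposed as
  `marker_options(direction = )` for anyone wanting the inverted reading.
* **Centred windows.** All three moving averages are centred rather than
  trailing, so phase estimates carry no systematic lag; positions whose full
  window leaves the record are undefined, and edge days are dropped rather
  than padded. For even window sizes (24 h at 5-min bins is 288 bins) the
  centre is taken with `floor((w-1)/2)` bins before and the remainder after;
  on a symmetric square wave this places onset exactly on the rising edge.
* **Day segmentation.** The search window runs ZT6 → ZT30 so a nocturnal
  onset near ZT12 is interior; first crossing wins, ties break earliest.
  Offsets that fall past ZT24 are reported with carry-over (values > 24)
  so per-animal means are never wrapped through midnight.
* **16-h midpoint span.** The normalising span for the midpoint is kept at
  16 h by default and exposed as `midpoint_span`; if the span runs past the
  record end, that day's midpoint (only) is undefined.
* **Units of inference.** Markers are computed per day, averaged per animal
  (`summarize_markers`), and group tests run on the per-animal means;
  animals, not animal-days, are the independent units.

## Free-running period (`estimate_period`)

The period is the location of the maximal FFT power within a 20-28 h search
band. The raw Fourier resolution of a 13-day record is ~1.8 h near 24 h —
two orders of magnitude coarser than the minute-scale group differences of
interest — so the estimator (i) zero-pads by an oversampling factor
(default 64), and (ii) refines the peak by quadratic interpolation of
log-power over the peak and its two neighbours. A Hann taper (default)
suppresses leakage from the strong harmonics of square-ish activity
profiles; detrending defaults to mean removal, with linear detrend available
for drifting baselines. The activity channel is the default; temperature is
available via `channel = "temperature"`.

With these defaults the estimator recovers a noiseless 24.000-h cosine
sampled at 5-min bins for 13 days to well under 0.005 h, a deterministic
simulated 23.700-h free-runner to under 0.01 h, and under default Poisson
count noise its per-animal error has sub-half-minute bias and roughly
half-minute SD (the test suite and `scripts/acceptance.R` recompute these).
Peaks on a band edge are flagged (`edge = TRUE`), not errors; a spectrum with
essentially no band power (< 1e-9 of total) raises a "no circadian
periodicity" error rather than returning noise.

## Light-transition responses

`align_to_transition` averages each animal's activity or temperature over
all occurrences of a lights-off (or lights-on) event on a relative grid
(bin 0 = first dark bin), and `per_bin_compare` runs a two-tailed two-sample
t-test per relative bin across animals. Raw p-values reproduce the
uncorrected multiple-t-test presentation common in this literature;
Holm-adjusted p-values are reported alongside as the defensible default.
Pooled-variance Student's t is the default, Welch behind a flag. Bins where
both groups have zero variance and equal means are flagged degenerate
rather than raising.

`onset_latency` operationalises "speed of the activity increase after
lights-off" — a quantity often described but rarely defined — as the time
from lights-off to the first bin reaching 50% of that day's dark-phase mean
activity (threshold exposed as `threshold_frac`), per day, averaged per
animal. Days whose dark phase has zero activity are flagged undefined.

## Group statistics

`students_t` is a degenerate-safe wrapper over the pooled-variance t-test.
`mann_whitney` computes U from midranks and, for combined n ≤ 20, obtains
the exact two-sided p by enumerating all `choose(n_a + n_b, n_a)`
assignments of the observed pooled values (ties handled by enumeration over
the actual values); the two-sided p is the null probability of
`|U - n_a n_b / 2|` at least as extreme as observed, which equals the
doubled one-sided tail in symmetric tie-free cases. At n = 5 vs 5 with
complete separation this gives 2/252 ≈ 0.0079 — the smallest achievable
two-sided exact p at those group sizes, and a value only an exact method
can produce. Above combined n = 20 a tie-corrected normal approximation
with continuity correction is used. `holm_adjust` delegates to
`stats::p.adjust`.

## The synthetic generator (`simulate_animal`)

The generator emulates the statistical structure the analyses assume, not
any particular animal:

* A latent drive `s(t)` in `[0, 1]` follows first-order relaxation towards a
  piecewise-constant target: 1 in the (subjective) night starting
  `onset_latency` minutes after each lights-off with time constant
  `rise_time`, and `light_suppression` in the (subjective) day with time
  constant `fall_time`. Under DD the target square wave free-runs at period
  `tau` with half the cycle active. The relaxation is integrated exactly per
  segment and averaged over a 60-s subgrid per bin, so the deterministic
  drive is reproducible to machine precision. A pure-cosine waveform is
  available for spectral tests, and an optional two-state ultradian
  modulation (off by default) adds bout structure.
* Counts per bin are negative binomial with mean
  `baseline_rate + amplitude * s` and dispersion `dispersion` (Poisson at
  `Inf`, the default; exactly the rounded mean in deterministic mode).
  Rodent activity counts are typically overdispersed, and the dispersion
  knob lets tests set the noise level precisely.
* Temperature is driven by the low-pass-filtered drive
  (`temp_smooth`, first-order), not by the realised counts — the weakest
  defensible coupling, keeping the two channels conditionally independent
  given the drive — plus Gaussian noise.
* One master seed yields per-animal substreams (`simulate_cohort`), so
  cohorts are exactly reproducible while animals are independent.

Default parameter choices and what they represent: `baseline_rate = 2` and
`amplitude = 40` counts per 5-min bin give a strongly nocturnal profile with
a realistic signal-to-noise for an implanted accelerometer;
`light_suppression = 0.05` encodes near-complete masking by light;
`tau = 23.7 h` is the canonical free-running period of laboratory mice;
`onset_latency = 40 min` / `rise_time = 30 min` / `fall_time = 20 min`
produce an activity rise over the first post-lights-off hour as seen in
entrained wild-type-like profiles; `temp_base = 36.2` °C with
`temp_amplitude = 1.2` °C and a 45-min smoothing constant reproduce the
~1 °C day-night core temperature swing that telemetry shows; temperature
noise SD is 0.1 °C. The `del_like` preset differs in exactly the programmed
phenotype: `tau` longer by 5.3 min and a faster lights-off response
(`onset_latency = 15`, `rise_time = 12` min).

What the generator does **not** emulate — and hence what passing tests do
not show about real data: ultradian bout structure is off by default, there
is no two-process sleep homeostat, no torpor, no sex or strain effects, no
cage-mate interactions or fighting artifacts, and activity "counts" are
abstract (tag acceleration thresholds are vendor-specific), so all analyses
are deliberately unit-free and scale-invariant.

## Numerical choices and degenerate inputs

* Moving averages use cumulative sums (relative error ~1e-13 on realistic
  lengths); positions without a full window are `NA`, never partial.
* The spectrum excludes frequency 0 from the peak search; interpolation is
  skipped (and flagged) on band edges or non-concave log-power triplets.
* Day windows require fully defined moving averages; records shorter than
  3 days yield no marker days and an informative error.
* Zero-variance group comparisons: equal means → degenerate flag with `NA`
  p; unequal means → p = 0 limit, flagged.
* Validation errors from the CSV readers name the offending row; a dropped
  activity bin is a format error because the analysis assumes a complete
  activity grid (missing temperature, by contrast, is representable as an
  empty cell).

## Problem sizes used in the test suite

The suite validates on the scales the methods are designed for: 42-day LD
and 13-day DD records at 5-min bins, cohorts of 5 animals per group, 100
replicate cohorts for the detectability and ordering checks, 20 seeds for
the period-noise calibration, and exhaustive enumeration up to combined
n = 8 for the exact rank test. These are the package's chosen validation
conditions; they mirror the durations and group sizes typical of long-term
telemetry studies.

## Known limitations

* Marker detection assumes a consolidated (unimodal) active phase per day;
  strongly bimodal or arrhythmic animals yield `valid = FALSE` days rather
  than forced markers.
* The FFT estimator assumes a complete, evenly sampled series; gapped data
  would need a Lomb-Scargle or chi-square periodogram, which are out of
  scope.
* The exact Mann-Whitney enumerates up to combined n = 22; beyond that the
  normal approximation is used.
* Actogram plotting is intentionally minimal: the package's outputs are
  tables, and presentation graphics are left to the caller.
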
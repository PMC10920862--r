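# actirhythm

Circadian analysis of long-term rodent actigraphy: activity counts and body
temperature logged in fixed 5-minute bins by an implantable
accelerometer/thermometer tag, recorded for weeks under a 12:12 light–dark
(LD) cycle and/or constant darkness (DD).

The package is for chronobiologists and behavioural neuroscientists who need
to compare genotypes (or treatments) on three quantitative axes:

1. **Daily phase markers.** Per day, activity *onset* is the first time a
   3-h centred moving average of activity rises above a 24-h centred moving
   average; *offset* is the subsequent fall below; the *midpoint* halves the
   cumulative activity over a 16-h span from onset; the *peak* is the
   maximum of a 1-h moving average. Markers are averaged per animal, and
   animals are the units of inference.
2. **Free-running period.** Each animal's endogenous period τ in DD is the
   location of the maximal FFT power in the 20–28 h band, refined far below
   the raw Fourier resolution by zero-padding (64×) plus quadratic
   log-power peak interpolation — minute-scale group differences in τ are
   resolvable from ~2-week records.
3. **Light-transition responses.** Daily mean ± SEM profiles of activity and
   temperature, lights-off-aligned response curves with per-bin two-sample
   t-tests (raw and Holm-adjusted), and a lights-off *response latency*
   (time to reach 50% of the dark-phase mean activity).

Group comparisons use the two-tailed pooled-variance Student's t-test and an
**exact Mann–Whitney U test** whose small-sample p-values come from full
enumeration of all `choose(n_a + n_b, n_a)` group assignments — at n = 5 vs 5
with complete separation this yields the exact minimum two-sided p of
2/252 ≈ 0.0079, which no normal approximation reproduces.

A seeded synthetic cohort generator (`simulate_animal`, `simulate_cohort`,
`genotype_presets`) emulates the recordings — entrained LD rhythm with a
lights-off response latency, free-running DD rhythm with a programmable τ,
negative-binomial count noise, and a temperature channel low-pass-coupled to
the activity drive — so the whole pipeline is testable without animal data.

## Worked example

Simulate two 5-animal groups for 6 weeks of LD — a wild-type-like preset and
a preset with a 5.3-min-longer free-running period and a faster lights-off
response — then detect markers and compare groups:

```r
library(actirhythm)

pr  <- genotype_presets()
sch <- light_schedule("LD")
co  <- simulate_cohort(list(list(group = "wt",  n = 5, params = pr$wt_like),
                            list(group = "del", n = 5, params = pr$del_like)),
                       sch, days = 42, master_seed = 1)
ms  <- summarize_markers(cohort_markers(co$records))
lat <- cohort_latencies(co$records)
group_report(ms, latencies = lat)
#>      quantity group_a group_b n_a n_b mean_a mean_b      t df      p_t  U    p_mw
#> 1    onset_zt      wt     del   5   5   13.0   12.4 113.04  8 4.19e-14 25 0.00794
#> 2   offset_zt      wt     del   5   5   24.4   24.3  16.84  8 1.56e-07 25 0.00794
#> 3 midpoint_zt      wt     del   5   5   19.0   18.6  45.76  8 5.75e-11 25 0.00794
#> 4     peak_zt      wt     del   5   5   19.2   18.2   3.75  8 5.61e-03 24 0.01587
#> 5     alpha_h      wt     del   5   5   11.4   11.9 -74.64  8 1.16e-12  0 0.00794
#> 6 latency_min      wt     del   5   5   57.6   23.4  65.93  8 3.12e-12 25 0.00794
```

The del-like group starts activity ~0.6 h earlier after lights-off (onset
ZT12.4 vs ZT13.0) and reaches half its dark-phase activity in 23 min vs
58 min — the programmed hypersensitivity to the light-to-dark transition,
detected by both the t-test and the exact rank test.

Free-running periods from a 13-day DD recording:

```r
dd   <- light_schedule("DD")
codd <- simulate_cohort(list(list(group = "wt",  n = 5, params = pr$wt_like),
                             list(group = "del", n = 5, params = pr$del_like)),
                        dd, days = 13, master_seed = 2)
pd <- cohort_periods(codd$records)
group_compare(pd, "period_h")
#>   quantity group_a group_b n_a n_b mean_a mean_b     t df      p_t U    p_mw
#> 1 period_h      wt     del   5   5   23.7   23.8 -17.8  8 1.02e-07 0 0.00794
```

Per-animal recovered periods (wt 23.688–23.704 h, del 23.785–23.812 h)
straddle the programmed 5.3-min difference; it is detected at p ≈ 1e-7
despite a raw Fourier resolution of ~1.8 h.

A thin command-line front end over the same functions lives at
`inst/cli/actirhythm.R` (subcommands `simulate`, `phases`, `period`,
`response`, `report`).

## Method details

See the methods vignette (`vignettes/actigraphy-methods.Rmd`) for the model
assumptions, parameter meanings and defaults, numerical choices, and known
limitations.
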
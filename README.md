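# sentrend

Spectral-entropy trend analysis of preictal intracranial EEG.

## What it does

In focal epilepsy, the minutes before a seizure may carry a reorganization
of the EEG power spectrum that is invisible by eye. `sentrend` quantifies
it with the **normalized spectral entropy** (SEN) of the focal channel,

    SEN = -Σ_k P_k log P_k / log N,

where `P_k` are the in-band power-spectrum values normalized to sum to 1
and `N` is the number of in-band frequency bins: SEN = 1 for a flat
(maximally dispersed) spectrum, 0 for all power in a single bin. The
pipeline

1. extracts the preictal segment (32 to 0 minutes before onset),
2. removes 50 Hz line noise with a 41-tap linear-phase FIR notch,
3. splits the signal into low (0.1–12 Hz), mid (12–32 Hz) and high
   (32–128 Hz) bands with order-40 Hamming-window FIR filters,
4. computes SEN on non-overlapping 16 s windows (4096 samples at 256 Hz,
   1024 spectral bins),
5. fits a regression line (slope `p`, in SEN per minute) and Pearson
   correlation `r` over the −32 to −4 minute interval, plus a centered
   4-minute moving average for display, and
6. aggregates per-patient `(p, |r|)` triplets into a cohort table with
   band means and slope-sign counts.

A seeded synthetic EEG generator (`synth_spec()` / `generate_eeg()`)
produces 1/f background, line noise, epileptiform-like spikes and a
*programmable per-band SEN drift*, so every stage is testable with known
ground truth. The packaged `cohort_reference()` table carries the published
per-patient slopes and correlations of a 20-patient invasive
focal-epilepsy cohort for the cohort-level arithmetic.

## Worked example

```r
library(sentrend)

rec <- generate_eeg(synth_spec(drift = c(high = 0.005), seed = 42))
res <- run_record(rec, "ch1")
tidy(res)
#> # A tibble: 3 × 9
#>   record_id    band  n_points slope_per_min  slope_se intercept        r   abs_r degenerate
#>   <chr>        <fct>    <int>         <dbl>     <dbl>     <dbl>    <dbl>   <dbl> <lgl>
#> 1 synth-seed42 low        105    -0.0000345 0.000464      0.763 -0.00733 0.00733 FALSE
#> 2 synth-seed42 mid        105     0.0000217 0.0000726     0.943  0.0294  0.0294  FALSE
#> 3 synth-seed42 high       105     0.00476   0.0000783     0.923  0.986   0.986   FALSE
```

The high band recovers the programmed +0.005 SEN/min drift (slope 0.0048,
tightly correlated with time), while the undrifted low and mid bands stay
statistically flat — their slopes are well within three standard errors of
zero. `autoplot(res)` draws the per-band SEN traces with the moving average
and fitted line.

Cohort arithmetic on the packaged reference values:

```r
co <- build_cohort(cohort_reference())
co$summary
#> # A tibble: 3 × 5
#>   band  mean_slope mean_abs_r n_positive_slope n_negative_slope
#>   <fct>      <dbl>      <dbl>            <int>            <int>
#> 1 low     0.000177      0.203               19                1
#> 2 mid     0.000188      0.145               14                6
#> 3 high    0.00541       0.073               20                0
```

All 20 high-band slopes are positive and an order of magnitude steeper
than the other bands, at the cost of low correlation (high variability) —
the property that makes high-frequency entropy a seizure-prediction
candidate. `render_table(co, "table.tsv")` writes the per-patient table
with an Average row.

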
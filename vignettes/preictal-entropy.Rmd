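---
title: "Preictal spectral-entropy trends: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Preictal spectral-entropy trends: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(sentrend)
```

## The scientific question

Focal epileptic seizures are thought to arise from a progressive failure of
inhibitory control: an abnormal discharge recruits a growing mass of neurons
until the clinical seizure erupts. If the recruitment reorganizes the
spectral content of the EEG in the minutes before onset, a summary of
spectral *shape* should change systematically during the preictal period —
even when nothing is visible by eye.

`sentrend` quantifies that reorganization with the **normalized spectral
entropy** (SEN) of the focal-channel intracranial EEG,

$$\mathrm{SEN} \;=\; \frac{-\sum_k P_k \log P_k}{\log N},$$

where the $P_k$ are the power-spectrum values inside a frequency band,
normalized so $\sum_k P_k = 1$, and $N$ is the number of in-band frequency
bins. SEN is 1 when the in-band spectrum is flat (energy maximally
dispersed) and 0 when all energy sits in one bin (maximal concentration,
e.g. strong narrowband synchronization). The ratio form makes SEN
dimensionless, invariant to the amplitude scale of the recording and to the
logarithm base — properties asserted in the test suite.

The analysis asks *which frequency band's entropy changes most reliably
before a seizure*. For each band the windowed SEN series is reduced to a
fitted line: its slope $p$ (SEN per minute) is the rate of spectral
redistribution, and the Pearson correlation $r$ between time and SEN
measures how tightly the series follows the line.

## The pipeline

1. **Segment extraction** (`extract_preictal()`): the half-open interval
   $[\mathrm{onset} - 32\,\mathrm{min},\, \mathrm{onset})$ of one channel,
   timestamps re-expressed relative to onset. The half-open convention
   prevents double counting when segments are tiled.
2. **Line-noise removal** (`notch_50hz()`): a 41-tap linear-phase FIR notch
   at 50 Hz (see *Numerical choices*).
3. **Band decomposition** (`split_bands()`): order-40 Hamming-window FIR
   filters for low (0.1–12 Hz), mid (12–32 Hz) and high (32–128 Hz) bands.
   "Order 40" means 41 taps, standard filter nomenclature. At a 256 Hz
   sampling rate the high band's upper edge *is* the Nyquist frequency, so
   that filter is designed as a highpass at 32 Hz — a bandpass with an edge
   at Nyquist is ill-posed.
4. **Windowed entropy** (`entropy_series()`): non-overlapping 16 s windows
   (4096 samples at 256 Hz), squared-magnitude FFT aggregated to 1024
   uniform bins over (0, 128] Hz, SEN over the band's bins. Window
   timestamps are window centers in minutes relative to onset.
5. **Trend** (`fit_trend()`, `moving_average()`): OLS of SEN on time and
   Pearson $r$ over $[-32, -4)$ min; a centered 4-minute moving average
   (up to 15 windows) over the whole $[-32, 0)$ span for display.
6. **Cohort** (`build_cohort()`, `render_table()`): per-patient
   (slope, $|r|$) triplets, unweighted band means, and counts of strictly
   positive slopes.

The final 4 minutes are excluded from the fit because entropy can rise
steeply immediately before onset, which would leverage the straight-line
fit; they are retained in the moving-average display.

### Parameters that matter

| parameter | default | units | why |
|---|---|---|---|
| band edges | 0.1–12, 12–32, 32–128 | Hz | low/mid/high split of the clinical spectrum; gamma activity falls in the high band |
| filter order | 40 | taps − 1 | matches the reference analysis; ~80 ms group delay, negligible against 16 s windows |
| window length | 4096 (16 s) | samples | long enough for 0.0625 Hz raw resolution, short enough to track minute-scale drift |
| spectral bins | 1024 | bins | adjacent DFT pairs summed; see below |
| fit interval | [−32, −4) | min | preictal span with approximately linear SEN drift |
| moving average | 4 | min | visualization smoothing (~15 windows) |
| notch | 50 | Hz | European mains frequency |

A 4096-sample real FFT has 2048 positive-frequency values; the analysis
uses 1024 uniform bins, obtained by summing adjacent pairs. Aggregation
(rather than truncation at 64 Hz) is the only reading that keeps the full
high band available; the raw 2048-bin spectrum is available via `n_bins =
2048`.

**Entropy normalization.** $N$ in the SEN formula is the number of bins
*inside the analyzed band*, not the full 1024. Normalizing by the full
spectrum's bin count would prevent a band-limited signal from ever reaching
SEN = 1 and would make values incomparable across bands of different
widths. Both conventions are available (`f_lo_hz`/`f_hi_hz` arguments);
band-restricted is the default throughout the pipeline.

## Numerical choices

**Notch design.** A windowed-sinc (Hamming) bandstop of order 40 cannot
realize a usable 50 Hz notch: its transition lobe at 41 taps is roughly
±12 Hz wide, so a 47–53 Hz design stopband yields only ~6 dB at 50 Hz
while already losing >3 dB at 45/55 Hz. The notch is therefore designed by
constrained weighted least squares: among symmetric order-40 FIRs, minimize
the deviation from unit gain outside 45–55 Hz subject to the amplitude
response being exactly zero at 50 Hz (a Lagrange constraint placing a
spectral null). The result attenuates 50 Hz essentially completely while
staying within ±3 dB of unity everywhere below 45 and above 55 Hz. This
keeps the notch in the same linear-phase FIR family as the band filters.

**Causal single-pass filtering.** Filters are applied once, causally, with
zero initial conditions (zero-padding at the segment start). The 20-sample
group delay is constant across frequency (linear phase) and shifts all
bands equally by ~80 ms, which is irrelevant at the 16 s window scale; it
is not compensated. The first 40 samples (<0.2 s of a 28-minute segment)
ramp in from the padding and are retained.

**FFT taper.** No taper is applied before the FFT (rectangular window);
the Hamming window belongs to the filter design stage only. Spectral
leakage is immaterial here because SEN summarizes the whole in-band
distribution rather than individual peaks.

**Degenerate cases.** A window with zero in-band power has undefined
entropy and is reported as `NA` — never silently 0 or 1 — and excluded
from the regression and the moving average. A zero-variance entropy series
gets slope 0 and its undefined correlation is reported as 0 with a
`degenerate` flag. The natural logarithm is used internally; the
base-invariance of the ratio is asserted in tests.

## The synthetic generator

Recordings of the kind this pipeline targets (long invasive preictal
records) are not redistributable, so validation uses `generate_eeg()` +
`synth_spec()`, which emulate a single focal channel:

- **1/f background**: Gaussian noise with a $1/f^{\alpha}$ amplitude
  spectrum ($\alpha = 1$ default), built in the frequency domain;
  flattened below 0.05 Hz in lieu of AC coupling.
- **Line noise**: optional 50 Hz sinusoid of configurable amplitude.
- **Spikes**: optional Poisson-timed biphasic transients (~70 ms support,
  5 ms Gaussian-derivative core), whose broadband spectrum inflates
  window-to-window variability of high-band SEN.
- **Programmable SEN drift**: per band, a signed rate (SEN/min). SEN
  responds to spectral *shape*, not power, so drift is realized as a
  time-varying convex mixture between a broadband in-band process (flat
  spectrum, SEN → 1) and a narrowband one (an eighth of the band width,
  concentrated spectrum). The mixing weight is solved numerically at 4 s
  knots so the nominal two-block SEN follows a straight line through
  `sen_mid` (default 0.85) at the record midpoint; infeasible programs
  (target SEN outside the mixture's achievable range) are rejected.
- Seizure onset is placed at the record end, so the default 50-minute
  duration always affords a 32-minute preictal segment; everything is a
  pure function of the seed.

Default conditions mirror the target data: 50 minutes, 256 Hz, single
channel. The validation batteries run 20 independent seeds each: (i)
zero-drift records, where each band's fitted slope should be statistically
indistinguishable from 0 (within 3 standard errors); (ii) a programmed
high-band drift of +0.005 SEN/min — the scale of published high-band
slopes — which should be recovered with the right sign and, in median,
within 50% of the programmed magnitude (observed: within ~5%); and (iii)
paired spiked/clean runs at 10 spikes/min checking that spikes strictly
inflate high-band SEN variance. These sizes keep the whole battery within
a few minutes on one CPU while leaving the binomial pass criteria
(≥ 18–19 of 20) far from chance.

What the generator does *not* emulate: physiological neural-mass dynamics,
multichannel spatial structure, non-stationary artifacts other than
spikes, or the seizure waveform itself. Passing these batteries therefore
shows that the *pipeline* measures what it claims on signals with known
spectral drift — not that real preictal EEG drifts this way.

## Worked example

```{r example, eval = FALSE}
library(sentrend)

rec <- generate_eeg(synth_spec(drift = c(high = 0.005), seed = 42))
res <- run_record(rec, "ch1")
tidy(res)
autoplot(res)

# cohort arithmetic on the packaged published reference values
co <- build_cohort(cohort_reference())
glance(co)
```

## Known limitations

- The focal channel must be named by the user; there is no automatic
  focus detection.
- No artifact rejection or re-referencing; recordings are assumed clean
  apart from line noise.
- Slopes carry no significance tests at the cohort level (none are
  defined for this analysis); `slope_se` is provided per record.
- The fit assumes linear SEN drift over the 28-minute interval; changepoint
  or robust alternatives are out of scope.
- EDF ingestion is not built in; convert to delimited text or int16 and
  supply the metadata through `read_eeg_text()` / `read_eeg_int16()`.
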
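---
title: "Monitoring chick distress calling through spectral entropy: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Monitoring chick distress calling through spectral entropy}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(chickcall)
```

## The measurement problem

A broiler house holds ~25,000 chicks and two dominant sound sources: the
birds and the machinery (fans, heaters). Young chicks have a small
repertoire — a handful of quiet contact calls and one loud, repetitive
distress call (an ascending-then-descending frequency sweep of 100–250 ms
with energy concentrated at 2756–4307 Hz). When many birds are stressed
the house soundscape becomes a chorus of near-identical tonal sweeps, and
the spectrum of a one-minute recording concentrates around the call band.
Spectral entropy — the Shannon entropy of the normalized mean amplitude
spectrum, divided by log *N* so it lies in [0, 1] — measures exactly this
concentration: 1 for spectrally flat noise, 0 for a pure tone. The
pipeline therefore needs no call detector: one scalar per minute tracks
flock-level distress calling, provided low-frequency machinery noise is
first removed by a high-pass filter at 2750 Hz.

## Feature extraction

Each one-minute, 44.1 kHz mono segment is processed as:

1. **Band-pass filter.** Three regimes: unfiltered; high-pass (≥ 2750 Hz);
   call region (2750–5000 Hz). The filter is a frequency-domain brick
   wall: the DFT of the whole segment is taken, bins outside the band
   zeroed, and the result inverse-transformed. This is parameter-free,
   idempotent, and gives stop-band rejection limited only by round-off —
   well beyond the 60 dB the pipeline requires. A windowed FIR design
   would trade that exactness for edge behaviour we do not need on
   60-second segments.
2. **Mean spectrum.** Non-overlapping 512-sample Hanning frames, magnitude
   spectra averaged over frames, normalized to sum to one. This yields
   *N* = 256 bins at 86.133 Hz spacing. The trailing partial frame is
   discarded. Magnitude (not power) is averaged, matching the convention
   of the classical bioacoustic mean-spectrum tools.
3. **Descriptors.** Twelve per regime. The frequency distribution is
   summarised treating relative amplitude *y* as a probability mass over
   bin frequencies *x*: weighted mean and sd, sem = sd/√N, the dominant
   (argmax) bin, and the 25th/50th/75th percentile frequencies read off
   the discrete cumulative mass without interpolation (well-defined at
   256-bin resolution; ties for the dominant bin resolve to the lowest
   frequency). Shape is described by the centroid Σ*x·y*, skewness and
   kurtosis, and spectral entropy −Σ*y* log *y* / log *N* with
   0·log 0 ≔ 0 (the base cancels in the ratio).

Two deliberate conventions deserve note. First, the full frequency range
is retained after filtering: a high-pass-filtered minute keeps its
near-zero low bins in the normalization rather than being renormalized
over the sub-band. Baseline high-pass entropies near 0.8 (as intercepts of
the calibration model imply) are only consistent with full-range
normalization — renormalizing over the pass band would push quiet minutes
toward 1 and change every downstream coefficient. Second, the printed
moment formulas for skewness and kurtosis are ambiguous about amplitude
weighting; the default treats *y* as the weight (so the moments describe
the spectral mass distribution), and `moments = "unweighted"` evaluates
the literal unweighted formulas over the bin frequencies instead. Note
that under the weighted reading the "mean frequency" and the "centroid"
are the same number by construction; the package reports both columns as
the field's tables do, without pretending they differ.

## The synthetic soundscape

The generator exists so every stage can be tested against known truth. A
minute is assembled from:

* a **noise bed**: brick-wall low-passed white noise below 2750 Hz
  (machinery; ≥ 95 % of its energy in-band by construction) plus low-level
  broadband white noise (litter rustle, movement);
* **distress calls**: tonal FM sweeps whose instantaneous frequency
  follows a piecewise-quadratic chevron — rising to the peak over
  `rise_fraction` (default 0.25) of the duration, then descending — with
  one harmonic at −12 dB and a raised-cosine envelope. Defaults place
  ≥ 70 % of call energy inside 2756–4307 Hz. Calls arrive in repetitive
  bouts (runs of 3–8 with 50–250 ms gaps), may overlap freely, and are
  ~20 dB above the bed RMS (distress calls are loud; exact SPL mapping is
  out of scope). The per-minute count is Poisson with the scene's rate,
  and the exact event list is returned as ground truth;
* **contact calls**: short, soft tones (~15 dB quieter than distress
  calls) scattered through the minute.

Everything is driven by one scene seed split into per-component streams,
so any sub-generator is independently reproducible and a fixed seed gives
bit-identical output.

The **study-level** simulator adds the grouping structure of a field
campaign: a latent per-flock welfare factor raises the distress-call rate
(with weight growing over days 1–4 — persistent calling late in the window
is the most informative welfare signal), lowers next-day weight, and
raises mortality; call rates decline with age; per-minute counts are
gamma-mixed Poisson (negative binomial — right-skewed, as field counts
are); day 1 contributes 42 minutes over hours 1–8 of placement, later days
144 at the 1-min/10-min duty cycle. Farm outcomes depend on the acoustics
*only through the latent factor*, so setting `welfare_effect = 0` makes
them independent by construction — the null case used to check that
forecast slopes are unbiased.

Two modes trade realism against cost. `mode = "audio"` synthesises
waveforms and runs the real extractor — used for the end-to-end sweep
(tens of minutes of audio). `mode = "stats"` draws the 36 candidates
directly from the generator's documented response model: high-pass entropy
reads the latent per-minute calling intensity linearly
(entropy ≈ 0.918 − intensity/1927, small measurement noise), the realized
count is Poisson around the same intensity, and the other 35 candidates
are monotone functions of intensity with noise set to mirror the tiering
of correlation strengths across regimes (high-pass aggregate descriptors
strongest; call-region and unfiltered weaker; quartile/dominant/shape
candidates weaker still, some positive). Putting the randomness in the
count rather than the index keeps the count-on-entropy regression free of
attenuation bias, so the calibration slope is age-independent in
expectation — the property the calibration stage tests for. What passing
stats-mode tests show is that the *statistical machinery* behaves
correctly under the assumed response model; only audio-mode runs exercise
the acoustics, and neither mode reproduces real-farm phenomena such as
reverberation, microphone placement effects, strain differences, or
non-stationary machinery noise.

## Statistical pipeline

**Ranking.** All 36 candidates are correlated with the manual count by
tie-corrected Spearman correlation (counts are right-skewed, so rank
correlation is appropriate), and ranked by |ρ| with ties sharing a rank. A
regression forest (2000 trees, 12-variable subsets to blunt collinearity)
supplies permutation importance: the increase in out-of-bag MSE when a
candidate is permuted, normalized by the standard deviation of those
increases. Filter regimes are compared by a paired t-test over the twelve
per-descriptor |ρ| values; zero-variance differences are handled exactly
(identical vectors give t = 0, p = 1) rather than erroring.

**Calibration.** A linear mixed model of manual count on entropy with a
flock random intercept, day of placement (factor) and the entropy × day
interaction, fitted by maximum likelihood so that likelihood ratio tests
between nested models are valid. If the interaction LRT is
non-significant the model is refitted without it and one slope applies
across ages; inverting that line (floored at zero) converts any entropy
to a predicted calls/minute. Denominator degrees of freedom use the
containment heuristic of the classical mixed-model summary — documented
as approximate. A collapsed random-intercept variance raises a singular-
fit error instead of silently degenerating.

**Behaviour models.** Entropy is the response; flock is a random
intercept; estimation is ML. The day-1 model includes hours from
placement and omits surrounding-square activity (nearly invariant on day
1); the day-2/3 model includes day as a two-level factor. Chick-count
terms are protected — never eliminated — and the remaining terms are
removed backward, dropping the single highest-p term per step by LRT
until all remaining terms have p < 0.05. Categorical coding: distribution
against category 1 (spread out), activity against category 0 (inactive),
day against day 2. Out-of-range categories raise a degenerate-design
error rather than being silently coerced.

**Forecasts.** Entropy is right-skewed within a day, so each flock-day is
summarised by its median (exact sample median; day 1 restricted to hours
1–8). Next-day mortality: log(proportion) on median entropy, flock random
intercept — the log is taken only when all proportions are positive; a
zero raises an error naming the row, and `log_offset` lets the user opt
into log(p + ε) explicitly, because silently offsetting would corrupt any
attempted reproduction. Next-day weight: weight on median entropy × day.
Day-32 endpoints: ordinary least squares of the endpoint on the four
daily medians, simplified by backward partial-F elimination; a constant
response legitimately reduces to the intercept-only model.

## Problem sizes and numerical choices

The test suite and the acceptance script size their simulations as a desk
study: the audio sweep uses 30 synthesised minutes (6 call rates × 5
seeds); the synthetic study uses 12 flocks × 4 days with 144 stats-mode
minutes per day; replicate-based checks use 50–100 replicates. Spectral
oracle agreement is asserted at 1e−8 (STFT vs naive DFT) and 1e−10
(descriptors vs direct formula evaluation); filter idempotence at 1e−9.
Degenerate inputs — silent audio, constant predictors, single flocks,
all-zero spectra — raise typed errors rather than producing numbers.

## Known limitations

* The brick-wall filter is periodic in the segment; on segments with
  strong discontinuities at the edges it can ring. Irrelevant at 60 s
  lengths but worth knowing for very short segments.
* The calibration is linear by design; at extreme call rates the true
  acoustic response saturates (an entropy floor), which the audio-mode
  sweep shows but the linear model does not capture.
* Stepwise selection at α = 0.05 retains, on average, about one spurious
  term per ~20 eligible noise terms; exact recovery of a lone active
  covariate in every replicate is not a property any α-level procedure
  can have.
* The deposited field tables are required to reproduce the published
  coefficients; the synthetic study reproduces the *structure* of those
  analyses (signs, rankings, age trends), not their numerical values.
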
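# chickcall

Flock-level welfare monitoring of young broiler chickens from whole-house
audio.

Day-old chicks emit a loud, repetitive **distress call** — a brief
ascending then prolonged descending frequency sweep, 100–250 ms long, with
most of its energy between 2756 and 4307 Hz — in response to cold, hunger,
isolation and other stressors. Because thousands of chicks call at once, a
single microphone hears the *house*, not individual birds, and counting
calls directly is impractical. The idea implemented here is that one cheap
statistic of the overall soundscape tracks the calling rate: **spectral
entropy**, the Shannon entropy of the normalized mean amplitude spectrum,

&nbsp;&nbsp;&nbsp;&nbsp;*H* = −Σᵢ yᵢ log yᵢ / log N,

which is 1 for white noise and falls toward 0 as a tonal chorus of distress
calls concentrates spectral mass. After high-pass filtering at 2750 Hz to
remove fan and heater noise, per-minute spectral entropy is strongly,
linearly and age-independently related to the distress-call count, and the
per-flock daily *median* entropy forecasts next-day and end-of-cycle weight
and mortality — a candidate "iceberg indicator" for precision livestock
farming.

The package implements the full pipeline:

* **Audio I/O** — RIFF/WAV reading (PCM 8/16/24/32 and float32, multi-channel
  averaged to mono), PCM16 writing, segmentation into one-minute windows.
* **Spectral features** — brick-wall band-pass filtering (unfiltered /
  high-pass ≥ 2750 Hz / call region 2750–5000 Hz), mean frequency spectrum
  by STFT (512-sample non-overlapping Hanning frames), and twelve
  descriptors per regime (weighted mean/sd/sem of frequency, dominant
  frequency, quartiles and IQR, centroid, skewness, kurtosis, spectral
  entropy).
* **Soundscape synthesis** — seeded generator of poultry-house minutes:
  FM distress calls in bouts, quiet contact calls, low-frequency machinery
  noise, broadband litter noise, with exact ground-truth call counts; plus
  a study-level simulator with a latent welfare factor linking calling to
  weight and mortality.
* **Validation statistics** — Spearman and random-forest (2000 trees,
  12-variable subsets, permutation importance) ranking of the 36
  descriptor × regime candidates against manual counts; paired comparison
  of filter regimes; mixed-model calibration of entropy to count with an
  age-interaction likelihood ratio test.
* **Welfare models** — daily median entropy (day 1 restricted to hours
  1–8), next-day log-mortality and weight mixed models, day-32 endpoint
  regressions with backward selection, and count prediction from entropy.

## Worked example

```r
library(chickcall)

# a synthetic minute with 100 expected distress calls/min, and one with none
busy  <- synth_minute(scene_spec(call_rate = 100, seed = 3))
quiet <- synth_minute(scene_spec(call_rate = 0,   seed = 3))
busy$true_count
#> [1] 104

extract_features(busy$segment)[, c("band", "entropy", "dominant_f")]
#>         band   entropy dominant_f
#> 1 unfiltered 0.8677478    3359.18
#> 2   highpass 0.8641292    3359.18
#> 3 callregion 0.5232146    3359.18
extract_features(quiet$segment)[2, "entropy"]   # high-pass, no calls
#> [1] 0.9719294
```

With 104 overlapping calls the high-pass entropy drops from 0.972 to 0.864:
the chorus concentrates energy near 3.4 kHz (the dominant frequency sits in
the distress band). On a simulated 12-flock study the whole sequence runs
as:

```r
st  <- synth_study(flocks = 12, days = 4, welfare_effect = 1, seed = 1)
res <- run_analyse(st$features, st$counts, st$behaviour, st$farm)
res$rank_table[1, ]
#>   parameter     band spearman_rho rho_rank rf_importance importance_rank
#> 8   entropy highpass   -0.9800874        1      67.26305               1
writeLines(render_report(res)[3:4])
#> top candidate: entropy (highpass), rho = -0.980, importance = 67.26
#> highpass vs unfiltered |rho|: t = 2.43, p = 0.0335
```

High-pass spectral entropy is the strongest of the 36 candidates under both
ranking criteria, and high-pass filtering significantly improves the
correlation strength over the unfiltered regime (paired t over the twelve
|ρ| values). Inverting the fitted calibration line predicts the calling
rate from entropy alone, e.g.
`estimate_count_from_entropy(0.85, res$calibration$fit)` ≈ 130 calls/min.

The numbered scripts under `analysis/` run these stages as a narrative
workflow (simulate → extract → rank → calibrate → forecast), writing tables
under `results/`.

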
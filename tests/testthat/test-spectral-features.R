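test_that("brick-wall filter attenuates stop band and passes pass band", {
  lo <- sine_segment(1000)
  hi <- sine_segment(4000)
  hp <- filter_band("highpass")
  cr <- filter_band("callregion")

  expect_lt(rms(apply_bandpass(lo, hp)$samples), 0.001 * rms(lo$samples))
  expect_gt(rms(apply_bandpass(hi, cr)$samples), 0.99 * rms(hi$samples))
  # oracle: zero the DFT bins below the cutoff and invert
  n <- lo$n_samples
  f <- pmin(44100 * (0:(n - 1)) / n, 44100 - 44100 * (0:(n - 1)) / n)
  spec <- stats::fft(lo$samples)
  spec[f < 2750] <- 0
  oracle <- Re(stats::fft(spec, inverse = TRUE)) / n
  expect_lt(max(abs(apply_bandpass(lo, hp)$samples - oracle)), 1e-9)

  expect_identical(apply_bandpass(lo, filter_band("unfiltered"))$samples,
                   lo$samples)
})

test_that("filtering is idempotent", {
  withr::with_seed(21, seg <- audio_segment(stats::rnorm(44100), 44100))
  for (b in list(filter_band("highpass"), filter_band("callregion"))) {
    once <- apply_bandpass(seg, b)
    twice <- apply_bandpass(once, b)
    expect_lt(max(abs(twice$samples - once$samples)), 1e-9)
  }
})

test_that("invalid bands raise band errors", {
  seg <- sine_segment(1000, dur_s = 0.1)
  expect_error(filter_band("custom", low_hz = 5000, high_hz = 2750),
               class = "band_error")
  expect_error(apply_bandpass(seg, filter_band("custom", low_hz = 100,
                                               high_hz = 30000)),
               class = "band_error")
})

test_that("mean spectrum is normalized and localises a bin-centred sinusoid", {
  seg <- sine_segment(40 * 44100 / 512)   # exactly bin 40: 3445.3 Hz
  ms <- mean_spectrum(seg)
  expect_equal(sum(ms$amps), 1, tolerance = 1e-9)
  expect_equal(ms$n_bins, 256L)
  expect_equal(ms$freqs_hz[2] - ms$freqs_hz[1], 44100 / 512)
  sp <- spectral_properties(ms)
  expect_equal(sp$dominant_f, 40 * 44100 / 512, tolerance = 1e-9)
})

test_that("mean spectrum matches a naive per-frame DFT oracle", {
  withr::with_seed(22, {
    for (frames in c(1L, 3L, 10L)) {
      x <- stats::runif(frames * 512L + 100L, -1, 1)  # trailing partial frame
      ms <- mean_spectrum(audio_segment(x, 44100))
      or <- naive_mean_spectrum(x, 44100)
      expect_lt(max(abs(ms$amps - or$amps)), 1e-8)
      expect_equal(ms$freqs_hz, or$freqs_hz)
    }
  })
})

test_that("white noise gives a near-flat mean spectrum", {
  withr::with_seed(23, seg <- audio_segment(stats::rnorm(60 * 44100), 44100))
  ms <- mean_spectrum(seg)
  expect_lt(stats::sd(ms$amps) / mean(ms$amps), 0.1)
})

test_that("too-short and silent inputs raise typed errors", {
  expect_error(mean_spectrum(audio_segment(numeric(100) + 0.1, 44100)),
               class = "too_short_error")
  expect_error(mean_spectrum(audio_segment(numeric(1024), 44100)),
               class = "degenerate_spectrum_error")
})

test_that("entropy is 1 for a flat spectrum and 0 for a single bin", {
  flat <- make_spectrum(rep(1 / 256, 256))
  expect_equal(spectral_properties(flat)$entropy, 1, tolerance = 1e-12)

  freqs <- 44100 * (0:255) / 512
  one <- numeric(256)
  one[round(3000 / (44100 / 512)) + 1] <- 1
  sp <- spectral_properties(make_spectrum(one, freqs))
  expect_equal(sp$entropy, 0)
  expect_equal(sp$sd_f, 0)
  f0 <- freqs[round(3000 / (44100 / 512)) + 1]
  expect_equal(sp$q25_f, f0)
  expect_equal(sp$median_f, f0)
  expect_equal(sp$q75_f, f0)
  expect_equal(sp$dominant_f, f0)
  expect_equal(sp$iqr_f, 0)
})

test_that("toy 4-bin spectrum reproduces the direct-formula entropy", {
  toy <- make_spectrum(c(0.4, 0.3, 0.2, 0.1), freqs = c(1000, 2000, 3000, 4000))
  got <- spectral_properties(toy)
  want <- -(0.4 * log(0.4) + 0.3 * log(0.3) + 0.2 * log(0.2) +
              0.1 * log(0.1)) / log(4)
  expect_equal(got$entropy, want, tolerance = 1e-12)
  expect_equal(got$entropy, 0.9232, tolerance = 1e-4)
  expect_equal(got$centroid, 2000, tolerance = 1e-9)
  expect_equal(got$mean_f, got$centroid)
})

test_that("descriptors agree with brute-force formula evaluation", {
  withr::with_seed(24, {
    for (i in 1:25) {
      sp <- random_spectrum()
      got <- spectral_properties(sp)
      want <- naive_properties(sp$freqs_hz, sp$amps)
      for (nm in names(want))
        expect_equal(got[[nm]], want[[nm]], tolerance = 1e-10, label = nm)
    }
  })
})

test_that("quantile ordering and iqr identity hold on random spectra", {
  withr::with_seed(25, {
    for (i in 1:1000) {
      sp <- random_spectrum(n_bins = sample(16:256, 1))
      got <- spectral_properties(sp)
      expect_true(got$q25_f <= got$median_f)
      expect_true(got$median_f <= got$q75_f)
      expect_equal(got$iqr_f, got$q75_f - got$q25_f)
      expect_true(got$entropy >= 0 && got$entropy <= 1)
      expect_true(got$dominant_f %in% sp$freqs_hz)
    }
  })
})

test_that("entropy never increases when mass moves to an already-larger bin", {
  withr::with_seed(26, {
    for (i in 1:50) {
      sp <- random_spectrum(64L)
      y <- sp$amps
      hi <- which.max(y); lo <- which.min(y)
      eps <- y[lo] * stats::runif(1, 0.1, 0.9)
      y2 <- y; y2[hi] <- y2[hi] + eps; y2[lo] <- y2[lo] - eps
      e1 <- spectral_properties(make_spectrum(y, sp$freqs_hz))$entropy
      e2 <- spectral_properties(make_spectrum(y2, sp$freqs_hz))$entropy
      expect_lte(e2, e1 + 1e-12)
    }
  })
})

test_that("unweighted moment mode evaluates the literal formulas", {
  sp <- random_spectrum(64L)
  got <- spectral_properties(sp, moments = "unweighted")
  x <- sp$freqs_hz; N <- 64L
  expect_equal(got$skewness,
               sum((x - mean(x))^3) / (N - 1) / stats::sd(x)^3,
               tolerance = 1e-12)
  expect_equal(got$kurtosis,
               sum((x - mean(x))^4) / (N - 1) / stats::sd(x)^4,
               tolerance = 1e-12)
})

test_that("extract_features is deterministic and covers the band set", {
  withr::with_seed(27, seg <- audio_segment(stats::rnorm(3 * 44100), 44100))
  a <- extract_features(seg)
  b <- extract_features(seg)
  expect_identical(a, b)
  expect_setequal(a$band, c("unfiltered", "highpass", "callregion"))
  expect_setequal(setdiff(names(a), "band"), descriptor_names())
})

test_that("feature CSV writer enforces schema and 6 significant digits", {
  withr::with_seed(28, seg <- audio_segment(stats::rnorm(44100), 44100))
  fe <- extract_features(seg)
  fe$file_id <- "F01_1_0000"; fe$flock_id <- "F01"; fe$day <- 1L
  fe$minute_index <- 0L
  p <- withr::local_tempfile(fileext = ".csv")
  write_feature_csv(fe, p)
  back <- utils::read.csv(p)
  expect_equal(names(back),
               c("file_id", "flock_id", "day", "minute_index", "band",
                 descriptor_names()))
  expect_equal(back$entropy, signif(fe$entropy, 6))
  expect_error(write_feature_csv(fe[, -3], p), class = "format_error")
})
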
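# Band-pass filtering, mean frequency spectrum, and the twelve spectral
# descriptors computed under three filter regimes.

#' Define a filter band
#'
#' The pipeline's three regimes: `unfiltered` (identity), `highpass`
#' (keep >= 2750 Hz, removing low-frequency fan/heater noise), and
#' `callregion` (2750-5000 Hz, bracketing the 2756-4307 Hz range where most
#' distress-call energy sits in 1- to 5-day-old chicks).
#'
#' @param name One of `"unfiltered"`, `"highpass"`, `"callregion"`, or
#'   `"custom"`.
#' @param low_hz,high_hz Cutoffs in Hz for a custom band; fixed for the
#'   named regimes.
#' @return A `filter_band` object with fields `name`, `low_hz`, `high_hz`.
#' @export
filter_band <- function(name = c("unfiltered", "highpass", "callregion", "custom"),
                        low_hz = NULL, high_hz = NULL) {
  name <- match.arg(name)
  band <- switch(name,
    unfiltered = list(low_hz = NULL, high_hz = NULL),
    highpass   = list(low_hz = 2750, high_hz = NULL),
    callregion = list(low_hz = 2750, high_hz = 5000),
    custom     = list(low_hz = low_hz, high_hz = high_hz))
  if (!is.null(band$low_hz) && !is.null(band$high_hz) &&
      band$low_hz >= band$high_hz)
    abort_chick("low cutoff must be below high cutoff", "band_error")
  structure(c(list(name = name), band), class = "filter_band")
}

#' The default three-band set
#' @return Named list of [filter_band]s: unfiltered, highpass, callregion.
#' @export
default_bands <- function() {
  list(unfiltered = filter_band("unfiltered"),
       highpass   = filter_band("highpass"),
       callregion = filter_band("callregion"))
}

#' Apply a brick-wall band-pass filter
#'
#' Frequency-domain filter: the DFT of the whole segment is taken, bins
#' outside `[low_hz, high_hz]` are zeroed, and the result inverse
#' transformed. Parameter-free and idempotent; stop-band rejection is
#' complete up to numerical round-off (far beyond 60 dB).
#'
#' @param seg An [audio_segment].
#' @param band A [filter_band].
#' @return Filtered [audio_segment] of identical length.
#' @export
apply_bandpass <- function(seg, band) {
  stopifnot(inherits(seg, "audio_segment"), inherits(band, "filter_band"))
  if (is.null(band$low_hz) && is.null(band$high_hz)) return(seg)
  nyq <- seg$rate_hz / 2
  for (cut in c(band$low_hz, band$high_hz))
    if (cut <= 0 || cut >= nyq)
      abort_chick(sprintf("cutoff %g Hz outside (0, Nyquist = %g)", cut, nyq),
                  "band_error")
  n <- seg$n_samples
  f <- seg$rate_hz * (0:(n - 1L)) / n
  f <- pmin(f, seg$rate_hz - f)            # fold to physical frequency
  keep <- rep(TRUE, n)
  if (!is.null(band$low_hz))  keep <- keep & f >= band$low_hz
  if (!is.null(band$high_hz)) keep <- keep & f <= band$high_hz
  spec <- stats::fft(seg$samples)
  spec[!keep] <- 0 + 0i
  out <- Re(stats::fft(spec, inverse = TRUE)) / n
  seg$samples <- out
  seg
}

#' Mean frequency spectrum by short-time Fourier transform
#'
#' Magnitude spectra of consecutive non-overlapping Hanning-windowed frames
#' (default 512 samples) are averaged over frames and normalized to sum to
#' one. A trailing partial frame is discarded. The result keeps the full
#' frequency range including the DC bin, so a high-pass filtered segment
#' still yields near-zero mass in its low bins rather than a renormalized
#' sub-band spectrum.
#'
#' @param seg An [audio_segment].
#' @param window_length Frame length in samples (default 512, giving
#'   N = 256 bins spaced `rate_hz / 512` apart, 86.133 Hz at 44.1 kHz).
#' @return A `mean_spectrum` object: `freqs_hz`, `amps` (sums to 1),
#'   `n_bins`.
#' @export
mean_spectrum <- function(seg, window_length = 512L) {
  stopifnot(inherits(seg, "audio_segment"))
  wl <- as.integer(window_length)
  if (wl < 4L || wl %% 2L != 0L)
    abort_chick("window_length must be an even integer >= 4", "band_error")
  if (seg$n_samples < wl)
    abort_chick(sprintf("segment of %d samples shorter than one %d-sample window",
                        seg$n_samples, wl), "too_short_error")
  n_frames <- seg$n_samples %/% wl
  n_bins <- wl %/% 2L
  # periodic Hanning window
  w <- 0.5 - 0.5 * cos(2 * pi * (0:(wl - 1L)) / wl)
  frames <- matrix(seg$samples[seq_len(n_frames * wl)], nrow = wl)
  frames <- frames * w
  mags <- Mod(stats::mvfft(frames))[seq_len(n_bins), , drop = FALSE]
  amps <- rowMeans(mags)
  total <- sum(amps)
  if (total <= 0)
    abort_chick("all-zero spectrum (silent input)", "degenerate_spectrum_error")
  structure(list(freqs_hz = seg$rate_hz * (0:(n_bins - 1L)) / wl,
                 amps = amps / total,
                 n_bins = n_bins),
            class = "mean_spectrum")
}

#' Spectral descriptors of a mean spectrum
#'
#' The twelve per-recording descriptors. Nine summarise the frequency
#' distribution treating relative amplitude `y` as a probability mass over
#' bin frequencies `x`: amplitude-weighted mean, sd, and sem of frequency;
#' dominant frequency (bin of maximum amplitude, ties broken toward the
#' lowest frequency); 25th/50th/75th percentile frequencies (first bin at
#' which cumulative amplitude mass reaches the threshold, no interpolation)
#' and their interquartile range. Three describe spectral shape: centroid
#' `sum(x * y)`, and skewness/kurtosis as third/fourth standardized moments.
#' Spectral entropy is `-sum(y * log(y)) / log(N)` with `0 * log(0) = 0`:
#' 1 for a flat (white-noise) spectrum, 0 for a single pure tone.
#'
#' With `moments = "weighted"` (default) skewness and kurtosis use
#' amplitude-weighted central moments; `moments = "unweighted"` evaluates
#' the unweighted moment formulas `sum((x - mean(x))^k) / (N - 1) / sd^k`
#' over the bin frequencies literally.
#'
#' @param spec A [mean_spectrum].
#' @param moments `"weighted"` or `"unweighted"` skewness/kurtosis.
#' @return A one-row data.frame with columns mean_f, median_f, sd_f, sem_f,
#'   dominant_f, q25_f, q75_f, iqr_f, centroid, skewness, kurtosis, entropy.
#' @export
spectral_properties <- function(spec, moments = c("weighted", "unweighted")) {
  stopifnot(inherits(spec, "mean_spectrum"))
  moments <- match.arg(moments)
  x <- spec$freqs_hz
  y <- spec$amps
  N <- spec$n_bins
  if (all(y == 0))
    abort_chick("degenerate spectrum: all amplitudes zero",
                "degenerate_spectrum_error")

  mean_f <- sum(x * y)
  sd_f <- sqrt(sum(y * (x - mean_f)^2))
  sem_f <- sd_f / sqrt(N)
  dominant_f <- x[which.max(y)]            # which.max -> first (lowest) bin
  cum <- cumsum(y)
  q25_f <- x[which(cum >= 0.25)[1L]]
  median_f <- x[which(cum >= 0.5)[1L]]
  q75_f <- x[which(cum >= 0.75)[1L]]

  if (moments == "weighted") {
    skewness <- if (sd_f > 0) sum(y * (x - mean_f)^3) / sd_f^3 else 0
    kurtosis <- if (sd_f > 0) sum(y * (x - mean_f)^4) / sd_f^4 else 0
  } else {
    mx <- mean(x)
    sx <- stats::sd(x)
    skewness <- sum((x - mx)^3) / (N - 1) / sx^3
    kurtosis <- sum((x - mx)^4) / (N - 1) / sx^4
  }

  yl <- y[y > 0]
  entropy <- -sum(yl * log(yl)) / log(N)

  data.frame(mean_f = mean_f, median_f = median_f, sd_f = sd_f, sem_f = sem_f,
             dominant_f = dominant_f, q25_f = q25_f, q75_f = q75_f,
             iqr_f = q75_f - q25_f, centroid = mean_f, skewness = skewness,
             kurtosis = kurtosis, entropy = entropy)
}

#' Extract the descriptor set under each filter regime
#'
#' Filter, then mean spectrum, then descriptors, per band. Deterministic:
#' identical input gives bit-identical profiles.
#'
#' @param seg An [audio_segment].
#' @param bands Named list of [filter_band]s (default [default_bands()]).
#' @param window_length STFT frame length, default 512.
#' @param moments Passed to [spectral_properties()].
#' @return A data.frame with one row per band; first column `band`.
#' @export
extract_features <- function(seg, bands = default_bands(),
                             window_length = 512L,
                             moments = "weighted") {
  rows <- lapply(names(bands), function(nm) {
    filt <- apply_bandpass(seg, bands[[nm]])
    props <- spectral_properties(mean_spectrum(filt, window_length),
                                 moments = moments)
    cbind(data.frame(band = nm, stringsAsFactors = FALSE), props)
  })
  do.call(rbind, rows)
}

#' The twelve descriptor column names
#' @return Character vector in canonical order.
#' @export
descriptor_names <- function() {
  c("mean_f", "median_f", "sd_f", "sem_f", "dominant_f", "q25_f", "q75_f",
    "iqr_f", "centroid", "skewness", "kurtosis", "entropy")
}

#' Write a feature table to CSV
#'
#' One row per recording x band; floats at 6 significant digits. Columns:
#' file_id, flock_id, day, minute_index, band, then the twelve descriptors.
#'
#' @param features Data.frame in the feature schema.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_feature_csv <- function(features, path) {
  need <- c("file_id", "flock_id", "day", "minute_index", "band",
            descriptor_names())
  missing <- setdiff(need, names(features))
  if (length(missing))
    abort_chick(paste("feature table missing columns:",
                      paste(missing, collapse = ", ")), "format_error")
  out <- features[, need]
  for (nm in descriptor_names()) out[[nm]] <- signif(out[[nm]], 6)
  utils::write.csv(out, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
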
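# Seeded synthetic poultry-house soundscape: frequency-modulated distress
# calls, quiet contact calls, low-frequency machinery noise, broadband
# litter noise; ground-truth call counts recorded exactly.

DISTRESS_BAND <- c(2756, 4307)   # Hz; energy band of chick distress calls
CALL_DURATION <- c(0.10, 0.25)   # s; distress-call duration bounds

#' Specify one distress call
#'
#' A distress call is a loud tonal sweep with a brief ascending then
#' prolonged descending frequency modulation, 100-250 ms long, with energy
#' concentrated between 2756 and 4307 Hz.
#'
#' @param onset_s Onset within the minute, seconds.
#' @param duration_s Duration in seconds, within \[0.10, 0.25\].
#' @param peak_f_hz Fundamental frequency at the contour apex.
#' @param rise_fraction Fraction of the duration spent ascending, in (0, 0.5).
#' @param amplitude_rel Linear gain relative to the noise-bed RMS.
#' @return A `call_spec` object.
#' @export
call_spec <- function(onset_s = 0, duration_s = 0.18, peak_f_hz = 3530,
                      rise_fraction = 0.25, amplitude_rel = 10) {
  if (duration_s < CALL_DURATION[1] || duration_s > CALL_DURATION[2])
    abort_chick(sprintf("call duration %.3f s outside [%.2f, %.2f] s",
                        duration_s, CALL_DURATION[1], CALL_DURATION[2]),
                "call_spec_error")
  if (rise_fraction <= 0 || rise_fraction >= 0.5)
    abort_chick("rise_fraction must lie in (0, 0.5)", "call_spec_error")
  if (onset_s < 0 || onset_s + duration_s > 60)
    abort_chick("call must fit within the 60 s minute", "call_spec_error")
  structure(list(onset_s = onset_s, duration_s = duration_s,
                 peak_f_hz = peak_f_hz, rise_fraction = rise_fraction,
                 amplitude_rel = amplitude_rel),
            class = "call_spec")
}

#' Instantaneous-frequency contour of a distress call
#'
#' Piecewise quadratic: rises from 0.88 x peak to the peak over
#' `rise_fraction` of the duration, then descends to 0.80 x peak, giving
#' the brief-ascent / prolonged-descent chevron shape.
#'
#' @param spec A [call_spec].
#' @param t Times in seconds from call onset (0 to duration_s).
#' @return Instantaneous frequency in Hz at each `t`.
#' @export
call_frequency_contour <- function(spec, t) {
  Td <- spec$duration_s
  tr <- spec$rise_fraction * Td
  fp <- spec$peak_f_hz
  f0 <- 0.88 * fp
  f1 <- 0.80 * fp
  u <- numeric(length(t))
  rise <- t <= tr
  # inverted parabolas with apex (zero slope) at t = tr
  u[rise] <- f0 + (fp - f0) * (1 - ((tr - t[rise]) / tr)^2)
  u[!rise] <- fp - (fp - f1) * ((t[!rise] - tr) / (Td - tr))^2
  u
}

#' Synthesise one distress call waveform
#'
#' Tonal FM sweep following [call_frequency_contour()], with one harmonic
#' at -12 dB and a raised-cosine (Hanning) amplitude envelope. At default
#' settings >= 70% of the energy falls within 2756-4307 Hz.
#'
#' @param spec A [call_spec].
#' @param rate_hz Sampling rate.
#' @return Numeric amplitude vector of length `round(duration_s * rate_hz)`,
#'   unit peak envelope scaled by `amplitude_rel`.
#' @export
synth_distress_call <- function(spec, rate_hz = 44100) {
  stopifnot(inherits(spec, "call_spec"))
  n <- round(spec$duration_s * rate_hz)
  t <- (seq_len(n) - 1L) / rate_hz
  f <- call_frequency_contour(spec, t)
  phase <- 2 * pi * cumsum(f) / rate_hz
  env <- 0.5 - 0.5 * cos(2 * pi * (seq_len(n) - 0.5) / n)
  spec$amplitude_rel * env * (sin(phase) + 10^(-12 / 20) * sin(2 * phase))
}

#' Synthesise the stationary noise bed
#'
#' Machinery noise (fans, heaters) is brick-wall low-passed white noise
#' confined below 2750 Hz; litter/rustle noise is low-level broadband white
#' noise. Deterministic under `seed`.
#'
#' @param duration_s Length in seconds.
#' @param machinery_level RMS-scale gain of the machinery component.
#' @param broadband_level RMS-scale gain of the broadband component.
#' @param rate_hz Sampling rate.
#' @param seed Integer seed.
#' @return Numeric amplitude vector.
#' @export
synth_noise_bed <- function(duration_s, machinery_level = 1,
                            broadband_level = 0.1, rate_hz = 44100,
                            seed = 1L) {
  if (duration_s <= 0)
    abort_chick("duration must be positive", "call_spec_error")
  n <- round(duration_s * rate_hz)
  if (machinery_level == 0 && broadband_level == 0) return(numeric(n))
  withr::with_seed(seed, {
    out <- numeric(n)
    if (machinery_level > 0) {
      mach <- stats::rnorm(n)
      seg <- audio_segment(mach, rate_hz)
      # low-pass: keep only the machinery band below the 2750 Hz cutoff
      seg <- apply_bandpass(seg, filter_band("custom", low_hz = 1e-6,
                                             high_hz = 2500))
      mach <- seg$samples
      out <- out + machinery_level * mach / stats::sd(mach)
    }
    if (broadband_level > 0)
      out <- out + broadband_level * stats::rnorm(n)
    out
  })
}

#' Specify a synthetic scene
#'
#' @param call_rate Expected distress calls per minute (Poisson mean).
#' @param contact_rate Expected quiet contact calls per minute.
#' @param machinery_level,broadband_level Noise-bed gains (see
#'   [synth_noise_bed()]).
#' @param age_day Day of placement 1-4; scales call pitch down slightly as
#'   chicks grow.
#' @param seed Integer seed; fixes the whole minute.
#' @return A `scene_spec` object.
#' @export
scene_spec <- function(call_rate = 100, contact_rate = 200,
                       machinery_level = 0.02, broadband_level = 0.004,
                       age_day = 1L, seed = 1L) {
  if (call_rate < 0 || contact_rate < 0)
    abort_chick("rates must be >= 0", "call_spec_error")
  if (!(age_day %in% 1:4))
    abort_chick("age_day must be 1-4", "call_spec_error")
  structure(list(call_rate = call_rate, contact_rate = contact_rate,
                 machinery_level = machinery_level,
                 broadband_level = broadband_level,
                 age_day = as.integer(age_day), seed = as.integer(seed)),
            class = "scene_spec")
}

# split one scene seed into independent per-component streams
split_seed <- function(seed, k) {
  (as.numeric(seed) * 48271 + k * 100003) %% 2147483629 + 1
}

#' Synthesise one minute of poultry-house sound with known call count
#'
#' The distress-call count is drawn Poisson(`call_rate`); calls are placed
#' in repetitive bouts (a bouted onset process), may overlap freely (many
#' chicks call simultaneously), and pitch is scaled down by 3% per day of
#' age. Quiet contact calls and the noise bed are added underneath. The
#' waveform is peak-limited to \[-1, 1\] only if it exceeds full scale.
#'
#' @param scene A [scene_spec].
#' @param rate_hz Sampling rate.
#' @return A `synthetic_minute`: `segment` ([audio_segment]), `true_count`,
#'   and `events` (data.frame of call parameters, one row per call).
#' @export
synth_minute <- function(scene, rate_hz = 44100) {
  stopifnot(inherits(scene, "scene_spec"))
  n <- 60L * as.integer(rate_hz)
  bed <- synth_noise_bed(60, scene$machinery_level, scene$broadband_level,
                         rate_hz, seed = split_seed(scene$seed, 1L))
  bed_rms <- sqrt(mean(bed^2))
  if (bed_rms == 0) bed_rms <- 1e-4      # silent bed: nominal reference
  x <- bed

  pitch_scale <- 1 - 0.03 * (scene$age_day - 1L)
  events <- withr::with_seed(split_seed(scene$seed, 2L), {
    n_calls <- stats::rpois(1L, scene$call_rate)
    if (n_calls == 0L) {
      NULL
    } else {
      # bouted onsets: calls arrive in runs of ~3-8 with short within-bout
      # gaps, bouts scattered uniformly over the minute
      onsets <- numeric(0)
      while (length(onsets) < n_calls) {
        bout_start <- stats::runif(1L, 0, 59)
        bout_len <- 3L + stats::rpois(1L, 3L)
        gaps <- stats::runif(bout_len, 0.05, 0.25)
        durs <- stats::runif(bout_len, 0.12, 0.22)
        on <- bout_start + cumsum(c(0, (durs + gaps)[-bout_len]))
        onsets <- c(onsets, on)
      }
      onsets <- onsets[seq_len(n_calls)]
      durs <- stats::runif(n_calls, CALL_DURATION[1] + 0.02,
                           CALL_DURATION[2] - 0.02)
      keep <- onsets + durs <= 60
      onsets <- onsets[keep]; durs <- durs[keep]
      # top up any calls dropped at the minute boundary
      while (length(onsets) < n_calls) {
        on <- stats::runif(1L, 0, 59)
        du <- stats::runif(1L, 0.12, 0.22)
        if (on + du <= 60) { onsets <- c(onsets, on); durs <- c(durs, du) }
      }
      data.frame(
        onset_s = onsets,
        duration_s = durs,
        peak_f_hz = pitch_scale * stats::runif(n_calls, 3100, 4100),
        rise_fraction = stats::runif(n_calls, 0.18, 0.32),
        amplitude_rel = 10^(stats::rnorm(n_calls, 20, 2) / 20))
    }
  })

  if (!is.null(events)) {
    for (i in seq_len(nrow(events))) {
      cs <- call_spec(events$onset_s[i], events$duration_s[i],
                      events$peak_f_hz[i], events$rise_fraction[i],
                      events$amplitude_rel[i] * bed_rms)
      w <- synth_distress_call(cs, rate_hz)
      i0 <- round(events$onset_s[i] * rate_hz) + 1L
      idx <- i0:(i0 + length(w) - 1L)
      x[idx] <- x[idx] + w
    }
  }

  x <- x + withr::with_seed(split_seed(scene$seed, 3L),
                            synth_contact_calls(scene$contact_rate, bed_rms,
                                                n, rate_hz))
  peak <- max(abs(x))
  if (peak > 0.99) x <- x * (0.99 / peak)
  structure(list(segment = audio_segment(x, rate_hz),
                 true_count = if (is.null(events)) 0L else nrow(events),
                 events = events),
            class = "synthetic_minute")
}

# quiet contact calls: short soft tones, ~15 dB below distress calls,
# spread over 2-4 kHz; assumes an active RNG stream
synth_contact_calls <- function(contact_rate, bed_rms, n, rate_hz) {
  out <- numeric(n)
  n_cc <- stats::rpois(1L, contact_rate)
  if (n_cc == 0L) return(out)
  onsets <- stats::runif(n_cc, 0, 59.8)
  for (i in seq_len(n_cc)) {
    du <- stats::runif(1L, 0.05, 0.12)
    m <- round(du * rate_hz)
    t <- (seq_len(m) - 1L) / rate_hz
    f <- stats::runif(1L, 2200, 4000)
    env <- 0.5 - 0.5 * cos(2 * pi * (seq_len(m) - 0.5) / m)
    amp <- bed_rms * 10^(stats::rnorm(1L, 6, 2) / 20)
    w <- amp * env * sin(2 * pi * f * t)
    i0 <- round(onsets[i] * rate_hz) + 1L
    idx <- i0:(i0 + m - 1L)
    out[idx] <- out[idx] + w
  }
  out
}
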
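# Independent oracles and small fixture builders used across tests.

# brute-force mean spectrum: per-frame naive DFT (matrix of complex
# exponentials), magnitudes averaged over frames, normalized to sum 1
naive_mean_spectrum <- function(samples, rate_hz, wl = 512L) {
  n_frames <- length(samples) %/% wl
  w <- 0.5 - 0.5 * cos(2 * pi * (0:(wl - 1L)) / wl)
  k <- 0:(wl %/% 2L - 1L)
  E <- exp(-2i * pi * outer(k, 0:(wl - 1L)) / wl)
  acc <- numeric(length(k))
  for (f in seq_len(n_frames)) {
    fr <- samples[((f - 1L) * wl + 1L):(f * wl)] * w
    acc <- acc + Mod(E %*% fr)[, 1L]
  }
  amps <- acc / n_frames
  list(freqs_hz = rate_hz * k / wl, amps = amps / sum(amps))
}

# direct evaluation of the descriptor formulas on a normalized spectrum
naive_properties <- function(x, y) {
  y <- y / sum(y)
  N <- length(y)
  mu <- sum(x * y)
  sdv <- sqrt(sum(y * (x - mu)^2))
  cum <- cumsum(y)
  q <- function(p) x[which(cum >= p)[1]]
  yl <- y[y > 0]
  list(mean_f = mu, sd_f = sdv, sem_f = sdv / sqrt(N),
       dominant_f = x[which.max(y)], q25_f = q(0.25), median_f = q(0.5),
       q75_f = q(0.75), iqr_f = q(0.75) - q(0.25), centroid = sum(x * y),
       skewness = if (sdv > 0) sum(y * (x - mu)^3) / sdv^3 else 0,
       kurtosis = if (sdv > 0) sum(y * (x - mu)^4) / sdv^4 else 0,
       entropy = -sum(yl * log(yl)) / log(N))
}

# random normalized mean_spectrum object
random_spectrum <- function(n_bins = 256L, rate_hz = 44100) {
  y <- stats::rexp(n_bins)
  structure(list(freqs_hz = rate_hz * (0:(n_bins - 1L)) / (2L * n_bins),
                 amps = y / sum(y), n_bins = n_bins),
            class = "mean_spectrum")
}

make_spectrum <- function(amps, freqs = NULL, rate_hz = 44100) {
  n <- length(amps)
  if (is.null(freqs)) freqs <- rate_hz * (0:(n - 1L)) / (2L * n)
  structure(list(freqs_hz = freqs, amps = amps / sum(amps), n_bins = n),
            class = "mean_spectrum")
}

sine_segment <- function(freq, dur_s = 1, rate_hz = 44100, amp = 0.8) {
  audio_segment(amp * sin(2 * pi * freq * (0:(dur_s * rate_hz - 1)) / rate_hz),
                rate_hz)
}

rms <- function(x) sqrt(mean(x^2))

# Table of printed Spearman correlations from the field study's candidate
# ranking (used as fixed input data for the paired filter comparison)
published_rho_table <- function() {
  hp <- c(entropy = -0.88, iqr_f = -0.88, q75_f = -0.88, mean_f = -0.88,
          centroid = -0.88, sem_f = -0.71, median_f = -0.71, sd_f = -0.71,
          q25_f = -0.29, dominant_f = 0.57, kurtosis = 0.38, skewness = 0.41)
  un <- c(entropy = -0.42, iqr_f = -0.48, q75_f = 0.11, mean_f = 0.15,
          centroid = 0.15, sem_f = 0.52, median_f = -0.64, sd_f = -0.64,
          q25_f = 0.57, dominant_f = 0.54, kurtosis = -0.56, skewness = -0.49)
  cr <- c(entropy = -0.45, iqr_f = -0.51, q75_f = -0.19, mean_f = -0.01,
          centroid = -0.01, sem_f = 0.10, median_f = -0.62, sd_f = -0.62,
          q25_f = 0.44, dominant_f = 0.57, kurtosis = 0.35, skewness = 0.36)
  data.frame(parameter = rep(names(hp), 3L),
             band = rep(c("highpass", "unfiltered", "callregion"),
                        each = 12L),
             spearman_rho = c(hp, un, cr), row.names = NULL)
}

# direct flock-day generator for parameter-recovery tests: known linear
# links, flock random intercepts
make_flock_days_direct <- function(flocks = 12L, mort_slope = -3,
                                   re_sd = 0.4, resid_sd = 0.3,
                                   entropy_sd = 0.06) {
  fid <- sprintf("F%02d", seq_len(flocks))
  re <- stats::rnorm(flocks, 0, re_sd)
  d <- expand.grid(flock_id = fid, day = 1:4, stringsAsFactors = FALSE)
  d$median_entropy <- pmin(0.99, pmax(0.4, stats::rnorm(nrow(d), 0.82,
                                                        entropy_sd)))
  lp <- 1.24 + mort_slope * d$median_entropy + re[match(d$flock_id, fid)] +
    stats::rnorm(nrow(d), 0, resid_sd)
  d$next_day_mortality_prop <- exp(lp)
  d$next_day_weight <- 40 * (d$day + 1) + 30 * d$median_entropy +
    re[match(d$flock_id, fid)] + stats::rnorm(nrow(d), 0, 2)
  d$weight_d32 <- 1.9
  d$mortality_pct_d32 <- 3.5
  d
}
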
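# Behaviour-correlate models and the welfare forecasts: daily median
# entropy -> next-day weight/mortality, and the day-32 endpoint models.

#' Exact sample median of per-minute entropies
#'
#' Median (mean of the central pair for even n) of a day's entropy values.
#'
#' @param values Numeric vector of per-minute entropies.
#' @return The median.
#' @export
median_daily_entropy <- function(values) {
  values <- values[!is.na(values)]
  if (length(values) == 0L)
    abort_chick("no recordings in the day window", "empty_window_error")
  stats::median(values)
}

#' Per flock-day median entropy table
#'
#' Daily medians of the high-pass spectral entropy (the forecasting
#' predictor; entropy is right-skewed so the median summarises the day).
#' Day 1 is restricted to hours 1-8 after placement (the first 48 duty-
#' cycle slots); later days use the full day.
#'
#' @param features Long feature table.
#' @param band Filter regime of the predictor (default `"highpass"`).
#' @param day1_hours Hours of day 1 retained (default 8).
#' @return Data.frame: flock_id, day, median_entropy, n_minutes.
#' @export
daily_entropy_table <- function(features, band = "highpass",
                                day1_hours = 8) {
  fe <- features[features$band == band, ]
  if (nrow(fe) == 0L)
    abort_chick(sprintf("no features for band '%s'", band),
                "empty_window_error")
  # duty cycle: 6 one-minute recordings per hour
  keep <- fe$day != 1L | fe$minute_index < day1_hours * 6
  fe <- fe[keep, ]
  out <- stats::aggregate(fe$entropy,
                          by = list(flock_id = fe$flock_id, day = fe$day),
                          FUN = median_daily_entropy)
  names(out)[3L] <- "median_entropy"
  n <- stats::aggregate(fe$entropy,
                        by = list(flock_id = fe$flock_id, day = fe$day),
                        FUN = length)
  out$n_minutes <- n$x
  out[order(out$flock_id, out$day), ]
}

#' Join daily entropy medians to next-day and endpoint outcomes
#'
#' Builds the flock-day records used by the forecasting models: day-d
#' median entropy joined to day-(d+1) weight and mortality and to the
#' day-32 endpoints.
#'
#' @param daily Output of [daily_entropy_table()].
#' @param farm Farm table: flock_id, day (outcome day), weight,
#'   mortality_count, birds_placed, weight_d32, mortality_pct_d32.
#' @return Data.frame: flock_id, day, median_entropy, next_day_weight,
#'   next_day_mortality_prop, weight_d32, mortality_pct_d32.
#' @export
make_flock_days <- function(daily, farm) {
  nx <- farm
  nx$day <- nx$day - 1L            # align outcome day d+1 to predictor day d
  out <- merge(daily, nx, by = c("flock_id", "day"))
  out$next_day_weight <- out$weight
  out$next_day_mortality_prop <- out$mortality_count / out$birds_placed
  out[order(out$flock_id, out$day),
      c("flock_id", "day", "median_entropy", "next_day_weight",
        "next_day_mortality_prop", "weight_d32", "mortality_pct_d32")]
}

# ---- backward stepwise engines ------------------------------------------

# LRT-based backward elimination for ML mixed models: drop the single
# highest-p eligible term per step while any p >= alpha
backward_lme <- function(response, terms, protected, data, alpha = 0.05) {
  current <- terms
  repeat {
    eligible <- setdiff(current, protected)
    if (length(eligible) == 0L) break
    full <- fit_lme_or_die(stats::reformulate(current, response), data)
    ps <- vapply(eligible, function(tm) {
      red <- fit_lme_or_die(stats::reformulate(setdiff(current, tm), response),
                            data)
      chisq <- 2 * (as.numeric(stats::logLik(full)) -
                      as.numeric(stats::logLik(red)))
      df <- attr(stats::logLik(full), "df") - attr(stats::logLik(red), "df")
      stats::pchisq(max(chisq, 0), df, lower.tail = FALSE)
    }, 0)
    worst <- names(ps)[which.max(ps)]
    if (ps[worst] < alpha) break
    current <- setdiff(current, worst)
  }
  fit_lme_or_die(stats::reformulate(current, response), data)
}

# partial-F backward elimination for ordinary linear models
backward_lm <- function(response, terms, data, alpha = 0.05) {
  current <- terms
  repeat {
    if (length(current) == 0L) break
    fit <- stats::lm(stats::reformulate(current, response), data = data)
    dr <- suppressWarnings(stats::drop1(fit, test = "F"))
    ps <- dr[["Pr(>F)"]][-1L]
    names(ps) <- rownames(dr)[-1L]
    if (all(is.na(ps)) || max(ps, na.rm = TRUE) < alpha) break
    current <- setdiff(current, names(ps)[which.max(ps)])
  }
  stats::lm(stats::reformulate(if (length(current)) current else "1",
                               response), data = data)
}

# ---- behaviour models ----------------------------------------------------

validate_behaviour <- function(records) {
  need <- c("video_id", "flock_id", "day", "hours_from_placement",
            "mic_total", "surr_total", "mic_distribution",
            "surr_distribution", "mic_activity", "surr_activity",
            "large_scale_movement", "surr_foraging", "surr_drinking",
            "entropy")
  missing <- setdiff(need, names(records))
  if (length(missing))
    abort_chick(paste("behaviour records missing columns:",
                      paste(missing, collapse = ", ")), "format_error")
  if (!all(records$mic_distribution %in% 1:3) ||
      !all(records$surr_distribution %in% 1:3))
    abort_chick("distribution categories must be 1-3",
                "degenerate_design_error")
  if (!all(records$mic_activity %in% 0:2) ||
      !all(records$surr_activity %in% 0:2))
    abort_chick("activity categories must be 0-2", "degenerate_design_error")
  if (any(records$surr_foraging < 0) || any(records$surr_drinking < 0) ||
      any(records$mic_total < 0) || any(records$surr_total < 0))
    abort_chick("behaviour counts must be >= 0", "degenerate_design_error")
  invisible(records)
}

behaviour_frame <- function(records) {
  data.frame(
    entropy = records$entropy,
    flock_id = records$flock_id,
    hours_from_placement = records$hours_from_placement,
    mic_total = records$mic_total, surr_total = records$surr_total,
    mic_distribution = factor(records$mic_distribution, levels = 1:3),
    surr_distribution = factor(records$surr_distribution, levels = 1:3),
    mic_activity = factor(records$mic_activity, levels = 0:2),
    surr_activity = factor(records$surr_activity, levels = 0:2),
    large_scale_movement = records$large_scale_movement,
    surr_foraging = records$surr_foraging,
    surr_drinking = records$surr_drinking,
    day_f = factor(records$day))
}

#' Behaviour-correlate models of spectral entropy
#'
#' Two mixed models with entropy as the response and a flock random
#' intercept, fitted by maximum likelihood and simplified by backward
#' stepwise elimination (likelihood ratio tests, threshold `alpha`).
#' Chick-count terms (`mic_total`, `surr_total`) are always retained to
#' control for numbers near the microphone. The day-1 model additionally
#' includes hours from placement and omits surrounding-square activity
#' (nearly invariant on day 1); the day-2/3 model includes day as a
#' two-level factor. Distribution is coded against category 1, activity
#' against category 0, day against day 2.
#'
#' @param records Behaviour records (schema of [sim_behaviour_records()]).
#' @param alpha Stepwise retention threshold (default 0.05).
#' @return List: `day1` and `day23` `model_fit`s (day23 `NULL` when no
#'   day-2/3 records are present).
#' @export
fit_behaviour_models <- function(records, alpha = 0.05) {
  validate_behaviour(records)
  base_terms <- c("mic_distribution", "surr_distribution", "mic_activity",
                  "large_scale_movement", "surr_foraging", "surr_drinking")
  protected <- c("mic_total", "surr_total")

  d1 <- behaviour_frame(records[records$day == 1L, ])
  if (length(unique(d1$flock_id)) < 2L)
    abort_chick("day-1 subset must span >= 2 flocks",
                "insufficient_data_error")
  day1 <- backward_lme("entropy",
                       c(protected, "hours_from_placement", base_terms),
                       protected = protected, data = droplevels_safe(d1),
                       alpha = alpha)

  d23 <- behaviour_frame(records[records$day %in% 2:3, ])
  day23 <- NULL
  if (nrow(d23) > 0L) {
    if (length(unique(d23$flock_id)) < 2L)
      abort_chick("day-2/3 subset must span >= 2 flocks",
                  "insufficient_data_error")
    day23 <- backward_lme("entropy",
                          c(protected, "day_f", base_terms, "surr_activity"),
                          protected = protected,
                          data = droplevels_safe(d23), alpha = alpha)
  }
  list(day1 = lme_model_fit(day1, "flock_id"),
       day23 = if (!is.null(day23)) lme_model_fit(day23, "flock_id"))
}

# drop empty factor levels so treatment contrasts stay estimable, keeping
# the reference coding (1 for distribution, 0 for activity, 2 for day)
droplevels_safe <- function(d) {
  for (nm in names(d)) if (is.factor(d[[nm]])) d[[nm]] <- droplevels(d[[nm]])
  d
}

# ---- forecasting models --------------------------------------------------

#' Next-day weight and mortality forecast models
#'
#' Mixed models with a flock random intercept, fitted by maximum
#' likelihood. Mortality: `log(proportion) ~ median_entropy`
#' (age-independent). Weight: `weight ~ median_entropy * day` (factor).
#' Zero mortality proportions raise an error naming the offending rows
#' unless `log_offset` is set, in which case `log(p + log_offset)` is used.
#'
#' @param flock_days Output of [make_flock_days()].
#' @param log_offset Optional additive offset inside the mortality log
#'   (default 0 = disabled).
#' @return List: `mortality` and `weight` `model_fit`s.
#' @export
fit_next_day_models <- function(flock_days, log_offset = 0) {
  if (length(unique(flock_days$flock_id)) < 2L)
    abort_chick("need >= 2 flocks", "insufficient_data_error")
  zero <- flock_days$next_day_mortality_prop <= 0
  if (any(zero) && log_offset == 0) {
    rows <- paste(sprintf("%s day %d", flock_days$flock_id[zero],
                          flock_days$day[zero]), collapse = "; ")
    abort_chick(sprintf(
      "zero mortality proportion in: %s (set log_offset to opt into log(p + eps))",
      rows), "zero_mortality_error")
  }
  d <- flock_days
  d$log_mort <- log(d$next_day_mortality_prop + log_offset)
  d$day_f <- factor(d$day)
  mort <- fit_lme_or_die(log_mort ~ median_entropy, d)
  wt_f <- if (nlevels(d$day_f) > 1L) next_day_weight ~ median_entropy * day_f
          else next_day_weight ~ median_entropy
  wt <- fit_lme_or_die(wt_f, d)
  list(mortality = lme_model_fit(mort, "flock_id"),
       weight = lme_model_fit(wt, "flock_id"))
}

#' Day-32 endpoint models
#'
#' Ordinary linear models of the day-32 average bird weight and cumulative
#' % flock mortality on the four daily entropy medians, simplified by
#' backward elimination (partial F) until only significant terms remain; a
#' constant response reduces to the intercept-only model.
#'
#' @param flock_days Output of [make_flock_days()] (days 1-4 per flock).
#' @param alpha Stepwise retention threshold.
#' @return List: `weight` and `mortality` `model_fit`s, plus `data` (the
#'   per-flock wide table of daily medians and endpoints).
#' @export
fit_day32_models <- function(flock_days, alpha = 0.05) {
  wide <- stats::reshape(
    flock_days[, c("flock_id", "day", "median_entropy")],
    idvar = "flock_id", timevar = "day", direction = "wide",
    sep = "_d")
  ends <- unique(flock_days[, c("flock_id", "weight_d32",
                                "mortality_pct_d32")])
  wide <- merge(wide, ends, by = "flock_id")
  if (nrow(wide) < 6L)
    abort_chick("need >= 6 flocks with endpoint data",
                "insufficient_data_error")
  terms <- grep("^median_entropy_d", names(wide), value = TRUE)
  wt <- backward_lm("weight_d32", terms, wide, alpha)
  mort <- backward_lm("mortality_pct_d32", terms, wide, alpha)
  list(weight = lm_model_fit(wt), mortality = lm_model_fit(mort),
       data = wide)
}

#' Predict distress-call count per minute from spectral entropy
#'
#' Inverse use of the calibration: linear prediction from the fitted
#' intercept and entropy slope, floored at zero.
#'
#' @param entropy Entropy value(s).
#' @param calibration A `model_fit` from [fit_count_calibration()] (its
#'   `$fit` element) containing an entropy term.
#' @return Predicted count(s) per minute.
#' @export
estimate_count_from_entropy <- function(entropy, calibration) {
  if (inherits(calibration, "list") && !is.null(calibration$fit))
    calibration <- calibration$fit
  terms <- calibration$terms
  ent_row <- grep("^entropy", terms$term)
  int_row <- which(terms$term == "(Intercept)")
  if (length(ent_row) == 0L || length(int_row) == 0L)
    abort_chick("calibration lacks an entropy slope or intercept",
                "uncalibrated_error")
  pmax(0, terms$value[int_row] + terms$value[ent_row[1L]] * entropy)
}
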
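# Ranking the 36 descriptor x filter candidates against manual distress-call
# counts, and the entropy-to-count calibration mixed model.

#' Join features to manual counts as a wide candidate matrix
#'
#' Pivots the long feature table (one row per minute x band) to one row per
#' counted minute with 36 candidate columns named `<descriptor>.<band>`.
#'
#' @param features Long feature table (spectral schema).
#' @param counts Data.frame with columns `file_id`, `manual_count`.
#' @return Wide data.frame: file_id, flock_id, day, manual_count, and the
#'   36 candidates.
#' @export
make_validation_matrix <- function(features, counts) {
  bands <- unique(features$band)
  wide <- NULL
  for (b in bands) {
    blk <- features[features$band == b,
                    c("file_id", "flock_id", "day", descriptor_names())]
    names(blk)[-(1:3)] <- paste0(descriptor_names(), ".", b)
    wide <- if (is.null(wide)) blk else
      merge(wide, blk[, -(2:3)], by = "file_id")
  }
  out <- merge(wide, counts[, c("file_id", "manual_count")], by = "file_id")
  if (any(out$manual_count < 0))
    abort_chick("manual counts must be >= 0", "format_error")
  out
}

candidate_columns <- function(wide) {
  grep("\\.(unfiltered|highpass|callregion)$", names(wide), value = TRUE)
}

#' Spearman ranking of candidates against manual counts
#'
#' Tie-corrected (average-rank) Spearman correlation of each candidate with
#' the manual count; candidates ranked by `|rho|` descending, ties sharing
#' the same (minimum) rank.
#'
#' @param wide Output of [make_validation_matrix()].
#' @return Rank table: parameter, band, spearman_rho, rho_rank.
#' @export
spearman_table <- function(wide) {
  cols <- candidate_columns(wide)
  if (nrow(wide) < 3L)
    abort_chick("need >= 3 counted recordings", "insufficient_data_error")
  rho <- vapply(cols, function(cn)
    stats::cor(wide[[cn]], wide$manual_count, method = "spearman"), 0)
  parts <- do.call(rbind, strsplit(cols, ".", fixed = TRUE))
  out <- data.frame(parameter = parts[, 1L], band = parts[, 2L],
                    spearman_rho = unname(rho))
  out$rho_rank <- rank(-abs(out$spearman_rho), ties.method = "min")
  out[order(out$rho_rank), ]
}

#' Random forest permutation importance of candidates
#'
#' Regression forest predicting the manual count from all 36 candidates;
#' 2000 trees, 12-variable subsets per tree. Importance is the increase in
#' out-of-bag mean squared error when a candidate is permuted, normalized
#' by the standard deviation of those increases (reported as % increase in
#' MSE).
#'
#' @param wide Output of [make_validation_matrix()].
#' @param n_trees Number of trees (default 2000).
#' @param vars_per_tree Variables tried per split (default 12).
#' @param seed Integer seed for the forest.
#' @return Rank table: parameter, band, rf_importance, importance_rank.
#' @export
rf_importance <- function(wide, n_trees = 2000L, vars_per_tree = 12L,
                          seed = 1L) {
  cols <- candidate_columns(wide)
  if (nrow(wide) < 30L)
    abort_chick("need >= 30 counted recordings for the forest",
                "insufficient_data_error")
  x <- wide[, cols]
  names(x) <- make.names(names(x))        # randomForest mangles '.' safely
  imp <- withr::with_seed(seed, {
    rf <- randomForest::randomForest(
      x = x, y = wide$manual_count, ntree = n_trees,
      mtry = min(vars_per_tree, length(cols)), importance = TRUE)
    randomForest::importance(rf, type = 1L, scale = TRUE)[, 1L]
  })
  parts <- do.call(rbind, strsplit(cols, ".", fixed = TRUE))
  out <- data.frame(parameter = parts[, 1L], band = parts[, 2L],
                    rf_importance = unname(imp))
  out$importance_rank <- rank(-out$rf_importance, ties.method = "min")
  out[order(out$importance_rank), ]
}

#' Full candidate rank table (Spearman + forest)
#'
#' @inheritParams rf_importance
#' @return 36-row table: parameter, band, spearman_rho, rho_rank,
#'   rf_importance, importance_rank.
#' @export
rank_candidates <- function(wide, n_trees = 2000L, vars_per_tree = 12L,
                            seed = 1L) {
  sp <- spearman_table(wide)
  rf <- rf_importance(wide, n_trees, vars_per_tree, seed)
  out <- merge(sp, rf, by = c("parameter", "band"))
  out[order(out$rho_rank), ]
}

#' Paired comparison of correlation strength between two filter regimes
#'
#' Paired t-test over the per-descriptor `|rho|` values of two bands
#' (testing whether filtering improves correlation strength). Zero-variance
#' differences are handled exactly: identical vectors give t = 0, p = 1; a
#' constant nonzero shift gives p = 0.
#'
#' @param rank_table Output of [spearman_table()] or [rank_candidates()].
#' @param band_a,band_b Band names; positive t means `band_a` correlates
#'   more strongly.
#' @return List: t, df, p, mean_diff.
#' @export
compare_filter_rhos <- function(rank_table, band_a, band_b) {
  a <- rank_table[rank_table$band == band_a, c("parameter", "spearman_rho")]
  b <- rank_table[rank_table$band == band_b, c("parameter", "spearman_rho")]
  m <- merge(a, b, by = "parameter", suffixes = c("_a", "_b"))
  n <- nrow(m)
  if (n < 2L)
    abort_chick("need >= 2 shared descriptors per band",
                "insufficient_data_error")
  d <- abs(m$spearman_rho_a) - abs(m$spearman_rho_b)
  md <- mean(d)
  sdd <- stats::sd(d)
  if (sdd == 0) {
    t <- if (md == 0) 0 else sign(md) * Inf
    p <- if (md == 0) 1 else 0
  } else {
    t <- md / (sdd / sqrt(n))
    p <- 2 * stats::pt(-abs(t), df = n - 1L)
  }
  list(t = t, df = n - 1L, p = p, mean_diff = md)
}

# tidy fixed-effect table from an nlme fit
lme_model_fit <- function(fit, grouping) {
  tt <- summary(fit)$tTable
  structure(list(
    terms = data.frame(term = rownames(tt), value = tt[, "Value"],
                       se = tt[, "Std.Error"], df = tt[, "DF"],
                       t_value = tt[, "t-value"], p_value = tt[, "p-value"],
                       row.names = NULL),
    loglik = as.numeric(stats::logLik(fit)),
    n_obs = fit$dims$N, grouping = grouping,
    formula = deparse(stats::formula(fit))),
    class = "model_fit")
}

lm_model_fit <- function(fit) {
  co <- suppressWarnings(summary(fit))$coefficients  # constant-response fits
  structure(list(
    terms = data.frame(term = rownames(co), value = co[, 1L], se = co[, 2L],
                       df = fit$df.residual, t_value = co[, 3L],
                       p_value = co[, 4L], row.names = NULL),
    loglik = as.numeric(stats::logLik(fit)),
    n_obs = length(fit$residuals), grouping = NA_character_,
    formula = deparse(stats::formula(fit))),
    class = "model_fit")
}

#' @export
print.model_fit <- function(x, ...) {
  cat(sprintf("model: %s  (n = %d%s)\n", x$formula, x$n_obs,
              if (!is.na(x$grouping))
                sprintf(", random intercept: %s", x$grouping) else ""))
  tab <- x$terms
  tab$value <- signif(tab$value, 5)
  tab$se <- signif(tab$se, 4)
  tab$t_value <- round(tab$t_value, 2)
  tab$p_value <- signif(tab$p_value, 3)
  print(tab, row.names = FALSE)
  invisible(x)
}

# raise on collapsed random-intercept variance instead of reporting a
# silently degenerate mixed model
check_singular <- function(fit) {
  vc <- nlme::VarCorr(fit)
  re_sd <- suppressWarnings(as.numeric(vc["(Intercept)", "StdDev"]))
  resid_sd <- fit$sigma
  if (is.finite(re_sd) && re_sd < 1e-5 * resid_sd)
    abort_chick("random-intercept variance collapsed to the boundary",
                "singular_fit_error")
  invisible(fit)
}

fit_lme_or_die <- function(formula, data, group_formula = ~ 1 | flock_id) {
  fit <- tryCatch(
    nlme::lme(fixed = formula, random = group_formula, data = data,
              method = "ML",
              control = nlme::lmeControl(opt = "optim", maxIter = 200,
                                         msMaxIter = 200)),
    error = function(e)
      abort_chick(sprintf("mixed model failed (%s): degenerate design?",
                          conditionMessage(e)), "degenerate_design_error"))
  check_singular(fit)
  fit
}

#' Calibrate manual call count against spectral entropy
#'
#' Linear mixed model with the manual count as response, a random intercept
#' per flock, and fixed effects entropy, day of placement (factor, 1-4) and
#' their interaction, fitted by maximum likelihood. A likelihood ratio test
#' compares the model with and without the interaction; when the
#' interaction is non-significant (slope age-independent) the model is
#' refitted without it and the main-effect slope reported.
#'
#' @param wide Output of [make_validation_matrix()], or any data.frame with
#'   columns manual_count, flock_id, day and the entropy candidate.
#' @param entropy_col Candidate used as the acoustic predictor (default
#'   high-pass spectral entropy).
#' @param alpha Significance threshold for retaining the interaction.
#' @return List: `fit` (a `model_fit`), `interaction_lrt` (chisq, df, p),
#'   `interaction_retained`.
#' @export
fit_count_calibration <- function(wide, entropy_col = "entropy.highpass",
                                  alpha = 0.05) {
  if (length(unique(wide$flock_id)) < 2L)
    abort_chick("need >= 2 flocks", "insufficient_data_error")
  if (stats::sd(wide[[entropy_col]]) == 0)
    abort_chick("acoustic predictor is constant", "degenerate_design_error")
  d <- data.frame(manual_count = wide$manual_count,
                  entropy = wide[[entropy_col]],
                  day_f = factor(wide$day),
                  flock_id = wide$flock_id)
  has_days <- nlevels(d$day_f) > 1L
  full_f <- if (has_days) manual_count ~ entropy * day_f
            else manual_count ~ entropy
  main_f <- if (has_days) manual_count ~ entropy + day_f
            else manual_count ~ entropy
  full <- fit_lme_or_die(full_f, d)
  lrt <- list(chisq = NA_real_, df = 0L, p = NA_real_)
  final <- full
  if (has_days) {
    main <- fit_lme_or_die(main_f, d)
    chisq <- 2 * (as.numeric(stats::logLik(full)) -
                    as.numeric(stats::logLik(main)))
    df <- attr(stats::logLik(full), "df") - attr(stats::logLik(main), "df")
    lrt <- list(chisq = chisq, df = df,
                p = stats::pchisq(chisq, df, lower.tail = FALSE))
    if (lrt$p >= alpha) final <- main
  }
  list(fit = lme_model_fit(final, "flock_id"), interaction_lrt = lrt,
       interaction_retained = has_days && lrt$p < alpha)
}
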
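# Orchestration: configuration, batch extraction, simulation, the full
# statistical sequence, and plain-text reporting. The numbered scripts
# under analysis/ are thin drivers over these functions.

#' Pipeline configuration
#'
#' Defaults reproduce the analysis settings: 512-sample STFT window, the
#' three filter regimes, amplitude-weighted moments, a 2000-tree forest
#' with 12-variable subsets, stepwise threshold 0.05, no mortality log
#' offset.
#'
#' @param window_length STFT frame length.
#' @param bands Named list of [filter_band]s.
#' @param moments `"weighted"` or `"unweighted"` spectral moments.
#' @param rf_trees,rf_vars Forest size and variables per tree.
#' @param stepwise_alpha Backward-elimination threshold.
#' @param log_offset Offset for log-mortality (0 = disabled).
#' @param seed Global seed.
#' @return A `pipeline_config` list.
#' @export
pipeline_config <- function(window_length = 512L, bands = default_bands(),
                            moments = "weighted", rf_trees = 2000L,
                            rf_vars = 12L, stepwise_alpha = 0.05,
                            log_offset = 0, seed = 1L) {
  structure(list(window_length = window_length, bands = bands,
                 moments = moments, rf_trees = rf_trees, rf_vars = rf_vars,
                 stepwise_alpha = stepwise_alpha, log_offset = log_offset,
                 seed = as.integer(seed)),
            class = "pipeline_config")
}

#' Batch feature extraction over WAV files
#'
#' Extracts the descriptor set for each file under each band. Metadata is
#' parsed from the `<flock>_<day>_<minute>.wav` naming convention or taken
#' from a sidecar table. Per-file failures are warned about and skipped;
#' `status` is 2 when any file failed (partial failure), 0 otherwise.
#'
#' @param paths WAV file paths, or a directory containing them.
#' @param config A [pipeline_config()].
#' @param meta Optional sidecar data.frame (file_id, flock_id, day,
#'   minute_index) overriding filename parsing.
#' @param out_csv Optional path; when given the feature CSV is written.
#' @return List: `features`, `n_ok`, `n_failed`, `status`.
#' @export
run_extract <- function(paths, config = pipeline_config(), meta = NULL,
                        out_csv = NULL) {
  if (length(paths) == 1L && dir.exists(paths))
    paths <- list.files(paths, pattern = "\\.wav$", ignore.case = TRUE,
                        full.names = TRUE)
  if (length(paths) == 0L)
    abort_chick("no WAV files to extract", "empty_audio_error")
  rows <- list()
  n_failed <- 0L
  for (p in sort(paths)) {
    res <- tryCatch({
      m <- if (!is.null(meta)) {
        id <- sub("\\.wav$", "", basename(p), ignore.case = TRUE)
        hit <- meta[meta$file_id == id, ]
        if (nrow(hit) == 0L)
          abort_chick(sprintf("no sidecar metadata for %s", id),
                      "format_error")
        hit[1L, c("file_id", "flock_id", "day", "minute_index")]
      } else parse_recording_meta(p)
      seg <- read_wav(p)
      fe <- extract_features(seg, config$bands, config$window_length,
                             config$moments)
      cbind(m, fe, row.names = NULL)
    }, error = function(e) e)
    if (inherits(res, "error")) {
      n_failed <- n_failed + 1L
      warn_chick(sprintf("skipping %s: %s", basename(p),
                         conditionMessage(res)), "extract_skip_warning")
    } else rows[[length(rows) + 1L]] <- res
  }
  if (length(rows) == 0L)
    abort_chick("all input files failed extraction", "empty_audio_error")
  features <- do.call(rbind, rows)
  if (!is.null(out_csv)) write_feature_csv(features, out_csv)
  list(features = features, n_ok = length(rows), n_failed = n_failed,
       status = if (n_failed > 0L) 2L else 0L)
}

#' Simulate a study corpus and write its tables
#'
#' Drives [synth_study()] and writes the four CSVs (features, counts,
#' behaviour, farm) plus the per-minute truth table to `out_dir`. Byte-
#' identical output under a fixed seed.
#'
#' @param out_dir Output directory (created if needed).
#' @param ... Passed to [synth_study()].
#' @param config A [pipeline_config()]; supplies the seed when `seed` is
#'   not given in `...`.
#' @return The [synth_study()] list, invisibly, with `paths` attached.
#' @export
run_simulate <- function(out_dir, ..., config = pipeline_config()) {
  dots <- list(...)
  if (is.null(dots$seed)) dots$seed <- config$seed
  study <- do.call(synth_study, dots)
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  paths <- list(
    features = file.path(out_dir, "features.csv"),
    counts = file.path(out_dir, "counts.csv"),
    behaviour = file.path(out_dir, "behaviour.csv"),
    farm = file.path(out_dir, "farm.csv"),
    truth = file.path(out_dir, "truth.csv"))
  for (nm in names(paths))
    utils::write.csv(study[[nm]], paths[[nm]], row.names = FALSE,
                     quote = FALSE)
  study$paths <- paths
  invisible(study)
}

#' Run the full statistical sequence
#'
#' Candidate ranking (Spearman + forest), filter-regime comparison, the
#' count calibration model, behaviour models, next-day forecasts and
#' day-32 endpoint models. Stages whose inputs are absent are skipped with
#' a notice recorded in `$notes`.
#'
#' @param features Long feature table.
#' @param counts Manual counts (file_id, manual_count), or `NULL`.
#' @param behaviour Behaviour records, or `NULL`.
#' @param farm Farm productivity table, or `NULL`.
#' @param config A [pipeline_config()].
#' @return List of stage results: `rank_table`, `filter_comparison`,
#'   `calibration`, `behaviour_fits`, `daily`, `flock_days`,
#'   `next_day_fits`, `day32_fits`, `notes`, `config`.
#' @export
run_analyse <- function(features, counts = NULL, behaviour = NULL,
                        farm = NULL, config = pipeline_config()) {
  res <- list(config = config, notes = character())
  note <- function(msg) res$notes <<- c(res$notes, msg)

  if (!is.null(counts)) {
    wide <- make_validation_matrix(features, counts)
    res$rank_table <- rank_candidates(wide, config$rf_trees, config$rf_vars,
                                      seed = config$seed)
    res$filter_comparison <- list(
      highpass_vs_unfiltered =
        compare_filter_rhos(res$rank_table, "highpass", "unfiltered"),
      callregion_vs_unfiltered =
        compare_filter_rhos(res$rank_table, "callregion", "unfiltered"))
    res$calibration <- fit_count_calibration(wide,
                                             alpha = config$stepwise_alpha)
  } else note("counts absent: ranking and calibration stages skipped")

  if (!is.null(behaviour)) {
    res$behaviour_fits <- fit_behaviour_models(behaviour,
                                               alpha = config$stepwise_alpha)
  } else note("behaviour absent: behaviour stage skipped")

  if (!is.null(farm)) {
    res$daily <- daily_entropy_table(features)
    res$flock_days <- make_flock_days(res$daily, farm)
    res$next_day_fits <- fit_next_day_models(res$flock_days,
                                             log_offset = config$log_offset)
    res$day32_fits <- fit_day32_models(res$flock_days,
                                       alpha = config$stepwise_alpha)
  } else note("farm absent: forecasting stages skipped")

  res
}

#' Render a plain-text analysis report
#'
#' @param res Output of [run_analyse()].
#' @return Character vector of report lines.
#' @export
render_report <- function(res) {
  lines <- c("== acoustic welfare analysis ==", "")
  fmt_fit <- function(label, mf) {
    c(sprintf("-- %s (n = %d) --", label, mf$n_obs),
      sprintf("  %-28s % 10.4g  se % .4g  t % .2f  p %.3g",
              mf$terms$term, mf$terms$value, mf$terms$se, mf$terms$t_value,
              mf$terms$p_value))
  }
  if (!is.null(res$rank_table)) {
    top <- res$rank_table[1L, ]
    lines <- c(lines,
      sprintf("top candidate: %s (%s), rho = %.3f, importance = %.2f",
              top$parameter, top$band, top$spearman_rho, top$rf_importance),
      sprintf("highpass vs unfiltered |rho|: t = %.2f, p = %.3g",
              res$filter_comparison$highpass_vs_unfiltered$t,
              res$filter_comparison$highpass_vs_unfiltered$p), "")
  }
  if (!is.null(res$calibration))
    lines <- c(lines, fmt_fit("count calibration", res$calibration$fit),
               sprintf("  interaction LRT: chisq = %.2f, df = %d, p = %.3g",
                       res$calibration$interaction_lrt$chisq,
                       res$calibration$interaction_lrt$df,
                       res$calibration$interaction_lrt$p), "")
  if (!is.null(res$behaviour_fits)) {
    lines <- c(lines, fmt_fit("day-1 behaviour", res$behaviour_fits$day1))
    if (!is.null(res$behaviour_fits$day23))
      lines <- c(lines, fmt_fit("day-2/3 behaviour",
                                res$behaviour_fits$day23))
    lines <- c(lines, "")
  }
  if (!is.null(res$next_day_fits))
    lines <- c(lines,
               fmt_fit("next-day log-mortality", res$next_day_fits$mortality),
               fmt_fit("next-day weight", res$next_day_fits$weight), "")
  if (!is.null(res$day32_fits))
    lines <- c(lines, fmt_fit("day-32 weight", res$day32_fits$weight),
               fmt_fit("day-32 mortality", res$day32_fits$mortality), "")
  c(lines, res$notes)
}

#' Export stage results as JSON with stable key order
#'
#' @param res Output of [run_analyse()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
export_results_json <- function(res, path) {
  strip <- function(x) {
    if (inherits(x, "model_fit")) unclass(x)
    else if (inherits(x, "pipeline_config"))
      unclass(x[setdiff(names(x), "bands")])
    else if (is.list(x)) lapply(x, strip)
    else x
  }
  keep <- intersect(c("config", "rank_table", "filter_comparison",
                      "calibration", "behaviour_fits", "next_day_fits",
                      "day32_fits", "notes"), names(res))
  jsonlite::write_json(strip(res[keep]), path, auto_unbox = TRUE,
                       digits = NA, dataframe = "columns", null = "null")
  invisible(path)
}

#' Reproduce the deposited-data analyses
#'
#' Runs the full Table-1/2/3 sequence against the study's deposited
#' supplementary tables, if the user has downloaded them: Dataset 1
#' (acoustic parameters + manual counts), Dataset 2 (behavioural data),
#' Dataset 3 (weight and mortality), as CSVs in `dir`.
#'
#' @param dir Directory holding `dataset1_acoustic.csv`,
#'   `dataset2_behaviour.csv`, `dataset3_farm.csv`.
#' @param config A [pipeline_config()].
#' @return [run_analyse()] results on the deposited tables.
#' @export
reproduce_deposited <- function(dir, config = pipeline_config()) {
  f <- function(x) file.path(dir, x)
  need <- c("dataset1_acoustic.csv", "dataset2_behaviour.csv",
            "dataset3_farm.csv")
  missing <- need[!file.exists(f(need))]
  if (length(missing))
    abort_chick(paste("deposited datasets not found:",
                      paste(missing, collapse = ", ")), "format_error")
  ds1 <- utils::read.csv(f("dataset1_acoustic.csv"))
  counts <- unique(ds1[, c("file_id", "manual_count")])
  features <- ds1[, setdiff(names(ds1), "manual_count")]
  run_analyse(features, counts,
              behaviour = utils::read.csv(f("dataset2_behaviour.csv")),
              farm = utils::read.csv(f("dataset3_farm.csv")),
              config = config)
}
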
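#' Pipeline configuration
#'
#' Bundles every tunable analysis parameter with defaults fixed to the
#' reference analysis: bands 0.1-12 / 12-32 / 32-128 Hz, order-40
#' Hamming-window FIR filters, 50 Hz notch, 4096-sample (16 s)
#' non-overlapping windows with 1024 spectral bins, trend fit over
#' `[-32, -4)` minutes, 4-minute moving average, and segment extraction
#' over the final 32 preictal minutes (the moving average is displayed up
#' to onset even though the fit stops at -4 min).
#'
#' @param bands Band table (default [default_bands()] at 256 Hz; re-derived
#'   from the record's rate at run time if it differs).
#' @param filter_order FIR order for notch and band filters (default 40).
#' @param window_samples Samples per analysis window (default 4096).
#' @param n_bins Spectral bins per window (default 1024).
#' @param segment_min `c(start, end)` minutes before onset to extract
#'   (default `c(32, 0)`).
#' @param fit_interval_min Trend-fit interval in minutes relative to onset
#'   (default `c(-32, -4)`).
#' @param moving_avg_min Moving-average window in minutes (default 4).
#' @param notch_hz Line frequency to notch (default 50; `NA` skips).
#' @param seed Optional seed recorded for stochastic options.
#' @return A list of class `pipeline_config`.
#' @export
pipeline_config <- function(bands = default_bands(), filter_order = 40,
                            window_samples = 4096, n_bins = 1024,
                            segment_min = c(32, 0),
                            fit_interval_min = c(-32, -4),
                            moving_avg_min = 4, notch_hz = 50,
                            seed = NULL) {
  check_order(filter_order)
  stopifnot(length(segment_min) == 2L, segment_min[[1L]] > segment_min[[2L]],
            segment_min[[2L]] >= 0, length(fit_interval_min) == 2L,
            fit_interval_min[[1L]] < fit_interval_min[[2L]],
            moving_avg_min > 0, window_samples >= 2)
  structure(
    list(bands = bands, filter_order = filter_order,
         window_samples = window_samples, n_bins = n_bins,
         segment_min = segment_min, fit_interval_min = fit_interval_min,
         moving_avg_min = moving_avg_min, notch_hz = notch_hz, seed = seed),
    class = "pipeline_config")
}

#' Write / read a pipeline configuration as YAML
#'
#' @param config A [pipeline_config()].
#' @param path YAML file path.
#' @return `write_config()` returns `path` invisibly; `read_config()` a
#'   `pipeline_config`.
#' @export
write_config <- function(config, path) {
  stopifnot(inherits(config, "pipeline_config"))
  lst <- unclass(config)
  lst$bands <- as.data.frame(lst$bands)
  yaml::write_yaml(lst, path)
  invisible(path)
}

#' @rdname write_config
#' @export
read_config <- function(path) {
  lst <- yaml::read_yaml(path)
  lst$bands <- tibble::as_tibble(as.data.frame(lst$bands))
  do.call(pipeline_config, lst)
}

run_stage <- function(stage, id, expr) {
  tryCatch(expr, error = function(e) {
    stop(sprintf("stage '%s' failed for record '%s': %s", stage, id,
                 conditionMessage(e)), call. = FALSE)
  })
}

#' Run the full per-record analysis
#'
#' Fixed stage order: preictal extraction, 50 Hz notch, band decomposition,
#' windowed spectral entropy, trend fit and moving average. Optionally
#' writes all artifacts (one `<id>.<band>.sen.tsv` per band, a trend TSV
#' and a YAML run manifest with the configuration, package version and an
#' input fingerprint).
#'
#' @param record An [eeg_record] with a known seizure onset.
#' @param channel Focal channel name or index.
#' @param config A [pipeline_config()].
#' @param out_dir Optional output directory (created if needed).
#' @return An object of class `sen_analysis`: a list with `record_id`,
#'   `channel`, `config`, `entropy` (tibble `band`, `t_min`, `sen`),
#'   `trends` ([fit_trend()] rows), `moving_avg` and a stage `log`.
#'   Supports [generics::tidy()], [generics::glance()] and
#'   [ggplot2::autoplot()].
#' @examples
#' rec <- generate_eeg(synth_spec(duration_min = 50, seed = 7))
#' res <- run_record(rec, "ch1")
#' tidy(res)
#' @export
run_record <- function(record, channel, config = pipeline_config(),
                       out_dir = NULL) {
  stopifnot(inherits(config, "pipeline_config"))
  id <- record_id(record)
  rate <- sampling_rate(record)
  bands <- config$bands
  if (max(bands$f_hi_hz) > rate / 2 + 1e-9) {
    bands <- default_bands(rate)
  }
  seg <- run_stage("eeg_io", id,
    extract_preictal(record, channel, config$segment_min[[1L]],
                     config$segment_min[[2L]]))
  ent <- run_stage("entropy_engine", id,
    compute_entropy(seg, bands = bands, order = config$filter_order,
                    window_samples = config$window_samples,
                    n_bins = config$n_bins, notch_hz = config$notch_hz))
  trends <- run_stage("trend_analysis", id,
    fit_trend(ent, config$fit_interval_min))
  ma <- run_stage("trend_analysis", id,
    moving_average(ent, config$moving_avg_min))
  n_fit <- sum(ent$t_min >= config$fit_interval_min[[1L]] &
                 ent$t_min < config$fit_interval_min[[2L]] &
                 !is.na(ent$sen)) / nrow(bands)
  res <- structure(
    list(record_id = id, channel = attr(seg, "channel"), config = config,
         entropy = ent, trends = trends, moving_avg = ma,
         log = list(n_windows_per_band = nrow(ent) / nrow(bands),
                    n_fit_points_per_band = n_fit,
                    n_missing = sum(is.na(ent$sen)))),
    class = "sen_analysis")
  if (!is.null(out_dir)) write_analysis(res, out_dir)
  res
}

write_analysis <- function(res, out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  for (b in levels(res$entropy$band)) {
    sub <- res$entropy[res$entropy$band == b, ]
    utils::write.table(
      sub, file.path(out_dir, sprintf("%s.%s.sen.tsv", res$record_id, b)),
      sep = "\t", row.names = FALSE, quote = FALSE)
  }
  tr <- dplyr::mutate(res$trends, record_id = res$record_id,
                      .before = 1L)
  utils::write.table(
    tr, file.path(out_dir, sprintf("%s.trend.tsv", res$record_id)),
    sep = "\t", row.names = FALSE, quote = FALSE)
  manifest <- list(
    record_id = res$record_id, channel = res$channel,
    package_version = as.character(utils::packageVersion("sentrend")),
    config = {
      lst <- unclass(res$config); lst$bands <- as.data.frame(lst$bands); lst
    },
    log = res$log)
  yaml::write_yaml(manifest,
                   file.path(out_dir, sprintf("%s.manifest.yaml",
                                              res$record_id)))
  invisible(out_dir)
}

#' Aggregate per-record analyses into a cohort table
#'
#' @param analyses A list of `sen_analysis` objects (or a tibble of stacked
#'   trend rows with a `record_id`/`patient` column).
#' @param path Optional TSV path; if given, the rendered table
#'   ([render_table()]) is written there.
#' @return A `sen_cohort` from [build_cohort()].
#' @export
run_cohort <- function(analyses, path = NULL) {
  if (is.data.frame(analyses)) {
    rows <- analyses
  } else {
    if (length(analyses) == 0L) {
      stop("no records to aggregate", call. = FALSE)
    }
    rows <- purrr::map(analyses, function(a) {
      stopifnot(inherits(a, "sen_analysis"))
      dplyr::mutate(a$trends, patient = a$record_id, .before = 1L)
    })
    rows <- dplyr::bind_rows(rows)
  }
  if (nrow(rows) == 0L) stop("no records to aggregate", call. = FALSE)
  cohort <- build_cohort(rows)
  if (!is.null(path)) render_table(cohort, path)
  cohort
}
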
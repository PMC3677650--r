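#' @export
print.sen_analysis <- function(x, ...) {
  cat(sprintf(
    "<sen_analysis '%s' (channel %s): %d windows/band, fit [%g, %g) min>\n",
    x$record_id, x$channel, x$log$n_windows_per_band,
    x$config$fit_interval_min[[1L]], x$config$fit_interval_min[[2L]]))
  print(x$trends, ...)
  invisible(x)
}

#' Tidy per-band trend estimates of an analysis
#'
#' @param x A `sen_analysis` from [run_record()].
#' @param ... Unused.
#' @return A tibble with one row per band: `record_id`, `band`, `n_points`,
#'   `slope_per_min`, `slope_se`, `intercept`, `r`, `abs_r`, `degenerate`.
#' @method tidy sen_analysis
#' @export
tidy.sen_analysis <- function(x, ...) {
  dplyr::mutate(x$trends, record_id = x$record_id, .before = 1L)
}

#' One-row summary of an analysis
#'
#' @param x A `sen_analysis`.
#' @param ... Unused.
#' @return A one-row tibble: `record_id`, `channel`, `n_bands`,
#'   `n_windows_per_band`, `n_fit_points_per_band`, `n_missing`.
#' @method glance sen_analysis
#' @export
glance.sen_analysis <- function(x, ...) {
  tibble::tibble(
    record_id = x$record_id, channel = x$channel,
    n_bands = nrow(x$config$bands),
    n_windows_per_band = x$log$n_windows_per_band,
    n_fit_points_per_band = x$log$n_fit_points_per_band,
    n_missing = x$log$n_missing)
}

#' @method tidy sen_cohort
#' @export
tidy.sen_cohort <- function(x, ...) x$rows

#' @method glance sen_cohort
#' @export
glance.sen_cohort <- function(x, ...) {
  s <- tidyr::pivot_wider(
    x$summary, names_from = "band",
    values_from = c("mean_slope", "mean_abs_r", "n_positive_slope",
                    "n_negative_slope"))
  dplyr::mutate(s, n_patients = x$n_patients, .before = 1L)
}

#' Plot a per-record entropy analysis
#'
#' One panel per band showing the windowed spectral-entropy trace, the
#' 4-minute moving average and the fitted regression line over the fit
#' interval -- the standard per-patient display of a preictal entropy
#' analysis.
#'
#' @param object A `sen_analysis` from [run_record()].
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot sen_analysis
#' @export
autoplot.sen_analysis <- function(object, ...) {
  fit <- object$config$fit_interval_min
  seg <- dplyr::mutate(
    object$trends,
    t0 = fit[[1L]], t1 = fit[[2L]],
    sen0 = .data$intercept + .data$slope_per_min * fit[[1L]],
    sen1 = .data$intercept + .data$slope_per_min * fit[[2L]])
  ggplot2::ggplot(object$entropy,
                  ggplot2::aes(x = .data$t_min, y = .data$sen)) +
    ggplot2::geom_line(alpha = 0.35, linewidth = 0.3, na.rm = TRUE) +
    ggplot2::geom_line(
      data = object$moving_avg,
      ggplot2::aes(y = .data$value), colour = "#2166ac",
      linewidth = 0.7, na.rm = TRUE) +
    ggplot2::geom_segment(
      data = seg,
      ggplot2::aes(x = .data$t0, xend = .data$t1, y = .data$sen0,
                   yend = .data$sen1),
      colour = "#b2182b", linewidth = 0.7) +
    ggplot2::facet_wrap(~band, ncol = 1, scales = "free_y") +
    ggplot2::labs(
      x = "time relative to seizure onset (min)",
      y = "normalized spectral entropy",
      title = sprintf("Preictal spectral entropy: %s", object$record_id),
      subtitle = "trace, 4-min moving average (blue), trend fit (red)") +
    ggplot2::theme_minimal()
}

#' Plot cohort slope and correlation distributions
#'
#' @param object A `sen_cohort` from [build_cohort()].
#' @param ... Unused.
#' @return A ggplot object: per-band distribution of patient slopes with
#'   the cohort mean marked.
#' @method autoplot sen_cohort
#' @export
autoplot.sen_cohort <- function(object, ...) {
  ggplot2::ggplot(object$rows,
                  ggplot2::aes(x = .data$band, y = .data$slope)) +
    ggplot2::geom_hline(yintercept = 0, linetype = 2, colour = "grey50") +
    ggplot2::geom_jitter(width = 0.12, height = 0, alpha = 0.6) +
    ggplot2::stat_summary(fun = mean, geom = "crossbar", width = 0.4,
                          colour = "#b2182b", linewidth = 0.4) +
    ggplot2::labs(x = NULL, y = "SEN slope (per minute)",
                  title = "Preictal entropy slopes by frequency band",
                  subtitle = sprintf("%d patients; red bar = cohort mean",
                                     object$n_patients)) +
    ggplot2::theme_minimal()
}
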
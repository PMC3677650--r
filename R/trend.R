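#' Fit the preictal linear trend of a spectral-entropy series
#'
#' Ordinary least-squares regression of SEN on time (minutes relative to
#' onset) over the fit interval, plus the Pearson correlation of the same
#' points. The default interval is the half-open `[-32, -4)` minutes before
#' onset: the final 4 minutes are excluded because entropy can rise sharply
#' immediately before the seizure and would distort the linear fit. Missing
#' (`NA`) entropy values are excluded, not imputed.
#'
#' @param series A tibble with columns `t_min` and `sen`, and optionally
#'   `band` (fits are then per band), e.g. from [compute_entropy()].
#' @param interval_min Fit interval `c(lo, hi)` in minutes relative to onset;
#'   points with `lo <= t_min < hi` are used.
#' @return A tibble with one row per band: `band`, `n_points`,
#'   `slope_per_min` (SEN units per minute), `slope_se`, `intercept`, `r`
#'   (signed Pearson correlation), `abs_r`, and `degenerate` (`TRUE` when
#'   the series has zero variance, in which case the slope is 0 and the
#'   undefined correlation is reported as 0).
#' @examples
#' s <- tibble::tibble(t_min = seq(-32, -4.1, by = 16 / 60),
#'                     sen = 0.5 + 0.005411 * (seq_along(t_min) - 1) * 16 / 60)
#' fit_trend(s)
#' @export
fit_trend <- function(series, interval_min = c(-32, -4)) {
  stopifnot(is.data.frame(series), all(c("t_min", "sen") %in% names(series)))
  if (length(interval_min) != 2L || interval_min[[1L]] >= interval_min[[2L]]) {
    stop("`interval_min` must be c(lo, hi) with lo < hi", call. = FALSE)
  }
  if (!"band" %in% names(series)) series$band <- NA_character_
  series |>
    dplyr::group_by(.data$band) |>
    dplyr::group_modify(~ fit_trend_one(.x, interval_min)) |>
    dplyr::ungroup()
}

fit_trend_one <- function(df, interval_min) {
  pts <- df[!is.na(df$sen) &
              df$t_min >= interval_min[[1L]] &
              df$t_min < interval_min[[2L]], ]
  if (nrow(pts) < 3L) {
    stop(sprintf(
      "insufficient data: %d usable points in [%g, %g) min; need >= 3",
      nrow(pts), interval_min[[1L]], interval_min[[2L]]), call. = FALSE)
  }
  if (stats::var(pts$sen) == 0) {
    return(tibble::tibble(
      n_points = nrow(pts), slope_per_min = 0, slope_se = NA_real_,
      intercept = pts$sen[[1L]], r = 0, abs_r = 0, degenerate = TRUE))
  }
  fit <- stats::lm(sen ~ t_min, data = pts)
  cf <- stats::coef(fit)
  # slope SE computed directly (summary.lm warns on zero-residual fits)
  sxx <- sum((pts$t_min - mean(pts$t_min))^2)
  se <- sqrt(sum(stats::residuals(fit)^2) / (nrow(pts) - 2) / sxx)
  r <- stats::cor(pts$t_min, pts$sen)
  tibble::tibble(
    n_points = nrow(pts),
    slope_per_min = unname(cf[["t_min"]]),
    slope_se = se,
    intercept = unname(cf[["(Intercept)"]]),
    r = r, abs_r = abs(r), degenerate = FALSE)
}

#' Centered moving average of a spectral-entropy series
#'
#' Running mean over a time window (default 4 minutes, i.e. up to 15 of the
#' 16 s analysis windows), centered on each observation. Edges use the
#' available, shorter one-sided neighborhood. Missing values are skipped.
#' Used to visualize the entropy trend over the whole preictal span.
#'
#' @param series A tibble with columns `t_min` and `sen` (optionally `band`).
#' @param window_min Averaging interval in minutes (default 4); must exceed
#'   the series time step.
#' @return A tibble with columns `band`, `t_min`, `value` (the running
#'   mean) and `n_used` (points averaged). One output row per input row.
#' @export
moving_average <- function(series, window_min = 4) {
  stopifnot(is.data.frame(series), all(c("t_min", "sen") %in% names(series)))
  if (!"band" %in% names(series)) series$band <- NA_character_
  if (nrow(series) == 0L) {
    return(tibble::tibble(band = character(), t_min = numeric(),
                          value = numeric(), n_used = integer()))
  }
  step <- min(diff(sort(unique(series$t_min))), Inf)
  if (is.finite(step) && window_min <= step) {
    stop("`window_min` must exceed the series time step", call. = FALSE)
  }
  half <- window_min / 2
  series |>
    dplyr::group_by(.data$band) |>
    dplyr::group_modify(function(df, key) {
      value <- numeric(nrow(df))
      n_used <- integer(nrow(df))
      for (j in seq_len(nrow(df))) {
        sel <- abs(df$t_min - df$t_min[[j]]) <= half + 1e-9
        v <- df$sen[sel]
        v <- v[!is.na(v)]
        n_used[[j]] <- length(v)
        value[[j]] <- if (length(v)) mean(v) else NA_real_
      }
      tibble::tibble(t_min = df$t_min, value = value, n_used = n_used)
    }) |>
    dplyr::ungroup()
}
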
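#' Published reference cohort values
#'
#' Per-patient regression slopes and absolute Pearson correlations of the
#' preictal spectral-entropy trend in the low, mid and high frequency bands,
#' as published for the 20-patient focal-epilepsy cohort of the Freiburg
#' seizure-prediction project (invasive recordings, focal channel, fit over
#' the 32-to-4-minute preictal interval). The recordings themselves are not
#' redistributable; these printed per-patient values let the cohort-level
#' arithmetic be exercised and checked without them. Values carry the
#' published precision (slopes 6 decimals, correlations 2).
#'
#' @return A tibble with columns `patient` (1-20), `band` (factor:
#'   low/mid/high), `slope` (SEN per minute) and `abs_r`.
#' @examples
#' build_cohort(cohort_reference())
#' @export
cohort_reference <- function() {
  path <- system.file("extdata", "cohort_reference.tsv",
                      package = "sentrend", mustWork = TRUE)
  wide <- utils::read.delim(path, check.names = FALSE)
  long <- tidyr::pivot_longer(
    wide, -"patient",
    names_to = c(".value", "band"), names_sep = "_")
  out <- tibble::tibble(
    patient = long$patient,
    band = factor(long$band, levels = c("low", "mid", "high")),
    slope = long$slope,
    abs_r = long$r)
  out[order(out$patient, out$band), ]
}

#' Assemble per-patient trends into a cohort table
#'
#' Collects one (slope, |r|) pair per patient and band and computes the
#' cohort statistics: unweighted arithmetic mean slope and mean |r| per band,
#' and the count of strictly positive slopes. Every patient must contribute
#' exactly one row per band.
#'
#' @param rows A tibble with columns `patient` (or `record_id`), `band`,
#'   `slope` (or `slope_per_min`) and `abs_r`, e.g. stacked [fit_trend()]
#'   results.
#' @return An object of class `sen_cohort`: a list with `rows` (the
#'   per-patient long table), `summary` (per-band `mean_slope`, `mean_abs_r`,
#'   `n_positive_slope`, `n_negative_slope`) and `n_patients`. Means are
#'   computed in full precision; rounding happens only at rendering.
#' @seealso [render_table()], [cohort_reference()]
#' @export
build_cohort <- function(rows) {
  stopifnot(is.data.frame(rows))
  rows <- tibble::as_tibble(rows)
  if (!"patient" %in% names(rows) && "record_id" %in% names(rows)) {
    rows <- dplyr::rename(rows, patient = "record_id")
  }
  if (!"slope" %in% names(rows) && "slope_per_min" %in% names(rows)) {
    rows <- dplyr::rename(rows, slope = "slope_per_min")
  }
  need <- c("patient", "band", "slope", "abs_r")
  if (!all(need %in% names(rows))) {
    stop("`rows` needs columns: ", paste(need, collapse = ", "),
         call. = FALSE)
  }
  if (nrow(rows) == 0L) stop("no patient rows supplied", call. = FALSE)
  band_levels <- if (is.factor(rows$band)) levels(rows$band) else
    unique(as.character(rows$band))
  rows$band <- factor(as.character(rows$band), levels = band_levels)
  counts <- table(rows$patient, rows$band)
  bad <- which(counts != 1L, arr.ind = TRUE)
  if (nrow(bad) > 0L) {
    stop(sprintf(
      "incomplete row: patient '%s' has %d entries for band '%s' (expected 1)",
      rownames(counts)[bad[1L, 1L]], counts[bad[1L, , drop = FALSE]],
      colnames(counts)[bad[1L, 2L]]), call. = FALSE)
  }
  summary <- rows |>
    dplyr::group_by(.data$band) |>
    dplyr::summarise(
      mean_slope = mean(.data$slope),
      mean_abs_r = mean(.data$abs_r),
      n_positive_slope = sum(.data$slope > 0),
      n_negative_slope = sum(.data$slope < 0),
      .groups = "drop")
  structure(
    list(rows = rows[order(rows$patient, rows$band),
                     c("patient", "band", "slope", "abs_r")],
         summary = summary,
         n_patients = length(unique(rows$patient))),
    class = "sen_cohort")
}

#' @export
print.sen_cohort <- function(x, ...) {
  cat(sprintf("<sen_cohort: %d patients x %d bands>\n", x$n_patients,
              nrow(x$summary)))
  print(x$summary, ...)
  invisible(x)
}

cohort_wide <- function(rows) {
  bands <- levels(rows$band)
  wide <- tidyr::pivot_wider(
    rows, id_cols = "patient", names_from = "band",
    values_from = c("slope", "abs_r"), names_sep = "_")
  wide[c("patient", paste0("slope_", bands), paste0("abs_r_", bands))]
}

#' Render a cohort table to delimited text
#'
#' Writes one row per patient with band-grouped columns (all slopes, then all
#' |r|), followed by an `Average` row. Slopes are printed with 6 decimals and
#' correlations with 2, the precision of the published reference table; the
#' averages are computed in full precision and rounded only for display.
#'
#' @param cohort A `sen_cohort` from [build_cohort()].
#' @param path Output path (TSV).
#' @return `path`, invisibly.
#' @export
render_table <- function(cohort, path) {
  stopifnot(inherits(cohort, "sen_cohort"))
  bands <- levels(cohort$rows$band)
  header <- c("patient", paste0("slope_", bands), paste0("r_", bands))
  con <- tryCatch(file(path, open = "wt"),
                  error = function(e) stop("I/O error: cannot write ", path,
                                           ": ", conditionMessage(e),
                                           call. = FALSE))
  on.exit(close(con))
  writeLines(paste(header, collapse = "\t"), con)
  if (cohort$n_patients == 0L) {
    warning("empty cohort: wrote header only", call. = FALSE)
    return(invisible(path))
  }
  wide <- cohort_wide(cohort$rows)
  fmt_row <- function(id, slopes, rs) {
    paste(c(id, sprintf("%.6f", slopes), sprintf("%.2f", rs)),
          collapse = "\t")
  }
  for (i in seq_len(nrow(wide))) {
    writeLines(fmt_row(
      wide$patient[[i]],
      unlist(wide[i, paste0("slope_", bands)]),
      unlist(wide[i, paste0("abs_r_", bands)])), con)
  }
  s <- cohort$summary[match(bands, as.character(cohort$summary$band)), ]
  writeLines(fmt_row("Average", s$mean_slope, s$mean_abs_r), con)
  invisible(path)
}
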
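#' Specification for a synthetic preictal EEG record
#'
#' Describes a single-channel synthetic recording emulating invasive focal
#' EEG: a 1/f^alpha Gaussian background, optional 50 Hz line contamination,
#' optional Poisson-timed biphasic spike transients, and a programmable,
#' signed per-band drift of the in-band spectral-entropy (SEN) toward
#' flattening (positive drift) or concentration (negative drift). Seizure
#' onset is placed at the end of the record so a 32-minute preictal segment
#' is always available at the default duration.
#'
#' Drift is realized as a time-varying convex mixture between a broadband
#' (flat in-band spectrum, high SEN) and a narrowband (concentrated
#' spectrum, low SEN) noise process within the band, because SEN responds to
#' spectral shape, not power. The mixing weight is solved at each time point
#' so that the band's nominal SEN follows the straight line
#' `sen_mid + drift * (t - t_mid)` (t in minutes relative to onset), giving
#' an approximately linear SEN trajectory. A drift whose implied SEN leaves
#' the achievable range of the mixture is rejected as infeasible.
#'
#' @param duration_min Record length in minutes (default 50, the minimum
#'   preictal history in the target data).
#' @param rate_hz Sampling rate in Hz (default 256).
#' @param background_exponent Spectral exponent alpha of the 1/f^alpha
#'   background (default 1).
#' @param line_noise_amp Amplitude of an added 50 Hz sinusoid (default 0;
#'   the background is normalized to unit standard deviation, so 1 means
#'   line noise on the scale of the EEG).
#' @param spike_rate_per_min Expected spike transients per minute
#'   (default 0).
#' @param spike_amp Peak spike amplitude in background-SD units (default 8).
#' @param drift Named numeric vector of SEN drift rates per minute for any of
#'   `low`, `mid`, `high` (e.g. `c(high = 0.005)`); unnamed bands carry the
#'   plain 1/f background and drift 0.
#' @param sen_mid Nominal SEN of each drifting band at the record midpoint
#'   (default 0.85).
#' @param seed Integer RNG seed; the generated record is a pure function of
#'   the spec.
#' @return A list of class `synth_spec`.
#' @seealso [generate_eeg()]
#' @export
synth_spec <- function(duration_min = 50, rate_hz = 256,
                       background_exponent = 1, line_noise_amp = 0,
                       spike_rate_per_min = 0, spike_amp = 8,
                       drift = NULL, sen_mid = 0.85, seed = 1) {
  n <- duration_min * 60 * rate_hz
  if (abs(n - round(n)) > 1e-9) {
    stop("`duration_min * 60 * rate_hz` must be an integer sample count",
         call. = FALSE)
  }
  if (line_noise_amp < 0 || spike_rate_per_min < 0) {
    stop("`line_noise_amp` and `spike_rate_per_min` must be >= 0",
         call. = FALSE)
  }
  bands <- default_bands(rate_hz)
  drift_full <- stats::setNames(rep(0, nrow(bands)), bands$band)
  if (!is.null(drift) && length(drift)) {
    if (is.null(names(drift)) || !all(names(drift) %in% bands$band)) {
      stop("`drift` must be named with band names: ",
           paste(bands$band, collapse = ", "), call. = FALSE)
    }
    drift_full[names(drift)] <- drift
  }
  spec <- structure(
    list(duration_min = duration_min, rate_hz = rate_hz,
         background_exponent = background_exponent,
         line_noise_amp = line_noise_amp,
         spike_rate_per_min = spike_rate_per_min, spike_amp = spike_amp,
         drift = drift_full, sen_mid = sen_mid, seed = as.integer(seed),
         n_samples = as.integer(round(n)), bands = bands),
    class = "synth_spec")
  for (b in bands$band[drift_full[bands$band] != 0]) {
    check_drift_feasible(spec, b)
  }
  spec
}

# Bin bookkeeping for a band under the default analysis settings
# (4096-sample windows aggregated to 1024 bins): in-band bin count N and
# the bin count m of the narrow sub-band (centered, 1/8 of the band width)
# used as the concentrated mixture component.
band_bin_model <- function(spec, band, window_samples = 4096,
                           n_bins = 1024) {
  row <- spec$bands[spec$bands$band == band, ]
  g <- (window_samples %/% 2L) %/% n_bins
  freqs <- colMeans(matrix(seq_len(window_samples %/% 2L) *
                             spec$rate_hz / window_samples, nrow = g))
  centre <- (row$f_lo_hz + row$f_hi_hz) / 2
  width <- (row$f_hi_hz - row$f_lo_hz) / 8
  nb_lo <- centre - width / 2
  nb_hi <- centre + width / 2
  list(
    f_lo = row$f_lo_hz, f_hi = row$f_hi_hz,
    nb_lo = nb_lo, nb_hi = nb_hi,
    N = sum(freqs >= row$f_lo_hz & freqs < row$f_hi_hz),
    m = sum(freqs >= nb_lo & freqs < nb_hi))
}

# SEN of the two-block mixture spectrum: weight (1-lam) spread flat over N
# bins plus weight lam concentrated flat over m of them.
sen_two_block <- function(lam, N, m) {
  p_out <- (1 - lam) / N
  p_in <- (1 - lam) / N + lam / m
  h <- 0
  if (p_out > 0) h <- h - (N - m) * p_out * log(p_out)
  if (p_in > 0) h <- h - m * p_in * log(p_in)
  h / log(N)
}

check_drift_feasible <- function(spec, band) {
  bm <- band_bin_model(spec, band)
  half_span <- abs(spec$drift[[band]]) * spec$duration_min / 2
  lo_target <- spec$sen_mid - half_span
  hi_target <- spec$sen_mid + half_span
  sen_min <- sen_two_block(1, bm$N, bm$m)
  if (lo_target < sen_min + 0.01 || hi_target > 1 - 1e-3 ||
      lo_target < 0 || hi_target > 1) {
    stop(sprintf(
      "infeasible drift for band '%s': target SEN range [%.3f, %.3f] outside achievable [%.3f, %.3f]",
      band, lo_target, hi_target, sen_min + 0.01, 1 - 1e-3), call. = FALSE)
  }
  invisible(bm)
}

# Gaussian noise with a prescribed one-sided amplitude profile, built in the
# frequency domain (Hermitian spectrum -> real signal). `amp` has one value
# per positive-frequency bin k = 1..n/2 (frequency k * rate / n).
shaped_noise <- function(n, amp) {
  half <- n %/% 2L
  stopifnot(length(amp) == half)
  z <- stats::rnorm(half) + 1i * stats::rnorm(half)
  z[half] <- stats::rnorm(1) * sqrt(2)   # Nyquist bin must be real
  X <- complex(n)
  X[2:(half + 1L)] <- z * amp
  X[n:(half + 2L)] <- Conj(X[2:half])
  Re(stats::fft(X, inverse = TRUE)) / n
}

#' Generate a synthetic preictal EEG record
#'
#' Realizes a [synth_spec()]: spectrally shaped Gaussian background (with
#' any drifting band's frequency range carved out and replaced by the
#' drift mixture), programmed per-band SEN drift, optional 50 Hz line noise
#' and spike transients. The output is normalized so the spike-free signal
#' has unit standard deviation; amplitude is arbitrary anyway since SEN is
#' scale-invariant. Identical specs produce bit-identical records.
#'
#' @param spec A [synth_spec()].
#' @return An [eeg_record] with a single channel `ch1`, seizure onset at the
#'   record end, and the ground truth (the spec plus per-band programmed
#'   drift) attached as attribute `ground_truth`.
#' @examples
#' rec <- generate_eeg(synth_spec(duration_min = 2, seed = 42))
#' nrow(rec)
#' @export
generate_eeg <- function(spec) {
  stopifnot(inherits(spec, "synth_spec"))
  set.seed(spec$seed)
  n <- spec$n_samples
  rate <- spec$rate_hz
  half <- n %/% 2L
  freqs <- seq_len(half) * rate / n
  alpha <- spec$background_exponent

  # reference 1/f^alpha amplitude profile; flat below 0.05 Hz to avoid the
  # DC blow-up (invasive recordings are AC-coupled in effect)
  amp_ref <- pmax(freqs, 0.05)^(-alpha / 2)
  drifting <- names(spec$drift)[spec$drift != 0]
  mask <- rep(TRUE, half)
  for (b in drifting) {
    row <- spec$bands[spec$bands$band == b, ]
    mask <- mask & !(freqs >= row$f_lo_hz & freqs < row$f_hi_hz)
  }
  pow_ref_total <- sum(amp_ref^2)
  x <- shaped_noise(n, amp_ref * mask)
  x <- x / stats::sd(x) * sqrt(sum((amp_ref * mask)^2) / pow_ref_total)

  t_min_rel_onset <- (seq_len(n) - 1) / rate / 60 - spec$duration_min
  for (b in drifting) {
    bm <- band_bin_model(spec, b)
    broad <- shaped_noise(n, as.numeric(freqs >= bm$f_lo & freqs < bm$f_hi))
    narrow <- shaped_noise(n, as.numeric(freqs >= bm$nb_lo &
                                           freqs < bm$nb_hi))
    broad <- broad / stats::sd(broad)
    narrow <- narrow / stats::sd(narrow)
    # solve the mixing weight at 4 s knots, interpolate per sample
    knots_s <- seq(0, spec$duration_min * 60, by = 4)
    knots_min <- knots_s / 60 - spec$duration_min
    target <- spec$sen_mid +
      spec$drift[[b]] * (knots_min + spec$duration_min / 2)
    lam <- vapply(target, function(s) {
      if (s >= sen_two_block(0, bm$N, bm$m)) return(0)
      stats::uniroot(function(l) sen_two_block(l, bm$N, bm$m) - s,
                     c(0, 1), tol = 1e-9)$root
    }, numeric(1))
    lam_t <- stats::approx(knots_s, lam, xout = (seq_len(n) - 1) / rate,
                           rule = 2)$y
    sel <- freqs >= bm$f_lo & freqs < bm$f_hi
    band_scale <- sqrt(sum(amp_ref[sel]^2) / pow_ref_total)
    x <- x + band_scale *
      (sqrt(1 - lam_t) * broad + sqrt(lam_t) * narrow)
  }

  x <- x / stats::sd(x)
  if (spec$line_noise_amp > 0) {
    x <- x + spec$line_noise_amp *
      sin(2 * pi * 50 * (seq_len(n) - 1) / rate)
  }
  if (spec$spike_rate_per_min > 0) {
    x <- inject_spikes(x, rate, spec$spike_rate_per_min, spec$spike_amp)
  }
  rec <- eeg_record(
    tibble::tibble(ch1 = x), rate,
    seizure_onset_s = spec$duration_min * 60,
    record_id = sprintf("synth-seed%d", spec$seed))
  attr(rec, "ground_truth") <- list(
    drift = spec$drift, sen_mid = spec$sen_mid,
    onset_s = spec$duration_min * 60, spec = spec)
  rec
}

#' Ground truth of a synthetic record
#'
#' @param record An [eeg_record] produced by [generate_eeg()].
#' @return The ground-truth list (programmed per-band drift, nominal
#'   mid-record SEN, onset time and the full spec), or `NULL`.
#' @export
ground_truth <- function(record) attr(record, "ground_truth", exact = TRUE)

#' Add biphasic spike transients to a signal
#'
#' Superimposes epileptiform-like spikes at Poisson-distributed times. The
#' template is a biphasic Gaussian-derivative transient: ~70 ms support with
#' a sharp core (5 ms scale, ~20 ms between the opposite peaks), matching
#' the sharp component of intracranial interictal spikes. Its spectrum is
#' broadband, reaching well into the gamma band, which makes spikes the main
#' driver of window-to-window variability of high-band spectral entropy.
#'
#' @param x Numeric signal.
#' @param rate_hz Sampling rate in Hz.
#' @param rate_per_min Expected spikes per minute; 0 returns `x` unchanged.
#' @param amp Peak spike amplitude (same units as `x`).
#' @param seed Optional seed for the spike times; `NULL` (default) draws
#'   from the current RNG stream.
#' @return The signal with spikes added, same length as `x`.
#' @export
inject_spikes <- function(x, rate_hz, rate_per_min, amp = 8, seed = NULL) {
  if (rate_per_min < 0) stop("`rate_per_min` must be >= 0", call. = FALSE)
  if (rate_per_min == 0) return(x)
  if (!is.null(seed)) set.seed(seed)
  dur_min <- length(x) / rate_hz / 60
  n_spikes <- stats::rpois(1, rate_per_min * dur_min)
  if (n_spikes == 0) return(x)
  tt <- seq(-0.035, 0.035, by = 1 / rate_hz)
  sigma <- 0.005
  template <- -tt / sigma^2 * exp(-tt^2 / (2 * sigma^2))
  template <- template / max(abs(template)) * amp
  L <- length(template)
  starts <- sample.int(length(x) - L + 1L, n_spikes, replace = TRUE)
  for (s in starts) {
    idx <- s:(s + L - 1L)
    x[idx] <- x[idx] + template
  }
  attr(x, "n_spikes") <- n_spikes
  x
}
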
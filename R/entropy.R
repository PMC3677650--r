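#' Binned power spectrum of one analysis window
#'
#' Squared-magnitude discrete Fourier spectrum at positive frequencies,
#' aggregated (summed) into `n_bins` uniform bins spanning `(0, rate/2]`.
#' With the default 4096-sample window the 2048 positive-frequency values are
#' pooled in adjacent pairs into 1024 bins of width `rate/2048` Hz. The DC
#' component is excluded; total power equals the sum over bins.
#'
#' @param x Numeric window of even length; `length(x) / 2` must be a
#'   multiple of `n_bins`.
#' @param rate_hz Sampling rate in Hz.
#' @param n_bins Number of output frequency bins (default 1024).
#' @return A tibble with columns `freq_hz` (bin centers, strictly
#'   increasing) and `power` (non-negative).
#' @examples
#' ps <- power_spectrum(sin(2 * pi * 10 * (0:4095) / 256), 256)
#' ps$freq_hz[which.max(ps$power)]
#' @export
power_spectrum <- function(x, rate_hz, n_bins = 1024) {
  L <- length(x)
  if (L < 2L || L %% 2L != 0L) {
    stop("window length must be even and >= 2", call. = FALSE)
  }
  half <- L %/% 2L
  if (half %% n_bins != 0L) {
    stop(sprintf(
      "cannot aggregate %d positive-frequency values into %d uniform bins",
      half, n_bins), call. = FALSE)
  }
  X <- stats::fft(x)
  P <- Mod(X[2:(half + 1L)])^2
  g <- half %/% n_bins
  freqs <- seq_len(half) * rate_hz / L
  if (g == 1L) {
    tibble::tibble(freq_hz = freqs, power = P)
  } else {
    grp <- matrix(P, nrow = g)
    tibble::tibble(
      freq_hz = colMeans(matrix(freqs, nrow = g)),
      power = colSums(grp)
    )
  }
}

#' Normalized spectral entropy (SEN)
#'
#' Shannon entropy of the power-spectrum distribution restricted to a
#' frequency band, normalized by the log of the in-band bin count so that
#' the value lies in \[0, 1\]:
#' \deqn{SEN = -\sum_k P_k \log P_k / \log N,}
#' where the \eqn{P_k} are the in-band bin powers normalized to sum to one
#' and \eqn{N} is the number of in-band bins. 1 means a flat (maximally
#' dispersed) in-band spectrum, 0 means all power in a single bin.
#' Zero-power bins contribute 0 (the \eqn{p \log p \to 0} limit); the ratio
#' form makes the result independent of the logarithm base and of any
#' amplitude scaling of the signal.
#'
#' @param power A [power_spectrum()] tibble, or a numeric vector of bin
#'   powers (then supply `freq_hz` to use a band restriction).
#' @param freq_hz Bin center frequencies (taken from `power` when it is a
#'   data frame).
#' @param f_lo_hz,f_hi_hz Band limits; bins with center in
#'   `[f_lo_hz, f_hi_hz)` are used. Defaults keep all bins.
#' @param base Logarithm base (default `exp(1)`; the result does not depend
#'   on it).
#' @return A number in \[0, 1\], or `NA` if the total in-band power is zero
#'   (undefined entropy, reported as missing rather than 0 or 1).
#' @examples
#' spectral_entropy(rep(1, 8))            # flat -> 1
#' spectral_entropy(c(1, 0, 0, 0))        # concentrated -> 0
#' spectral_entropy(c(1, 1, 0, 0))        # log(2)/log(4) = 0.5
#' @export
spectral_entropy <- function(power, freq_hz = NULL, f_lo_hz = -Inf,
                             f_hi_hz = Inf, base = exp(1)) {
  if (is.data.frame(power)) {
    freq_hz <- power$freq_hz
    power <- power$power
  }
  if (!is.null(freq_hz)) {
    if (length(freq_hz) != length(power)) {
      stop("`freq_hz` and `power` lengths differ", call. = FALSE)
    }
    sel <- freq_hz >= f_lo_hz & freq_hz < f_hi_hz
    power <- power[sel]
  }
  if (any(power < 0, na.rm = TRUE)) {
    stop("bin powers must be non-negative", call. = FALSE)
  }
  n <- length(power)
  if (n < 2L) {
    stop("need at least 2 in-band bins to define spectral entropy",
         call. = FALSE)
  }
  tot <- sum(power)
  if (!is.finite(tot) || tot <= 0) return(NA_real_)
  p <- power / tot
  p <- p[p > 0]
  sen <- -sum(p * log(p, base = base)) / log(n, base = base)
  min(max(sen, 0), 1)
}

#' Windowed spectral-entropy series for one band
#'
#' Cuts the band-filtered signal into non-overlapping windows (default
#' 4096 samples = 16 s at 256 Hz; any trailing remainder is discarded),
#' computes the binned power spectrum of each, and evaluates the normalized
#' spectral entropy over the band's bins. Window timestamps are the window
#' centers, in minutes relative to seizure onset (negative = preictal).
#'
#' @param x Numeric band-filtered signal.
#' @param rate_hz Sampling rate in Hz.
#' @param f_lo_hz,f_hi_hz Band limits for the entropy computation.
#' @param start_s_rel_onset Time of the first sample, in seconds relative to
#'   onset (e.g. -1920 for a segment starting 32 min before the seizure).
#' @param window_samples Samples per window (default 4096).
#' @param n_bins Spectral bins per window (default 1024).
#' @param band Optional band label stored in the output.
#' @return A tibble with columns `band`, `t_min` (strictly increasing, step
#'   `window_samples / rate_hz / 60` min) and `sen` in \[0, 1\] (`NA` for
#'   windows with zero in-band power). Zero windows fit in the signal gives
#'   an empty tibble with a warning.
#' @export
entropy_series <- function(x, rate_hz, f_lo_hz, f_hi_hz,
                           start_s_rel_onset = 0, window_samples = 4096,
                           n_bins = 1024, band = NA_character_) {
  if (window_samples < 2) {
    stop("`window_samples` must be >= 2", call. = FALSE)
  }
  nw <- floor(length(x) / window_samples)
  if (nw == 0L) {
    warning(sprintf(
      "signal (%d samples) is shorter than one %d-sample window; empty series",
      length(x), window_samples), call. = FALSE)
    return(tibble::tibble(band = character(), t_min = numeric(),
                          sen = numeric()))
  }
  half <- window_samples %/% 2L
  if (window_samples %% 2L != 0L || half %% n_bins != 0L) {
    stop("`window_samples` must be even and `window_samples / 2` a multiple of `n_bins`",
         call. = FALSE)
  }
  g <- half %/% n_bins
  mat <- matrix(x[seq_len(nw * window_samples)], nrow = window_samples)
  P <- Mod(stats::mvfft(mat)[2:(half + 1L), , drop = FALSE])^2
  freqs <- seq_len(half) * rate_hz / window_samples
  if (g > 1L) {
    P <- rowsum(P, rep(seq_len(n_bins), each = g))
    freqs <- colMeans(matrix(freqs, nrow = g))
  }
  sel <- freqs >= f_lo_hz & freqs < f_hi_hz
  if (sum(sel) < 2L) {
    stop("fewer than 2 spectral bins fall inside the band", call. = FALSE)
  }
  Pb <- P[sel, , drop = FALSE]
  n_band <- nrow(Pb)
  tot <- colSums(Pb)
  sen <- vapply(seq_len(nw), function(j) {
    if (tot[[j]] <= 0) return(NA_real_)
    p <- Pb[, j] / tot[[j]]
    p <- p[p > 0]
    min(max(-sum(p * log(p)) / log(n_band), 0), 1)
  }, numeric(1))
  t_min <- (start_s_rel_onset +
              (seq_len(nw) - 0.5) * window_samples / rate_hz) / 60
  tibble::tibble(band = band, t_min = t_min, sen = sen)
}

#' Band-wise spectral-entropy series for a preictal segment
#'
#' The per-record analysis core: 50 Hz notch, band decomposition, then a
#' windowed spectral-entropy series per band.
#'
#' @param segment An `eeg_segment` from [extract_preictal()].
#' @param bands Band table (default [default_bands()] at the segment's rate).
#' @param order FIR order for notch and band filters (default 40).
#' @param window_samples Samples per analysis window (default 4096).
#' @param n_bins Spectral bins (default 1024).
#' @param notch_hz Line frequency to notch, or `NA` to skip the notch
#'   (skipping is logged with a message).
#' @return A tibble with columns `band` (factor in band order), `t_min`,
#'   `sen`.
#' @export
compute_entropy <- function(segment, bands = NULL, order = 40,
                            window_samples = 4096, n_bins = 1024,
                            notch_hz = 50) {
  if (!inherits(segment, "eeg_segment")) {
    stop("`segment` must be an eeg_segment from extract_preictal()",
         call. = FALSE)
  }
  rate <- sampling_rate(segment)
  bands <- bands %||% default_bands(rate)
  x <- segment$value
  if (is.na(notch_hz)) {
    message("notch filter skipped by caller")
  } else {
    x <- notch_50hz(x, rate, notch_hz, order)
  }
  filtered <- split_bands(x, rate, bands, order)
  start_s <- segment$t_s[[1L]]
  out <- purrr::pmap(
    bands[c("band", "f_lo_hz", "f_hi_hz")],
    function(band, f_lo_hz, f_hi_hz) {
      entropy_series(filtered[[band]], rate, f_lo_hz, f_hi_hz,
                     start_s_rel_onset = start_s,
                     window_samples = window_samples, n_bins = n_bins,
                     band = band)
    })
  out <- dplyr::bind_rows(out)
  out$band <- factor(out$band, levels = bands$band)
  out
}
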
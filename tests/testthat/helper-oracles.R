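# Independent oracles used across tests: direct DTFT evaluation for filter
# responses, quadrature projection for sinusoid amplitudes, and a plain
# textbook recomputation of normalized spectral entropy.

dtft_gain <- function(taps, f, rate) {
  n <- seq_along(taps) - 1
  vapply(f, function(ff) Mod(sum(taps * exp(-2i * pi * ff / rate * n))),
         numeric(1))
}

rms <- function(x) sqrt(mean(x^2))

sine <- function(f, n, rate, phase = 0) {
  sin(2 * pi * f * (seq_len(n) - 1) / rate + phase)
}

# amplitude of the frequency-f component of x by projection onto the
# quadrature pair at f
proj_amp <- function(x, f, rate) {
  n <- length(x)
  t <- (seq_len(n) - 1) / rate
  sqrt((2 / n * sum(x * sin(2 * pi * f * t)))^2 +
         (2 / n * sum(x * cos(2 * pi * f * t)))^2)
}

# brute-force normalized spectral entropy of a discrete spectrum
brute_sen <- function(p, base = exp(1)) {
  stopifnot(all(p >= 0), length(p) >= 2)
  if (sum(p) == 0) return(NA_real_)
  q <- p / sum(p)
  q <- q[q > 0]
  -sum(q * log(q, base = base)) / log(length(p), base = base)
}

make_white_record <- function(n, rate = 256, seed = 1, onset_s = n / rate) {
  set.seed(seed)
  eeg_record(data.frame(ch1 = rnorm(n)), rate, seizure_onset_s = onset_s,
             record_id = sprintf("white-%d", seed))
}

# high-band SEN variance of a 28-min signal after the standard pipeline
high_band_sen_var <- function(x, rate = 256) {
  v <- notch_50hz(x, rate)
  hb <- split_bands(v, rate)$high
  stats::var(entropy_series(hb, rate, 32, rate / 2, -1920)$sen, na.rm = TRUE)
}
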
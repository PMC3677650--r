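test_that("non-overlapping windowing yields floor(n / window) windows", {
  set.seed(1)
  s28 <- entropy_series(rnorm(430080), 256, 0.1, 12,
                        start_s_rel_onset = -1920)
  expect_equal(nrow(s28), 105)
  expect_true(all(s28$sen >= 0 & s28$sen <= 1, na.rm = TRUE))
  expect_equal(unique(round(diff(s28$t_min), 10)), 16 / 60)
  s32 <- entropy_series(rnorm(491520), 256, 0.1, 12,
                        start_s_rel_onset = -1920)
  expect_equal(nrow(s32), 120)
  expect_warning(
    empty <- entropy_series(rnorm(4000), 256, 0.1, 12),
    "shorter than one")
  expect_equal(nrow(empty), 0)
})

test_that("power spectrum concentrates a bin-centered sine in one bin", {
  n <- 4096
  rate <- 256
  f <- 16                                  # exactly at a DFT bin
  ps <- power_spectrum(sine(f, n, rate), rate)
  expect_equal(nrow(ps), 1024)
  expect_true(all(diff(ps$freq_hz) > 0))
  k <- which.max(ps$power)
  expect_lt(abs(ps$freq_hz[[k]] - f), rate / 2 / 1024)
  expect_gte(ps$power[[k]] / sum(ps$power), 0.99)
  # oracle: direct DFT summation at f
  t <- (seq_len(n) - 1) / rate
  direct <- Mod(sum(sine(f, n, rate) * exp(-2i * pi * f * t)))^2
  expect_equal(ps$power[[k]], direct, tolerance = 1e-8)

  expect_true(all(power_spectrum(numeric(n), rate)$power == 0))
})

test_that("binned power obeys Parseval's identity", {
  set.seed(2)
  for (i in 1:20) {
    x <- rnorm(256)
    x <- x - mean(x)
    ps <- power_spectrum(x, 256, n_bins = 64)
    ratio <- sum(ps$power) / sum(x^2)
    expect_equal(ratio, 256 / 2, tolerance = 0.02)
  }
})

test_that("spectral entropy matches its analytic extremes and closed forms", {
  expect_equal(spectral_entropy(rep(1, 1024)), 1)
  expect_equal(spectral_entropy(c(5, 0, 0, 0, 0, 0)), 0)
  expect_equal(spectral_entropy(c(1, 1, 0, 0)), 0.5)  # log 2 / log 4
  expect_true(is.na(spectral_entropy(numeric(8))))
  expect_error(spectral_entropy(c(1, -1, 1)), "non-negative")
  expect_error(spectral_entropy(1), "at least 2")
  # band restriction picks bins with center in [f_lo, f_hi)
  ps <- tibble::tibble(freq_hz = c(1, 2, 3, 4, 5), power = c(9, 1, 1, 1, 9))
  expect_equal(spectral_entropy(ps, f_lo_hz = 2, f_hi_hz = 5), 1)
})

test_that("spectral entropy is invariant to log base and amplitude", {
  set.seed(3)
  for (i in 1:50) {
    p <- rexp(sample(4:64, 1))
    p[sample(length(p), 1)] <- 0
    s_e <- spectral_entropy(p)
    expect_equal(s_e, spectral_entropy(p, base = 2), tolerance = 1e-12)
    expect_equal(s_e, spectral_entropy(p, base = 10), tolerance = 1e-12)
    expect_equal(s_e, spectral_entropy(p * 1e6), tolerance = 1e-12)
    expect_equal(s_e, brute_sen(p), tolerance = 1e-12)
  }
})

test_that("concentrating power never increases entropy", {
  set.seed(4)
  for (i in 1:100) {
    p <- rexp(sample(5:40, 1))
    ij <- order(p)[c(1, length(p))]       # lowest- and highest-power bin
    delta <- runif(1) * p[[ij[[1]]]]
    q <- p
    q[[ij[[1]]]] <- q[[ij[[1]]]] - delta
    q[[ij[[2]]]] <- q[[ij[[2]]]] + delta
    expect_lte(spectral_entropy(q), spectral_entropy(p) + 1e-12)
    expect_equal(spectral_entropy(q), brute_sen(q), tolerance = 1e-12)
  }
})

test_that("white-noise full-band entropy is near its flat-spectrum maximum", {
  set.seed(5)
  sens <- replicate(50,
    spectral_entropy(power_spectrum(rnorm(4096), 256)))
  expect_gte(mean(sens), 0.9)
})

test_that("entropy_series matches the single-window composition", {
  set.seed(6)
  x <- rnorm(3 * 512)
  series <- entropy_series(x, 256, 5, 60, start_s_rel_onset = 0,
                           window_samples = 512, n_bins = 128)
  expect_equal(nrow(series), 3)
  for (w in 1:3) {
    ps <- power_spectrum(x[((w - 1) * 512 + 1):(w * 512)], 256,
                         n_bins = 128)
    expect_equal(series$sen[[w]],
                 spectral_entropy(ps, f_lo_hz = 5, f_hi_hz = 60),
                 tolerance = 1e-12)
    expect_equal(series$t_min[[w]], (w - 0.5) * 2 / 60, tolerance = 1e-12)
  }
})

test_that("SEN is invariant to amplitude scaling through the whole pipeline", {
  set.seed(8)
  x <- rnorm(3 * 4096)
  pipe_sen <- function(v) {
    v <- notch_50hz(v, 256)
    bands <- split_bands(v, 256)
    lapply(c(low = "low", mid = "mid", high = "high"), function(b) {
      bd <- default_bands(256)
      entropy_series(bands[[b]], 256, bd$f_lo_hz[bd$band == b],
                     bd$f_hi_hz[bd$band == b])$sen
    })
  }
  expect_equal(pipe_sen(x), pipe_sen(137.5 * x), tolerance = 1e-9)
})
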
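window_centers <- function(start_min = -32, end_min = 0, step_min = 16 / 60) {
  n <- floor((end_min - start_min) / step_min)
  start_min + (seq_len(n) - 0.5) * step_min
}

test_that("an exact line is recovered with r = 1", {
  t <- window_centers()
  s <- tibble::tibble(t_min = t, sen = 0.5 + 0.005411 * (t + 32))
  fit <- fit_trend(s)
  expect_equal(fit$slope_per_min, 0.005411, tolerance = 1e-10)
  expect_equal(fit$r, 1, tolerance = 1e-10)
  expect_equal(fit$abs_r, 1, tolerance = 1e-10)
  expect_equal(fit$n_points, 105)
  expect_false(fit$degenerate)
})

test_that("a constant series gives slope 0 and a degenerate-fit flag", {
  s <- tibble::tibble(t_min = window_centers(), sen = 0.7)
  fit <- fit_trend(s)
  expect_equal(fit$slope_per_min, 0)
  expect_equal(fit$r, 0)
  expect_true(fit$degenerate)
})

test_that("noisy-line fit matches closed-form OLS and brackets the truth", {
  set.seed(10)
  t <- window_centers()
  sen <- 0.3 + 0.0002 * t + rnorm(length(t), sd = 0.05)
  fit <- fit_trend(tibble::tibble(t_min = t, sen = sen))
  use <- t >= -32 & t < -4
  tt <- t[use]
  ss <- sen[use]
  slope_oracle <- sum((tt - mean(tt)) * (ss - mean(ss))) /
    sum((tt - mean(tt))^2)
  expect_equal(fit$slope_per_min, slope_oracle, tolerance = 1e-12)
  expect_equal(fit$intercept, mean(ss) - slope_oracle * mean(tt),
               tolerance = 1e-12)
  expect_equal(fit$r, stats::cor(tt, ss), tolerance = 1e-12)
  expect_lte(abs(fit$slope_per_min - 0.0002), 3 * fit$slope_se)
})

test_that("points outside the fit interval are excluded", {
  t <- window_centers()
  s <- tibble::tibble(t_min = t, sen = 0.4 + 0.001 * t)
  spiked <- dplyr::bind_rows(
    s, tibble::tibble(t_min = c(-2, -0.5), sen = c(5, 9)),
    tibble::tibble(t_min = -40, sen = -3))
  expect_equal(fit_trend(spiked)$slope_per_min,
               fit_trend(s)$slope_per_min, tolerance = 1e-12)
  expect_error(
    fit_trend(tibble::tibble(t_min = c(-10, -9), sen = c(0.1, 0.2))),
    "insufficient data")
})

test_that("trend fit is shift-invariant and time-reversal antisymmetric", {
  set.seed(11)
  t <- window_centers()
  sen <- 0.5 + 0.003 * t + rnorm(length(t), sd = 0.02)
  base <- fit_trend(tibble::tibble(t_min = t, sen = sen))
  shifted <- fit_trend(tibble::tibble(t_min = t, sen = sen + 0.123))
  expect_equal(shifted$slope_per_min, base$slope_per_min, tolerance = 1e-12)
  expect_equal(shifted$r, base$r, tolerance = 1e-12)
  mirrored <- fit_trend(tibble::tibble(t_min = -t, sen = sen),
                        interval_min = c(4, 32))
  expect_equal(mirrored$slope_per_min, -base$slope_per_min,
               tolerance = 1e-12)
  expect_equal(mirrored$r, -base$r, tolerance = 1e-12)
})

test_that("fits are computed per band when a band column is present", {
  t <- window_centers()
  s <- dplyr::bind_rows(
    tibble::tibble(band = "low", t_min = t, sen = 0.5 + 1e-4 * (t + 32)),
    tibble::tibble(band = "high", t_min = t, sen = 0.2 + 5e-3 * (t + 32)))
  fit <- fit_trend(s)
  expect_equal(nrow(fit), 2)
  expect_equal(fit$slope_per_min[fit$band == "high"], 5e-3,
               tolerance = 1e-10)
})

test_that("moving average is centered, bounded and edge-shrinking", {
  t <- window_centers()
  const <- moving_average(tibble::tibble(t_min = t, sen = 0.42))
  expect_equal(nrow(const), length(t))
  expect_true(all(const$value == 0.42))

  alt <- moving_average(tibble::tibble(t_min = t,
                                       sen = rep_len(c(0, 1), length(t))))
  interior <- alt$n_used == 15
  expect_true(any(interior))
  # mean of 15 alternating terms is 7/15 or 8/15
  expect_true(all(alt$value[interior] >= 7 / 15 - 1e-12 &
                    alt$value[interior] <= 8 / 15 + 1e-12))
  expect_true(all(alt$n_used >= 8))      # edges keep the one-sided half

  set.seed(12)
  sen <- runif(length(t))
  ma <- moving_average(tibble::tibble(t_min = t, sen = sen))
  expect_true(all(ma$value >= min(sen) & ma$value <= max(sen)))

  empty <- moving_average(tibble::tibble(t_min = numeric(),
                                         sen = numeric()))
  expect_equal(nrow(empty), 0)
  expect_error(
    moving_average(tibble::tibble(t_min = t, sen = sen), window_min = 0.1),
    "exceed the series time step")
})
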
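test_that("text reader recovers channels and auto-detects delimiters", {
  path <- withr::local_tempfile(fileext = ".txt")
  writeLines(c("1 2", "3 4", "5 6"), path)
  rec <- read_eeg_text(path, 256, seizure_onset_s = 0.01)
  expect_s3_class(rec, "eeg_record")
  expect_equal(ncol(rec), 2)
  expect_equal(nrow(rec), 3)
  expect_equal(rec$ch1, c(1, 3, 5))
  expect_equal(rec$ch2, c(2, 4, 6))
  expect_equal(sampling_rate(rec), 256)

  for (d in c(",", "\t")) {
    p2 <- withr::local_tempfile(fileext = ".txt")
    writeLines(c(paste(1:2, collapse = d), paste(3:4, collapse = d)), p2)
    r2 <- read_eeg_text(p2, 100, seizure_onset_s = 0)
    expect_equal(r2$ch2, c(2, 4))
  }
})

test_that("text reader errors name the offending row and column", {
  p <- withr::local_tempfile(fileext = ".txt")
  writeLines("1 x", p)
  expect_error(read_eeg_text(p, 256), "row 1, column 2")
  writeLines(c("1 2", "3"), p)
  expect_error(read_eeg_text(p, 256), "ragged")
  writeLines(character(), p)
  expect_error(read_eeg_text(p, 256), "empty input")
})

test_that("a 50-minute single-channel record has duration 3000 s", {
  rec <- eeg_record(data.frame(ch1 = numeric(768000)), 256,
                    seizure_onset_s = 3000)
  expect_equal(nrow(rec) / sampling_rate(rec), 3000)
  expect_equal(nrow(rec) / sampling_rate(rec) / 60, 50)
})

test_that("text round-trip reproduces samples", {
  set.seed(42)
  rec <- eeg_record(data.frame(ch1 = rnorm(200), ch2 = rnorm(200)), 128,
                    seizure_onset_s = 1)
  p <- withr::local_tempfile(fileext = ".tsv")
  write_eeg_text(rec, p)
  back <- read_eeg_text(p, 128, seizure_onset_s = 1)
  expect_equal(back$ch1, rec$ch1, tolerance = 1e-12)
  expect_equal(back$ch2, rec$ch2, tolerance = 1e-12)
})

test_that("int16 reader decodes interleaved samples and checks sizes", {
  p <- withr::local_tempfile(fileext = ".dat")
  writeBin(c(1L, -1L), p, size = 2, endian = "little")
  rec <- read_eeg_int16(p, 1, 256)
  expect_equal(rec$ch1, c(1, -1))

  writeBin(as.integer(1:6), p, size = 2, endian = "little")
  rec2 <- read_eeg_int16(p, 2, 256)
  expect_equal(nrow(rec2), 3)
  expect_equal(rec2$ch1, c(1, 3, 5))
  expect_equal(rec2$ch2, c(2, 4, 6))

  big <- withr::local_tempfile(fileext = ".dat")
  writeBin(as.integer(c(258, -2)), big, size = 2, endian = "big")
  expect_equal(read_eeg_int16(big, 1, 256, byte_order = "big")$ch1,
               c(258, -2))

  writeBin(as.raw(rep(0, 13)), p)
  expect_error(read_eeg_int16(p, 2, 256), "truncation")
  expect_error(read_eeg_int16(p, 0, 256), "positive integer")
})

test_that("preictal extraction yields the exact half-open window", {
  rec <- make_white_record(768000, 256, seed = 3, onset_s = 3000)
  seg <- extract_preictal(rec, "ch1", 32, 4)
  expect_equal(nrow(seg), 430080)
  expect_equal(seg$t_s[[1]], -1920)
  expect_lt(max(seg$t_s), -240)
  seg_full <- extract_preictal(rec, "ch1", 32, 0)
  expect_equal(nrow(seg_full), 491520)

  short <- make_white_record(20 * 60 * 256, 256, seed = 4,
                             onset_s = 20 * 60)
  expect_error(extract_preictal(short, "ch1", 32, 4),
               "insufficient history")
  expect_error(extract_preictal(rec, "nope", 32, 4), "not found")
})

test_that("extracted duration is exactly (start - end) minutes for any spec", {
  rate <- 64
  rec <- make_white_record(50 * 60 * rate, rate, seed = 5,
                           onset_s = 50 * 60)
  set.seed(99)
  for (i in 1:25) {
    start <- runif(1, 1, 50)
    end <- runif(1, 0, start - 0.5)
    seg <- extract_preictal(rec, 1, start, end)
    expect_equal(nrow(seg), floor((start - end) * 60 * rate))
    expect_equal(seg$t_s[[2]] - seg$t_s[[1]], 1 / rate)
  }
})

test_that("record validation rejects inconsistent metadata", {
  expect_error(eeg_record(data.frame(a = 1:3), -1), "positive")
  expect_error(eeg_record(data.frame(a = 1:3), 256, seizure_onset_s = 10),
               "exceeds the record duration")
  expect_error(eeg_record(data.frame(a = character(1)), 256), "numeric")
})
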
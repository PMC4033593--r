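test_that("trace and marks validation rejects malformed inputs", {
  expect_error(signal_trace(c(1, NA), 250), "finite")
  expect_error(signal_trace(1:10, -1), "fs")
  expect_error(cc_marks(c(1.0, 0.8)), "strictly increasing")
  expect_error(cc_marks(c(-0.5, 1)), "non-negative")
  expect_error(cc_marks(c(0, 0.1, 0.2), validate_rate = TRUE), "intervals")
  expect_silent(cc_marks(c(0, 0.5, 1.0), validate_rate = TRUE))
  ecg <- signal_trace(rnorm(1000), 250)
  expect_error(signal_record(ecg, marks = cc_marks(10)), "time span")
})

test_that("CSV and WFDB round trips preserve the record", {
  set.seed(11)
  n <- 5000
  ecg <- signal_trace(round(rnorm(n, sd = 0.5), 3), 500)
  cd <- signal_trace(round(runif(n, 0, 50), 2), 500)
  rec <- signal_record(ecg, cd, cc_marks(c(0.5, 1.1, 1.6)),
                       rhythm_label = "VF", record_id = "demo")
  csv <- file.path(withr::local_tempdir(), "rec.csv")
  write_record(rec, csv, "csv")
  back <- read_record(csv, "csv", rhythm_label = "VF")
  expect_equal(length(back$ecg$samples), 5000)
  expect_equal(back$ecg$fs, 500)
  expect_equal(back$ecg$samples, rec$ecg$samples, tolerance = 1e-9)
  expect_equal(back$cd$samples, rec$cd$samples, tolerance = 1e-9)
  expect_equal(back$marks$t, rec$marks$t)

  base <- file.path(withr::local_tempdir(), "rec")
  write_record(rec, base, "wfdb")
  back2 <- read_record(paste0(base, ".hea"), "wfdb")
  # format 16 quantizes at the stored gain (1000 units/mV, 100 units/mm)
  expect_equal(back2$ecg$samples, rec$ecg$samples, tolerance = 1e-3)
  expect_equal(back2$cd$samples, rec$cd$samples, tolerance = 1e-2)
  expect_equal(back2$marks$t, rec$marks$t)
})

test_that("read_record rejects files without an ECG channel", {
  tmp <- file.path(withr::local_tempdir(), "bad.csv")
  write.csv(data.frame(time = (0:9) / 250, foo = rnorm(10)), tmp,
            row.names = FALSE)
  expect_error(read_record(tmp, "csv"), "ecg_mv")
})

test_that("resampling halves 500 Hz to 250 Hz and preserves tones", {
  tr <- signal_trace(rnorm(1000), 500)
  out <- resample_to_fs(tr, 250)
  expect_equal(length(out$samples), 500)
  expect_equal(out$fs, 250)
  expect_identical(resample_to_fs(tr, 500)$samples, tr$samples)

  t <- (0:2999) / 500
  x <- sin(2 * pi * 5 * t)
  r <- resample_to_fs(signal_trace(x, 500), 250)
  X <- Mod(fft(r$samples)) / length(r$samples) * 2
  f <- (seq_along(X) - 1) * 250 / length(X)
  pk <- which.max(X[f <= 125])
  expect_equal(f[pk], 5)
  expect_lt(abs(X[pk] - 1), 0.01)
})

test_that("resampling down then up recovers a band-limited signal", {
  set.seed(4)
  fs <- 500
  # band-limited test signal: sum of tones well under 125 Hz
  t <- (0:(4 * fs - 1)) / fs
  x <- rowSums(sapply(c(3, 11, 27, 48), function(f0)
    runif(1, 0.3, 1) * sin(2 * pi * f0 * t + runif(1, 0, 2 * pi))))
  dn <- resample_poly(x, 1, 2)
  up <- resample_poly(dn, 2, 1)
  expect_lt(sqrt(mean((up - x)^2)) / sqrt(mean(x^2)), 0.01)
})

test_that("conditioning band-pass rejects DC and out-of-band tones", {
  fs <- 250
  dc <- signal_trace(rep(1, 10 * fs), fs)
  y <- bandpass_ecg(dc)
  expect_lt(max(abs(y$samples[(2 * fs):(10 * fs)])), 0.01)

  t <- (0:(20 * fs - 1)) / fs
  ss <- function(f0) {
    y <- bandpass_ecg(signal_trace(sin(2 * pi * f0 * t), fs))
    max(abs(y$samples[(10 * fs):(20 * fs)]))
  }
  expect_lt(abs(ss(10) - 1), 0.05)
  expect_lt(ss(50), 0.05)
  expect_error(bandpass_ecg(signal_trace(rnorm(100), 500)), "resample")
})

test_that("band-pass design matches an independent Butterworth reference", {
  sos <- butter_sos(5, c(0.5, 30), "pass", 250)
  bf <- signal::butter(5, c(0.5, 30) / 125, type = "pass")
  f <- c(0.1, 1, 5, 10, 20, 25, 40, 60)
  mine <- Mod(sos_response(sos, f))
  ref <- Mod(signal::freqz(bf$b, bf$a, 2 * pi * f / 250)$h)
  expect_equal(mine, ref, tolerance = 1e-3)
  # half-power points sit at the band edges by construction
  expect_equal(Mod(sos_response(sos, c(0.5, 30))), rep(1 / sqrt(2), 2),
               tolerance = 1e-6)
})

test_that("band-pass filtering is linear", {
  set.seed(5)
  fs <- 250
  a <- rnorm(3 * fs); b <- rnorm(3 * fs)
  ya <- bandpass_ecg(signal_trace(a, fs))$samples
  yb <- bandpass_ecg(signal_trace(b, fs))$samples
  yab <- bandpass_ecg(signal_trace(a + b, fs))$samples
  expect_equal(yab, ya + yb, tolerance = 1e-9)
})

test_that("segment extraction drops the trailing remainder", {
  fs <- 250
  mk <- function(dur) signal_record(signal_trace(rnorm(dur * fs), fs),
                                    rhythm_label = "VF")
  expect_length(extract_segments(mk(20)), 2)
  expect_length(extract_segments(mk(9)), 1)
  expect_length(extract_segments(mk(8.9)), 0)
  segs <- extract_segments(mk(30.5))
  expect_equal(sum(vapply(segs, function(s) length(s$windows), 0)),
               2250 * length(segs))
  expect_lte(2250 * length(segs), 30.5 * fs)
  expect_true(all(vapply(segs, function(s) s$label, "") == "Sh"))
  # windows are contiguous half-open ranges aligned to the record start
  rec <- mk(9)
  segs <- extract_segments(rec)
  expect_equal(as.numeric(segs[[1]]$windows),
               rec$ecg$samples[1:2250])
})
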
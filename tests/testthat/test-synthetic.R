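fs <- 250

test_that("VF generator meets the coarse-VF definition", {
  vf <- gen_rhythm("VF", amplitude = 0.6, rate = 5, duration = 9, seed = 7)
  expect_gt(diff(range(vf$samples)), 0.2)
  X <- Mod(fft(vf$samples))^2
  f <- (seq_along(X) - 1) * fs / length(X)
  half <- f <= fs / 2
  centroid <- sum(f[half] * X[half]) / sum(X[half])
  expect_gte(centroid, 2.5)
  expect_lte(centroid, 7.5)
  expect_identical(vf$samples,
                   gen_rhythm("VF", amplitude = 0.6, rate = 5, duration = 9,
                              seed = 7)$samples)
  expect_error(gen_rhythm("VF", amplitude = 0.1, rate = 5), "0.2 mV")
  expect_error(gen_rhythm("VF", amplitude = 0.5, rate = 9), "2.5")
})

test_that("asystole stays under the amplitude cap in every 2-s span", {
  asy <- gen_rhythm("ASY", amplitude = 0.03, duration = 12, seed = 2)
  for (start in seq(1, 10 * fs, by = fs)) {
    span <- asy$samples[start:(start + 2 * fs - 1)]
    expect_lt(diff(range(span)), 0.1)
  }
  expect_error(gen_rhythm("ASY", amplitude = 0.15), "0.1 mV")
})

test_that("organized rhythm places the requested number of QRS deflections", {
  org <- gen_rhythm("ORG", amplitude = 1.5, rate = 1.33, duration = 9, seed = 5)
  pk <- pracma::findpeaks(abs(org$samples),
                          minpeakheight = 0.35 * max(abs(org$samples)),
                          minpeakdistance = round(0.5 / 1.33 * fs))
  expect_equal(nrow(pk), 12)
  expect_error(gen_rhythm("ORG", amplitude = 1, rate = 4), "0.5, 3.5")
})

test_that("class amplitude invariants hold across many seeds", {
  for (seed in 1:60) {
    vf <- gen_rhythm("VF", amplitude = runif(1, 0.25, 2), rate = runif(1, 2.6, 7.4),
                     duration = 3, seed = seed)
    expect_gt(diff(range(vf$samples)), 0.2)
    asy <- gen_rhythm("ASY", amplitude = runif(1, 0.01, 0.09), duration = 3,
                      seed = seed)
    expect_lt(diff(range(asy$samples)), 0.1)
  }
})

test_that("artifact marks and fundamental follow the requested rate", {
  af <- gen_artifact(rate = 120, rate_jitter = 0, duration = 10, seed = 1)
  expect_length(af$marks$t, 20)
  expect_equal(diff(af$marks$t), rep(0.5, 19), tolerance = 1e-12)
  X <- Mod(fft(af$trace$samples))^2
  f <- (seq_along(X) - 1) * fs / length(X)
  pk <- f[which.max(X[f > 0.5 & f <= fs / 2]) + sum(f <= 0.5)]
  expect_equal(pk, 2.0, tolerance = 0.05)

  z <- gen_artifact(rate = 120, harmonic_amplitudes = rep(0, 5), duration = 10,
                    seed = 1)
  expect_true(all(z$trace$samples == 0))
  expect_gt(length(z$marks$t), 0)
})

test_that("inter-mark jitter realizes the configured coefficient of variation", {
  af <- gen_artifact(rate = 120, rate_jitter = 0.05, duration = 155, seed = 9)
  iv <- diff(af$marks$t)
  expect_gte(length(iv), 299)
  cv <- sd(iv) / mean(iv)
  expect_lt(abs(cv - 0.05), 0.03)
})

test_that("the artifact is reproducible from its stored coefficient paths", {
  af <- gen_artifact(rate = 105, rate_jitter = 0.04, duration = 12, seed = 17)
  rebuilt <- artifact_from_paths(attr(af$trace, "phi"),
                                 attr(af$trace, "amp_paths"),
                                 attr(af$trace, "psi"))
  expect_identical(rebuilt, af$trace$samples)
})

test_that("corpus allocation, SNR and reproducibility contracts hold", {
  corpus <- gen_corpus(10, c(VF = 0.4, ORG = 0.4, ASY = 0.2), snr_db = -5,
                       duration = 9, seed = 1)
  cls <- vapply(corpus, function(r) attr(r, "rhythm_class"), "")
  expect_equal(unname(table(cls)[c("VF", "ORG", "ASY")]),
               as.table(c(4L, 4L, 2L)), ignore_attr = TRUE)
  for (r in corpus) {
    clean <- attr(r, "clean"); art <- attr(r, "artifact")
    snr <- 10 * log10(band_power(clean$samples) / band_power(art$samples))
    expect_lt(abs(snr - (-5)), 0.5)
    expect_identical(clean$samples + art$samples, r$ecg$samples)
    expect_s3_class(r, "signal_record")
  }
  corpus2 <- gen_corpus(10, c(VF = 0.4, ORG = 0.4, ASY = 0.2), snr_db = -5,
                        duration = 9, seed = 1)
  expect_identical(lapply(corpus, function(r) r$ecg$samples),
                   lapply(corpus2, function(r) r$ecg$samples))
})

test_that("compression marks can be re-detected from the depth channel", {
  af <- gen_artifact(rate = 110, duration = 20, seed = 3)
  cd <- gen_cd(af$marks, duration = 20, seed = 4)
  det <- detect_marks_from_cd(cd)
  expect_equal(length(det$t), length(af$marks$t))
  expect_lt(max(abs(det$t - af$marks$t)), 0.05)
})
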
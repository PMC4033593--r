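#' Generate a clean cardiac-arrest rhythm
#'
#' Seedable generators for the three rhythm classes the shock-advice
#' algorithm must separate, all at the analysis rate:
#'
#' * `"VF"` (coarse ventricular fibrillation): Gaussian noise band-pass
#'   filtered to a narrow band around the fibrillation frequency, with slow
#'   sinusoidal amplitude modulation. Coarse VF requires a peak-to-peak
#'   amplitude above 0.2 mV and a fibrillation frequency in 2.5 to 7.5 Hz.
#' * `"ORG"` (organized rhythm): a train of sharp biphasic QRS-like
#'   deflections (~100 ms wide) at the heart rate, over a low-amplitude
#'   smooth baseline. The number of beats is `round(rate * duration)`,
#'   evenly spaced.
#' * `"ASY"` (asystole): low-pass noise kept under the 0.1 mV peak-to-peak
#'   amplitude cap that defines asystole.
#'
#' Traces are rescaled so the peak-to-peak amplitude equals `amplitude`
#' exactly; specifications violating the class definitions (VF at or below
#' 0.2 mV, ASY at or above 0.1 mV, rates out of range) are rejected.
#'
#' @param kind `"VF"`, `"ORG"` or `"ASY"`.
#' @param amplitude peak-to-peak amplitude in mV.
#' @param rate fibrillation frequency in Hz for VF (2.5 to 7.5), heart rate
#'   in Hz for ORG (0.5 to 3.5); ignored for ASY.
#' @param duration length in seconds.
#' @param seed integer seed; equal seeds give identical traces.
#' @param fs sampling rate in Hz.
#' @return A [signal_trace()] in mV.
#' @export
gen_rhythm <- function(kind = c("VF", "ORG", "ASY"), amplitude, rate = NULL,
                       duration = 9, seed = 1, fs = 250) {
  kind <- match.arg(kind)
  stopifnot(amplitude > 0, duration > 0)
  n <- round(duration * fs)
  samples <- withr_seed(seed, {
    switch(kind,
      VF = {
        if (amplitude <= 0.2) stop("coarse VF requires pk-pk amplitude > 0.2 mV")
        if (is.null(rate) || rate < 2.5 || rate > 7.5)
          stop("VF fibrillation frequency must lie in [2.5, 7.5] Hz")
        bw <- min(1.2, rate - 1.3, 0.98 * (fs / 2 - rate))
        sos <- butter_sos(2, c(rate - bw, rate + bw), "pass", fs)
        x <- sos_apply(sos, stats::rnorm(n + 2 * fs), match_dc = FALSE)
        x <- x[2 * fs + seq_len(n)]         # drop filter warm-up
        tt <- (seq_len(n) - 1) / fs
        x * (1 + 0.3 * sin(2 * pi * 0.3 * tt + stats::runif(1, 0, 2 * pi)))
      },
      ORG = {
        if (is.null(rate) || rate < 0.5 || rate > 3.5)
          stop("ORG heart rate must lie in [0.5, 3.5] Hz")
        n_beats <- round(rate * duration)
        beat_t <- (seq_len(n_beats) - 0.5) / rate
        x <- numeric(n)
        # biphasic QRS template: derivative of a Gaussian, ~100 ms support
        sigma <- 0.022
        half_w <- round(0.06 * fs)
        tpl_t <- (-half_w:half_w) / fs
        tpl <- -tpl_t / sigma * exp(0.5 - tpl_t^2 / (2 * sigma^2))
        tpl <- tpl / max(abs(tpl))
        for (bt in beat_t) {
          i0 <- round(bt * fs) + 1L
          idx <- i0 + (-half_w:half_w)
          ok <- idx >= 1 & idx <= n
          x[idx[ok]] <- x[idx[ok]] + tpl[ok]
        }
        # smooth low-amplitude baseline (T-wave-like activity + drift)
        base <- sos_apply(butter_sos(2, 1.5, "low", fs),
                          stats::rnorm(n, sd = 1), match_dc = FALSE)
        x + 0.06 * base / max(abs(base), 1e-12)
      },
      ASY = {
        if (amplitude >= 0.1) stop("asystole requires pk-pk amplitude < 0.1 mV")
        x <- sos_apply(butter_sos(2, 2, "low", fs),
                       stats::rnorm(n + 2 * fs), match_dc = FALSE)
        x[2 * fs + seq_len(n)]
      })
  })
  pkpk <- diff(range(samples))
  signal_trace(samples / pkpk * amplitude, fs = fs)
}

# run code with a local RNG seed, restoring the caller's RNG state
withr_seed <- function(seed, code) {
  old <- if (exists(".Random.seed", globalenv(), inherits = FALSE))
    get(".Random.seed", globalenv()) else NULL
  on.exit({
    if (is.null(old)) suppressWarnings(rm(".Random.seed", envir = globalenv()))
    else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  code
}

#' Generate a chest-compression artifact and its marks
#'
#' Synthesizes the quasiperiodic compression interference exactly by the
#' harmonic forward model: compression marks with jittered inter-compression
#' intervals, a phase accumulated sample by sample from the piecewise
#' constant instantaneous compression frequency, and five harmonics with
#' slowly drifting amplitudes,
#' `s(n) = sum_k c_k(n) cos(k phi(n) + psi_k)`.
#'
#' The realized amplitude paths, harmonic phase offsets and accumulated
#' phase are attached as attributes so that tests can re-run the forward
#' model from the stored paths and check bit-level self-consistency
#' (see [artifact_from_paths()]).
#'
#' @param rate compression rate in compressions per minute (80 to 160).
#' @param rate_jitter fractional standard deviation of the inter-compression
#'   interval (e.g. 0.05 for 5 %).
#' @param harmonic_amplitudes five non-negative harmonic amplitudes in mV.
#' @param amplitude_drift peak fractional amplitude drift rate per second;
#'   each harmonic amplitude follows a slow sinusoid
#'   `c_k(t) = a_k * (1 + e_k * sin(2 pi f_k t + p_k))` whose excursion
#'   `e_k = amplitude_drift / (2 pi f_k)` realizes that drift rate.
#' @param duration length in seconds.
#' @param seed integer seed.
#' @param fs sampling rate in Hz.
#' @return A list with `trace` (a [signal_trace()]) and `marks`
#'   (a [cc_marks()]); the trace carries attributes `amp_paths` (n x 5
#'   matrix), `psi` (harmonic phase offsets) and `phi` (accumulated
#'   fundamental phase).
#' @export
gen_artifact <- function(rate = 116, rate_jitter = 0.03,
                         harmonic_amplitudes = c(0.5, 0.25, 0.12, 0.06, 0.03),
                         amplitude_drift = 0.05, duration = 10, seed = 1,
                         fs = 250) {
  stopifnot(rate >= 30, rate <= 300, rate_jitter >= 0,
            length(harmonic_amplitudes) == 5, all(harmonic_amplitudes >= 0),
            amplitude_drift >= 0, duration > 0)
  n <- round(duration * fs)
  out <- withr_seed(seed, {
    base_iv <- 60 / rate
    t <- 0; tk <- numeric(0)
    while (t < duration) {
      tk <- c(tk, t)
      iv <- base_iv * (1 + rate_jitter * stats::rnorm(1))
      iv <- max(iv, 0.201)
      t <- t + iv
    }
    marks <- cc_marks(tk)
    fo <- instantaneous_frequency(marks, n, fs)
    phi <- rep(NA_real_, n)
    p <- 0
    for (i in which(!is.na(fo))) {
      p <- p + 2 * pi * fo[i] / fs
      phi[i] <- p
    }
    tt <- (seq_len(n) - 1) / fs
    psi <- stats::runif(5, 0, 2 * pi)
    drift_f <- stats::runif(5, 0.05, 0.15)   # Hz, slow
    drift_p <- stats::runif(5, 0, 2 * pi)
    amp <- sapply(seq_len(5), function(k) {
      # sinusoidal modulation whose peak fractional rate of change is
      # amplitude_drift per second: excursion = drift / (2 pi f_drift)
      exc <- amplitude_drift / (2 * pi * drift_f[k])
      harmonic_amplitudes[k] *
        (1 + exc * sin(2 * pi * drift_f[k] * tt + drift_p[k]))
    })
    amp <- matrix(pmax(amp, 0), nrow = n)
    list(marks = marks, phi = phi, psi = psi, amp = amp)
  })
  s <- artifact_from_paths(out$phi, out$amp, out$psi)
  trace <- signal_trace(s, fs = fs)
  attr(trace, "amp_paths") <- out$amp
  attr(trace, "psi") <- out$psi
  attr(trace, "phi") <- out$phi
  list(trace = trace, marks = out$marks)
}

#' Harmonic forward model of the compression artifact
#'
#' Evaluates `s(n) = sum_k amp[n, k] * cos(k * phi[n] + psi[k])`, with zero
#' contribution where `phi` is `NA` (no compressions). This is the exact
#' model [gen_artifact()] synthesizes from, exposed so consumers can verify
#' a generated artifact against its stored coefficient paths.
#'
#' @param phi accumulated fundamental phase per sample (`NA` outside
#'   compressions).
#' @param amp n x 5 matrix of harmonic amplitude paths (mV).
#' @param psi length-5 harmonic phase offsets (radians).
#' @return Numeric vector of artifact samples.
#' @export
artifact_from_paths <- function(phi, amp, psi) {
  stopifnot(ncol(amp) == 5, length(psi) == 5, nrow(amp) == length(phi))
  s <- numeric(length(phi))
  ok <- !is.na(phi)
  for (k in seq_len(5))
    s[ok] <- s[ok] + amp[ok, k] * cos(k * phi[ok] + psi[k])
  s
}

#' Synthesize a compression-depth channel from marks
#'
#' A smoothed pulse train: one raised-cosine compression pulse per mark with
#' peak depths drawn around 36 mm (clipped to 21 to 53 mm), so that
#' mark re-detection from the depth channel can be exercised.
#'
#' @param marks a [cc_marks()] object.
#' @param duration trace length in seconds.
#' @param seed integer seed.
#' @param fs sampling rate in Hz.
#' @return A [signal_trace()] in mm.
#' @export
gen_cd <- function(marks, duration, seed = 1, fs = 250) {
  n <- round(duration * fs)
  withr_seed(seed, {
    x <- numeric(n)
    ivs <- diff(marks$t)
    med_iv <- if (length(ivs)) stats::median(ivs) else 0.5
    w <- round(0.6 * med_iv * fs)           # pulse support
    for (tk in marks$t) {
      depth <- min(max(stats::rnorm(1, 36, 5), 21), 53)
      i0 <- round(tk * fs) + 1L
      idx <- i0 + seq(-w %/% 2, w %/% 2)
      ok <- idx >= 1 & idx <= n
      pulse <- depth * 0.5 * (1 + cos(2 * pi * seq(-w %/% 2, w %/% 2) / w))
      x[idx[ok]] <- pmax(x[idx[ok]], pulse[ok])
    }
    signal_trace(x, fs = fs)
  })
}

#' Re-detect compression marks from a depth channel
#'
#' Peak detection on the compression-depth trace with a 0.2-s refractory
#' period and a minimum depth, mirroring how marks are derived from CPR
#' assist-pad recordings.
#'
#' @param cd compression-depth [signal_trace()] in mm.
#' @param min_depth minimum peak depth in mm.
#' @return A [cc_marks()] object.
#' @export
detect_marks_from_cd <- function(cd, min_depth = 10) {
  stopifnot(inherits(cd, "signal_trace"))
  # zero-pad so compressions at the very edges of the trace still peak
  pk <- pracma::findpeaks(c(0, cd$samples, 0), minpeakheight = min_depth,
                          minpeakdistance = round(0.2 * cd$fs))
  if (is.null(pk)) return(cc_marks())
  cc_marks(sort(cd$start_time + (pk[, 2] - 2) / cd$fs))
}

#' Generate a corpus of artifact-corrupted records with ground truth
#'
#' Each record is a clean rhythm plus a compression artifact scaled to the
#' requested in-band signal-to-noise ratio (power ratio inside the 0.5 to
#' 30 Hz analysis band, the band where the filter and the features operate).
#' Class allocation is deterministic (largest-remainder rounding of
#' `n_records * class_mix`), per-record generator draws are seeded from
#' `seed`, and the clean rhythm component is retained on each record (attr
#' `"clean"`) for oracle evaluation.
#'
#' @param n_records number of records.
#' @param class_mix named proportions for `VF`, `ORG`, `ASY` (sum to 1).
#' @param snr_db clean-rhythm to artifact power ratio in dB inside the
#'   analysis band.
#' @param duration record duration in seconds (>= 9).
#' @param seed integer seed.
#' @param fs sampling rate in Hz.
#' @return A list of [signal_record()]s; each carries attributes `clean`
#'   (the clean rhythm trace), `artifact` (the scaled artifact trace) and
#'   `class` (`"VF"`, `"ORG"` or `"ASY"`).
#' @export
gen_corpus <- function(n_records, class_mix = c(VF = 0.4, ORG = 0.4, ASY = 0.2),
                       snr_db = 0, duration = 27, seed = 1, fs = 250) {
  stopifnot(n_records >= 1, abs(sum(class_mix) - 1) < 1e-9, duration >= 9)
  classes <- c("VF", "ORG", "ASY")
  mix <- class_mix[classes]; mix[is.na(mix)] <- 0
  exact <- n_records * mix
  counts <- floor(exact)
  rem <- n_records - sum(counts)
  if (rem > 0) {
    extra <- order(exact - counts, decreasing = TRUE)[seq_len(rem)]
    counts[extra] <- counts[extra] + 1
  }
  kinds <- rep(classes, counts)
  params <- withr_seed(seed, {
    kinds <- sample(kinds)     # interleave classes across record indices
    data.frame(
      kind = kinds,
      seed_r = sample.int(2^30, n_records),
      seed_a = sample.int(2^30, n_records),
      seed_c = sample.int(2^30, n_records),
      vf_rate = stats::runif(n_records, 3.5, 6.5),
      org_rate = stats::runif(n_records, 0.7, 2.8),
      amp = NA_real_,
      cc_rate = stats::runif(n_records, 88, 156),
      stringsAsFactors = FALSE)
  })
  params$amp <- withr_seed(seed + 1L, ifelse(
    params$kind == "VF", stats::runif(n_records, 0.4, 1.5),
    ifelse(params$kind == "ORG", stats::runif(n_records, 0.5, 2.0),
           stats::runif(n_records, 0.02, 0.08))))

  bp <- .cached_sos("bp_ecg", fs, function() butter_sos(5, c(0.5, 30), "pass", fs))
  lapply(seq_len(n_records), function(i) {
    p <- params[i, ]
    rate <- switch(p$kind, VF = p$vf_rate, ORG = p$org_rate, ASY = NULL)
    clean <- gen_rhythm(p$kind, amplitude = p$amp, rate = rate,
                        duration = duration, seed = p$seed_r, fs = fs)
    art <- gen_artifact(rate = p$cc_rate, duration = duration,
                        seed = p$seed_a, fs = fs)
    p_sig <- mean(sos_apply(bp, clean$samples)^2)
    p_art <- mean(sos_apply(bp, art$trace$samples)^2)
    scale <- if (p_art > 0) sqrt(p_sig / p_art * 10^(-snr_db / 10)) else 0
    art_scaled <- signal_trace(art$trace$samples * scale, fs = fs)
    ecg <- signal_trace(clean$samples + art_scaled$samples, fs = fs)
    cd <- gen_cd(art$marks, duration, seed = p$seed_c, fs = fs)
    label <- switch(p$kind, VF = "VF", ORG = "PEA", ASY = "ASY")
    rec <- signal_record(ecg, cd, art$marks, rhythm_label = label,
                         patient_id = sprintf("p%03d", i),
                         record_id = sprintf("r%03d", i))
    attr(rec, "clean") <- clean
    attr(rec, "artifact") <- art_scaled
    attr(rec, "rhythm_class") <- p$kind
    rec
  })
}
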
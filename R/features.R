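#' Feature extraction configuration
#'
#' Tunable constants for the six per-window discrimination features.
#'
#' @param lea_highpass_cutoff cut-off (Hz) of the order-5 Butterworth
#'   high-pass applied before the low-electrical-activity features.
#' @param slope_window_ms moving-average span (ms) for the squared-slope
#'   envelope; 100 ms is 25 samples at 250 Hz.
#' @param peak_threshold fixed threshold on the max-normalized slope envelope
#'   above which local maxima count as peaks.
#' @param fib_band fibrillation band (Hz), the range where human VF
#'   concentrates its power.
#' @param high_band high spectral band (Hz); the upper edge is the analysis
#'   bandwidth of the conditioning band-pass.
#' @param fft_len zero-padded FFT length for spectral features.
#' @param fs analysis sampling rate (Hz).
#' @return A list of class `feature_config`.
#' @export
feature_config <- function(lea_highpass_cutoff = 2.5, slope_window_ms = 100,
                           peak_threshold = 0.2, fib_band = c(2.5, 7.5),
                           high_band = c(12, 30), fft_len = 1024L, fs = 250) {
  stopifnot(lea_highpass_cutoff > 0, lea_highpass_cutoff < fs / 2,
            slope_window_ms > 0, peak_threshold > 0, peak_threshold < 1,
            length(fib_band) == 2, length(high_band) == 2,
            all(c(fib_band, high_band) > 0), all(c(fib_band, high_band) <= fs / 2),
            fft_len >= 3 * fs)
  structure(list(lea_highpass_cutoff = lea_highpass_cutoff,
                 slope_window_ms = slope_window_ms,
                 peak_threshold = peak_threshold,
                 fib_band = fib_band, high_band = high_band,
                 fft_len = as.integer(fft_len), fs = fs),
            class = "feature_config")
}

.check_window <- function(x, fs) {
  if (length(x) != 3L * fs)
    stop(sprintf("expected a 3-s window of %d samples, got %d", 3L * fs, length(x)))
}

#' High-pass a window for low-electrical-activity analysis
#'
#' Causal order-5 Butterworth high-pass (2.5 Hz cut-off by default) that
#' removes the slow fluctuations typical of low-electrical-activity rhythms
#' while preserving the VF band.
#'
#' @param window numeric vector, one 3-s window of the filtered ECG (mV).
#' @param config a [feature_config()].
#' @return Numeric vector `s_LEA`, same length.
#' @export
highpass_lea <- function(window, config = feature_config()) {
  .check_window(window, config$fs)
  sos <- .cached_sos(paste0("hp_lea", config$lea_highpass_cutoff), config$fs,
                     function() butter_sos(5, config$lea_highpass_cutoff,
                                           "high", config$fs))
  sos_apply(sos, window)
}

#' Energy of the high-passed window
#'
#' `P_LEA = sum(s_LEA^2)` over the 3-s window (mV^2 times samples). Low in
#' asystole and other low-electrical-activity rhythms, large in coarse VF.
#'
#' @param s_lea numeric vector from [highpass_lea()].
#' @param fs sampling rate (window length check only).
#' @return Non-negative scalar.
#' @export
compute_p_lea <- function(s_lea, fs = 250) {
  .check_window(s_lea, fs)
  sum(s_lea^2)
}

#' Minimum subinterval curve length
#'
#' The window is cut into six non-overlapping 0.5-s subintervals; the curve
#' length of each is `L_k = sum(sqrt(diff(s_LEA)^2 + Ts^2))` over its
#' `fs / 2` samples, and the feature is the minimum of the six. A constant
#' subinterval attains the floor `0.5` (each of the 125 terms contributing
#' exactly one sample period), so `L_min >= 0.5` always; it measures the
#' minimum electrical activity seen in any half-second of the window.
#'
#' @param s_lea numeric vector from [highpass_lea()].
#' @param fs sampling rate in Hz.
#' @return Scalar `L_min >= 0.5 * (fs * Ts) = 0.5` (seconds-scaled).
#' @export
compute_l_min <- function(s_lea, fs = 250) {
  .check_window(s_lea, fs)
  ts <- 1 / fs
  half <- fs / 2
  d <- c(0, diff(s_lea))        # first difference; leading term has no
                                # predecessor inside the window and adds Ts
  lk <- vapply(seq_len(6L), function(k) {
    idx <- (k - 1L) * half + seq_len(half)
    sum(sqrt(d[idx]^2 + ts^2))
  }, 0)
  min(lk)
}

#' Slope features: baseline and peak count
#'
#' QRS complexes are enhanced by the moving average of the squared first
#' difference of the window,
#' `d(n) = (1/N) * sum_{k=0}^{N-1} (s(n-k) - s(n-k-1))^2`, with `N` the
#' number of samples in `slope_window_ms` (25 at 250 Hz). The squared-slope
#' series is reflect-padded at the window start so `d` has full length, then
#' divided by its maximum to give `d_bar` in `[0, 1]`. Two features follow:
#'
#' * `bS` (slope baseline): the 10th percentile of `d_bar` (linear
#'   interpolation between order statistics). Organized rhythms concentrate
#'   slope around zero between QRS complexes, giving small `bS`; VF keeps
#'   the slope active throughout, giving large `bS`.
#' * `nP`: the number of strict local maxima of `d_bar` above a fixed
#'   threshold, with a minimum separation of one slope window (100 ms) so
#'   ripple on one deflection is not double-counted. The global maximum
#'   (height 1) always counts, so `nP >= 1` for any non-degenerate window.
#'
#' An identically zero window is degenerate: both features are 0 and the
#' result carries `attr(, "degenerate") = TRUE`.
#'
#' @param window numeric vector, one 3-s window of the filtered ECG.
#' @param config a [feature_config()].
#' @return Named numeric vector `c(bS = , nP = )`.
#' @export
slope_features <- function(window, config = feature_config()) {
  fs <- config$fs
  .check_window(window, fs)
  N <- max(1L, round(config$slope_window_ms / 1000 * fs))
  z <- diff(window)^2                       # squared slope, length 3*fs - 1
  zext <- c(z[pmin(N:1, length(z))], z)     # reflect-pad at the window start
  m <- as.numeric(stats::filter(zext, rep(1 / N, N), sides = 1))
  d <- m[N:(N + 3L * fs - 1L)]              # d[n] = mean of the N squared
                                            # slopes ending at sample n
  mx <- max(d)
  if (mx <= 0) {
    out <- c(bS = 0, nP = 0)
    attr(out, "degenerate") <- TRUE
    return(out)
  }
  dbar <- d / mx
  bS <- unname(stats::quantile(dbar, 0.10, type = 7))
  nP <- .count_slope_peaks(dbar, config$peak_threshold, N)
  # the global maximum is by definition a peak at height 1 even when it sits
  # on the window boundary where no interior local maximum exists
  if (nP == 0L) nP <- 1L
  c(bS = bS, nP = nP)
}

# strict local maxima above `threshold`, thinned greedily (tallest first,
# ties toward the earlier sample) so that no two retained peaks lie within
# `min_dist` samples: one slope window, so ripple on a single deflection is
# never double-counted. All height comparisons use 12 significant digits so
# the peak set does not depend on last-bit rounding of the envelope.
.count_slope_peaks <- function(x, threshold, min_dist) {
  n <- length(x)
  if (n < 3) return(0L)
  x <- signif(x, 12)
  mid <- 2:(n - 1)
  cand <- mid[x[mid] > threshold & x[mid] > x[mid - 1] & x[mid] > x[mid + 1]]
  if (!length(cand)) return(0L)
  cand <- cand[order(-x[cand], cand)]
  taken <- integer(0)
  for (i in cand) {
    if (!length(taken) || all(abs(i - taken) > min_dist))
      taken <- c(taken, i)
  }
  length(taken)
}

#' Spectral features: fibrillation-band and high-band power fractions
#'
#' A Hamming window is applied to the 3-s window and its zero-padded
#' 1024-point FFT computed; the power spectral density over the positive
#' frequencies up to Nyquist is normalized to total power one. Features:
#' `P_fib`, the power fraction in the fibrillation band (2.5 to 7.5 Hz,
#' where human VF concentrates its power) and `P_h`, the fraction in the
#' high band (12 Hz up to the 30 Hz analysis bandwidth, where harmonics of
#' the heart rate of organized rhythms live).
#'
#' A zero window is degenerate: both fractions are 0 with
#' `attr(, "degenerate") = TRUE`.
#'
#' @param window numeric vector, one 3-s window of the filtered ECG.
#' @param config a [feature_config()].
#' @return Named numeric vector `c(P_fib = , P_h = )`.
#' @export
spectral_features <- function(window, config = feature_config()) {
  fs <- config$fs
  .check_window(window, fs)
  if (all(window == 0)) {
    out <- c(P_fib = 0, P_h = 0)
    attr(out, "degenerate") <- TRUE
    return(out)
  }
  nfft <- config$fft_len
  xw <- window * signal::hamming(length(window))
  X <- stats::fft(c(xw, numeric(nfft - length(xw))))
  f <- (seq_len(nfft) - 1) * fs / nfft
  pos <- f > 0 & f <= fs / 2
  psd <- Mod(X[pos])^2
  psd <- psd / sum(psd)
  fpos <- f[pos]
  fib <- fpos >= config$fib_band[1] & fpos <= config$fib_band[2]
  hi <- fpos >= config$high_band[1] & fpos <= config$high_band[2]
  c(P_fib = sum(psd[fib]), P_h = sum(psd[hi]))
}

#' All six discrimination features for one window
#'
#' Convenience wrapper: high-passes the window for the two
#' low-electrical-activity features (`P_LEA`, `L_min`) and computes the four
#' shock/no-shock features (`bS`, `nP`, `P_fib`, `P_h`) on the window
#' itself.
#'
#' @param window numeric vector, one 3-s window of the filtered ECG (mV).
#' @param config a [feature_config()].
#' @return Named numeric vector with components `P_LEA`, `L_min`, `bS`,
#'   `nP`, `P_fib`, `P_h`.
#' @export
window_features <- function(window, config = feature_config()) {
  s_lea <- highpass_lea(window, config)
  sl <- slope_features(window, config)
  sp <- spectral_features(window, config)
  c(P_LEA = compute_p_lea(s_lea, config$fs),
    L_min = compute_l_min(s_lea, config$fs),
    sl, sp)
}
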
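# Independent brute-force oracles: plain loops over the feature and model
# definitions, deliberately sharing no code with the implementation.

oracle_p_lea <- function(s) {
  acc <- 0
  for (v in s) acc <- acc + v * v
  acc
}

oracle_l_min <- function(s, fs = 250) {
  ts <- 1 / fs
  half <- fs / 2
  best <- Inf
  for (k in 0:5) {
    acc <- 0
    for (n in (k * half + 1):((k + 1) * half)) {
      d <- if (n >= 2) s[n] - s[n - 1] else 0
      acc <- acc + sqrt(d * d + ts * ts)
    }
    if (acc < best) best <- acc
  }
  best
}

# squared-slope moving average with reflection about the window start
# (z-index j <= 0 maps to z[1 - j]), then max-normalization
oracle_slope_envelope <- function(s, N = 25) {
  L <- length(s)
  z <- numeric(L - 1)
  for (i in seq_len(L - 1)) z[i] <- (s[i + 1] - s[i])^2
  d <- numeric(L)
  for (n in seq_len(L)) {
    acc <- 0
    for (k in 0:(N - 1)) {
      j <- n - 1 - k
      idx <- if (j >= 1) j else 1 - j
      acc <- acc + z[idx]
    }
    d[n] <- acc / N
  }
  d
}

oracle_slope_features <- function(s, N = 25, threshold = 0.2) {
  d <- oracle_slope_envelope(s, N)
  mx <- max(d)
  if (mx <= 0) return(c(bS = 0, nP = 0))
  db <- d / mx
  bS <- unname(stats::quantile(db, 0.10, type = 7))
  # strict local maxima above threshold, then greedy suppression within N
  # samples, strongest first; all height comparisons at 12 significant
  # digits, ties toward the earlier sample (the package's documented
  # convention, re-derived here by explicit loops)
  db <- signif(db, 12)
  cand <- integer(0)
  for (i in 2:(length(db) - 1)) {
    if (db[i] > threshold && db[i] > db[i - 1] && db[i] > db[i + 1])
      cand <- c(cand, i)
  }
  keep <- logical(length(cand))
  ord <- order(-db[cand], cand)
  taken <- integer(0)
  for (o in ord) {
    if (all(abs(cand[o] - taken) > N)) {
      keep[o] <- TRUE
      taken <- c(taken, cand[o])
    }
  }
  nP <- sum(keep)
  if (nP == 0) nP <- 1
  c(bS = bS, nP = nP)
}

# direct DFT evaluation of the Hamming-windowed zero-padded periodogram
oracle_spectral <- function(s, fs = 250, nfft = 1024,
                            fib = c(2.5, 7.5), hi = c(12, 30)) {
  L <- length(s)
  w <- 0.54 - 0.46 * cos(2 * pi * (0:(L - 1)) / (L - 1))
  xw <- s * w
  bins <- 1:(nfft / 2)                       # positive frequencies to Nyquist
  p <- numeric(length(bins))
  for (b in seq_along(bins)) {
    k <- bins[b]
    p[b] <- Mod(sum(xw * exp(-2i * pi * k * (0:(L - 1)) / nfft)))^2
  }
  p <- p / sum(p)
  f <- bins * fs / nfft
  c(P_fib = sum(p[f >= fib[1] & f <= fib[2]]),
    P_h = sum(p[f >= hi[1] & f <= hi[2]]))
}

# naive double-loop Gaussian-kernel discriminant
oracle_svm_f <- function(sv, coefs, b, gamma, x) {
  acc <- 0
  for (i in seq_len(nrow(sv))) {
    d2 <- 0
    for (j in seq_len(ncol(sv))) d2 <- d2 + (x[j] - sv[i, j])^2
    acc <- acc + coefs[i] * exp(-gamma * d2)
  }
  acc + b
}

# exhaustive pairwise AUC with half credit for ties
oracle_auc <- function(scores, pos) {
  sp <- scores[pos]; sn <- scores[!pos]
  acc <- 0
  for (a in sp) for (b in sn) acc <- acc + (a > b) + 0.5 * (a == b)
  acc / (length(sp) * length(sn))
}

# closed-form least-squares projection onto the 10-dimensional harmonic basis
oracle_harmonic_ls <- function(x, phi) {
  ok <- !is.na(phi)
  B <- sapply(1:5, function(k) cos(k * phi[ok]))
  B <- cbind(B, sapply(1:5, function(k) sin(k * phi[ok])))
  fit <- stats::lm.fit(B, x[ok])
  out <- rep(0, length(x))
  out[ok] <- as.numeric(B %*% fit$coefficients)
  out
}

# shared small fixtures -------------------------------------------------------

# random 3-s windows with varied character (VF-like, ORG-like, noise)
random_windows <- function(n, seed = 1, fs = 250) {
  set.seed(seed)
  lapply(seq_len(n), function(i) {
    kind <- i %% 3
    if (kind == 0) gen_rhythm("VF", amplitude = runif(1, 0.3, 1.5),
                              rate = runif(1, 3, 7), duration = 3,
                              seed = 1000 + i)$samples
    else if (kind == 1) gen_rhythm("ORG", amplitude = runif(1, 0.5, 2),
                                   rate = runif(1, 0.8, 3), duration = 3,
                                   seed = 2000 + i)$samples
    else rnorm(3 * fs, sd = runif(1, 0.05, 0.5))
  })
}

# a small trained shock-advice model, built once per test run
cached_small_model <- local({
  model <- NULL
  function() {
    if (is.null(model)) {
      corpus <- gen_corpus(18, c(VF = 1/3, ORG = 1/3, ASY = 1/3),
                           snr_db = 0, duration = 9, seed = 7)
      feats <- corpus_features(corpus)
      model <<- train_saa(feats,
                          train_config(cost_grid = 2^seq(-1, 3),
                                       gamma_grid = 2^seq(-4, 0), seed = 3))
    }
    model
  }
})

# exact stationary artifact following the harmonic model at constant rate
stationary_artifact <- function(duration = 12, rate_hz = 2, fs = 250,
                                ck = c(0.5, 0.3, 0.2, 0.1, 0.05)) {
  marks <- cc_marks(seq(0, duration - 1 / rate_hz, by = 1 / rate_hz))
  n <- duration * fs
  fo <- instantaneous_frequency(marks, n, fs)
  phi <- rep(NA_real_, n); p <- 0
  for (i in which(!is.na(fo))) {
    p <- p + 2 * pi * fo[i] / fs
    phi[i] <- p
  }
  s <- numeric(n)
  ok <- !is.na(phi)
  for (k in 1:5) s[ok] <- s[ok] + ck[k] * cos(k * phi[ok])
  list(s = s, marks = marks, phi = phi)
}

# in-band SNR helper (0.5-30 Hz)
band_power <- function(x, fs = 250) {
  bp <- butter_sos(5, c(0.5, 30), "pass", fs)
  mean(sos_apply(bp, x)^2)
}
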
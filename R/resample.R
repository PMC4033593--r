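#' Polyphase rational resampling
#'
#' Resamples `x` by the rational factor `p/q` with an FIR anti-alias
#' low-pass (Hamming-windowed, cut at the tighter of the two Nyquist
#' frequencies). The input is reflect-padded so the FIR start-up transient
#' does not bias the ends of the record, and the FIR group delay is
#' compensated exactly, so output sample `m` sits at input time
#' `(m - 1) * q / p` samples.
#'
#' @param x numeric vector.
#' @param p,q positive integers; output rate is `p/q` times the input rate.
#' @return Numeric vector of length `ceiling(length(x) * p / q)`.
#' @export
resample_poly <- function(x, p, q) {
  stopifnot(is.numeric(x), length(x) >= 2, p >= 1, q >= 1,
            p == round(p), q == round(q))
  if (any(!is.finite(x))) stop("non-finite samples in input")
  g <- .gcd(p, q); p <- p / g; q <- q / g
  if (p == 1 && q == 1) return(x)
  L <- length(x)
  M <- max(p, q)
  half <- 10L * M
  h <- signal::fir1(2L * half, 1 / M) * p

  kpad <- ceiling(half / p) + 1L
  idx_front <- pmin(pmax(seq(kpad + 1L, 2L), 1L), L)
  idx_back <- pmin(pmax(seq(L - 1L, L - kpad), 1L), L)
  xp <- c(x[idx_front], x, x[idx_back])

  xu <- numeric(length(xp) * p)
  xu[(seq_along(xp) - 1L) * p + 1L] <- xp
  cv <- .fft_conv(xu, h)

  n_out <- ceiling(L * p / q)
  u <- kpad * p + 1L + (seq_len(n_out) - 1L) * q
  cv[u + half]
}

.gcd <- function(a, b) if (b == 0) a else .gcd(b, a %% b)

.fft_conv <- function(x, h) {
  n <- length(x) + length(h) - 1L
  nf <- stats::nextn(n, 2)
  y <- Re(stats::fft(stats::fft(c(x, numeric(nf - length(x)))) *
                       stats::fft(c(h, numeric(nf - length(h)))), inverse = TRUE)) / nf
  y[seq_len(n)]
}

#' Resample a signal trace to a target rate
#'
#' Rational-factor polyphase resampling of a [signal_trace()]; the 500 to
#' 250 Hz case reduces to exact 2:1 decimation with anti-alias filtering.
#'
#' @param trace a [signal_trace()].
#' @param target_fs target sampling rate in Hz.
#' @return A [signal_trace()] at `target_fs` covering the same time span to
#'   within one sample period.
#' @export
resample_to_fs <- function(trace, target_fs) {
  stopifnot(inherits(trace, "signal_trace"), target_fs > 0)
  if (trace$fs == target_fs) return(trace)
  r <- .rat(target_fs / trace$fs)
  y <- resample_poly(trace$samples, r[1], r[2])
  signal_trace(y, fs = target_fs, start_time = trace$start_time)
}

# small-denominator rational approximation (continued fractions)
.rat <- function(x, tol = 1e-9, max_den = 10000L) {
  a0 <- floor(x)
  p0 <- a0; q0 <- 1; p1 <- 1; q1 <- 0
  frac <- x - a0
  while (abs(p0 / q0 - x) > tol * x && q0 < max_den && frac > 1e-12) {
    r <- 1 / frac
    a <- floor(r)
    frac <- r - a
    tmp_p <- a * p0 + p1; tmp_q <- a * q0 + q1
    p1 <- p0; q1 <- q0; p0 <- tmp_p; q0 <- tmp_q
  }
  c(as.integer(p0), as.integer(q0))
}
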
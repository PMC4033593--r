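#' Butterworth filter design in cascaded second-order sections
#'
#' Designs a causal digital Butterworth filter by bilinear transformation of
#' the analog prototype and returns it factored into second-order sections
#' (biquads). The cascaded form keeps each section's polynomial coefficients
#' well conditioned even when band edges sit very close to DC relative to the
#' sampling rate (e.g. 0.5 Hz at 250 Hz), where a single direct-form
#' polynomial of order 10 starts to lose precision.
#'
#' For `type = "pass"` the prototype order `n` doubles, so `n = 5` yields the
#' order-10 band-pass used for ECG conditioning.
#'
#' @param n prototype order (number of analog prototype poles).
#' @param cutoff cutoff frequency in Hz (scalar for low/high, length-2 for
#'   pass).
#' @param type filter type: `"low"`, `"high"` or `"pass"`.
#' @param fs sampling rate in Hz.
#' @return An object of class `sos_filter`: a list with `sections` (each a
#'   list with numerator `b` and denominator `a`, both length <= 3) and a
#'   scalar `gain` applied once to the input.
#' @seealso [sos_apply()], [sos_response()]
#' @export
butter_sos <- function(n, cutoff, type = c("low", "high", "pass"), fs) {
  type <- match.arg(type)
  stopifnot(n >= 1, fs > 0, all(cutoff > 0), all(cutoff < fs / 2))
  K <- 2 * fs
  warp <- function(f) K * tan(pi * f / fs)
  k <- seq_len(n)
  p_proto <- exp(1i * pi * (2 * k + n - 1) / (2 * n))

  if (type == "low") {
    Wc <- warp(cutoff[1])
    s_poles <- Wc * p_proto
    n_zero_pos <- 0L                      # zeros at z = +1
    n_zero_neg <- n                       # zeros at z = -1 (from s = Inf)
    z_ref <- 1 + 0i
  } else if (type == "high") {
    Wc <- warp(cutoff[1])
    s_poles <- Wc / p_proto
    n_zero_pos <- n
    n_zero_neg <- 0L
    z_ref <- -1 + 0i
  } else {
    stopifnot(length(cutoff) == 2, cutoff[1] < cutoff[2])
    W1 <- warp(cutoff[1]); W2 <- warp(cutoff[2])
    W0 <- sqrt(W1 * W2); B <- W2 - W1
    bp <- 0.5 * B * p_proto
    d <- sqrt(bp^2 - W0^2)
    s_poles <- c(bp + d, bp - d)
    n_zero_pos <- n
    n_zero_neg <- n
    z_ref <- exp(2i * atan(W0 / K))       # geometric centre frequency
  }

  z_poles <- (1 + s_poles / K) / (1 - s_poles / K)

  # group poles into conjugate pairs (plus at most one real pole per pair of
  # real poles); Butterworth poles are simple so tolerance grouping is safe
  ord <- order(-Im(z_poles), Re(z_poles))
  zp <- z_poles[ord]
  upper <- zp[Im(zp) > 1e-9]
  realp <- Re(zp[abs(Im(zp)) <= 1e-9])
  sections <- list()
  for (p in upper) {
    a <- c(1, -2 * Re(p), Mod(p)^2)
    sections[[length(sections) + 1L]] <- list(a = a, poles = 2L)
  }
  while (length(realp) >= 2) {
    a <- c(1, -(realp[1] + realp[2]), realp[1] * realp[2])
    sections[[length(sections) + 1L]] <- list(a = a, poles = 2L)
    realp <- realp[-(1:2)]
  }
  if (length(realp) == 1) {
    sections[[length(sections) + 1L]] <- list(a = c(1, -realp[1]), poles = 1L)
  }

  # distribute zeros at z = +1 / z = -1 over the sections; band-pass biquads
  # get one of each so every section stays balanced
  for (i in seq_along(sections)) {
    np <- sections[[i]]$poles
    if (np == 2L) {
      if (n_zero_pos > 0 && n_zero_neg > 0) {
        b <- c(1, 0, -1); n_zero_pos <- n_zero_pos - 1L; n_zero_neg <- n_zero_neg - 1L
      } else if (n_zero_pos >= 2) {
        b <- c(1, -2, 1); n_zero_pos <- n_zero_pos - 2L
      } else if (n_zero_neg >= 2) {
        b <- c(1, 2, 1); n_zero_neg <- n_zero_neg - 2L
      } else if (n_zero_pos == 1) {
        b <- c(1, -1, 0); n_zero_pos <- 0L
      } else if (n_zero_neg == 1) {
        b <- c(1, 1, 0); n_zero_neg <- 0L
      } else b <- c(1, 0, 0)
    } else {
      if (n_zero_pos > 0) { b <- c(1, -1); n_zero_pos <- n_zero_pos - 1L }
      else if (n_zero_neg > 0) { b <- c(1, 1); n_zero_neg <- n_zero_neg - 1L }
      else b <- c(1, 0)
    }
    sections[[i]]$b <- b
  }

  sos <- structure(list(sections = lapply(sections, function(s) list(b = s$b, a = s$a)),
                        gain = 1, fs = fs, type = type, cutoff = cutoff),
                   class = "sos_filter")
  href <- .sos_eval(sos, z_ref)
  sos$gain <- 1 / Mod(href)
  sos
}

.sos_eval <- function(sos, z) {
  h <- rep(sos$gain + 0i, length(z))
  for (s in sos$sections) {
    num <- rowSums(outer(z, rev(seq_along(s$b)) - 1, `^`) *
                     rep(s$b, each = length(z)))
    den <- rowSums(outer(z, rev(seq_along(s$a)) - 1, `^`) *
                     rep(s$a, each = length(z)))
    h <- h * num / den
  }
  h
}

#' Frequency response of a cascaded filter
#'
#' @param sos an `sos_filter` from [butter_sos()].
#' @param f frequencies in Hz.
#' @return Complex response at each frequency.
#' @export
sos_response <- function(sos, f) {
  .sos_eval(sos, exp(2i * pi * f / sos$fs))
}

#' Apply a cascaded filter causally
#'
#' Runs the biquad cascade as a causal filter. With `match_dc = TRUE`
#' (default) each section's state is initialized to its steady-state response
#' for a constant input equal to the first sample, which removes the step
#' transient a zero initial state would produce at the start of the record.
#' For a filter with a zero at DC this makes the response to a constant input
#' identically (numerically) zero from the first sample.
#'
#' @param sos an `sos_filter`.
#' @param x numeric input vector.
#' @param match_dc initialize states to the DC steady state of `x[1]`.
#' @return Filtered numeric vector, same length as `x`.
#' @export
sos_apply <- function(sos, x, match_dc = TRUE) {
  stopifnot(is.numeric(x))
  y <- x * sos$gain
  v <- if (match_dc && length(y)) y[1] else 0
  for (s in sos$sections) {
    g <- sum(s$b) / sum(s$a)
    nb <- length(s$b); na <- length(s$a)
    if (match_dc) {
      y <- as.numeric(signal::filter(s$b, s$a, y,
                                     init.x = rep(v, nb - 1),
                                     init.y = rep(v * g, na - 1)))
    } else {
      y <- as.numeric(signal::filter(s$b, s$a, y))
    }
    v <- v * g
  }
  y
}
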
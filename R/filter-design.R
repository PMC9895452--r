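# IIR design in zero-pole-gain form, realized as second-order sections.
# Only what the preprocessing chain needs: even-order Butterworth band-pass
# and Chebyshev type II low/high-pass, discretized by the bilinear transform
# with frequency prewarping.

poly_from_roots <- function(r) {
  p <- complex(real = 1)
  for (rt in r) p <- c(p, 0 + 0i) - c(0 + 0i, p * rt)
  p
}

butter_prototype <- function(n) {
  k <- seq_len(n)
  p <- exp(1i * pi * (2 * k + n - 1) / (2 * n))
  list(z = complex(0), p = p, k = 1)
}

cheby2_prototype <- function(n, rs) {
  eps <- 1 / sqrt(10^(rs / 10) - 1)
  mu <- asinh(1 / eps) / n
  theta <- pi * (seq_len(n) * 2 - 1) / (2 * n)
  p1 <- -sinh(mu) * sin(theta) + 1i * cosh(mu) * cos(theta)
  p <- 1 / p1
  ct <- cos(theta)
  z <- 1i / ct[abs(ct) > 1e-12]           # odd order: one zero at infinity
  k <- Re(prod(-p) / prod(-z))
  list(z = z, p = p, k = k)
}

lp2lp_zpk <- function(f, w0) {
  list(z = f$z * w0, p = f$p * w0,
       k = f$k * w0^(length(f$p) - length(f$z)))
}

lp2hp_zpk <- function(f, w0) {
  degree <- length(f$p) - length(f$z)
  z <- w0 / f$z
  p <- w0 / f$p
  k <- f$k * Re(prod(-f$z) / prod(-f$p))
  list(z = c(z, rep(0 + 0i, degree)), p = p, k = k)
}

lp2bp_zpk <- function(f, w0, bw) {
  degree <- length(f$p) - length(f$z)
  zs <- f$z * bw / 2
  ps <- f$p * bw / 2
  z <- c(zs + sqrt(as.complex(zs^2 - w0^2)), zs - sqrt(as.complex(zs^2 - w0^2)))
  p <- c(ps + sqrt(as.complex(ps^2 - w0^2)), ps - sqrt(as.complex(ps^2 - w0^2)))
  list(z = c(z, rep(0 + 0i, degree)), p = p, k = f$k * bw^degree)
}

bilinear_zpk <- function(f, fs) {
  fs2 <- 2 * fs
  degree <- length(f$p) - length(f$z)
  zd <- (fs2 + f$z) / (fs2 - f$z)
  pd <- (fs2 + f$p) / (fs2 - f$p)
  k <- f$k * Re(prod(fs2 - f$z) / prod(fs2 - f$p))
  list(z = c(zd, rep(-1 + 0i, degree)), p = pd, k = k)
}

prewarp <- function(f_hz, fs) 2 * fs * tan(pi * f_hz / fs)

# Pair conjugate pole pairs (closest to the unit circle first) with the
# nearest remaining zero pair. All designs used here have even order with
# poles and zeros in conjugate pairs.
zpk_to_sos <- function(zpk) {
  take_pairs <- function(v) {
    v <- v[order(Im(v))]
    up <- v[Im(v) > 1e-9]
    re <- sort(Re(v[abs(Im(v)) <= 1e-9]))
    if (length(re) %% 2 != 0)
      stop("odd number of real roots; even-order designs expected")
    reps <- c(up, if (length(re)) complex(real = re[seq(1, length(re), 2)]))
    real_mate <- c(rep(NA_real_, length(up)),
                   if (length(re)) re[seq(2, length(re), 2)])
    list(rep = reps, mate = real_mate)
  }
  zz <- take_pairs(zpk$z)
  pp <- take_pairs(zpk$p)
  if (length(zz$rep) != length(pp$rep))
    stop("zero/pole pair count mismatch")
  ord <- order(abs(1 - abs(pp$rep)))
  nsec <- length(pp$rep)
  sos <- matrix(0, nsec, 6)
  used <- rep(FALSE, nsec)
  for (s in seq_len(nsec)) {
    p1 <- pp$rep[ord[s]]
    cand <- which(!used)
    zi <- cand[which.min(abs(zz$rep[cand] - p1))]
    used[zi] <- TRUE
    zpair <- if (is.na(zz$mate[zi])) c(zz$rep[zi], Conj(zz$rep[zi]))
             else c(zz$rep[zi], complex(real = zz$mate[zi]))
    ppair <- if (is.na(pp$mate[ord[s]])) c(p1, Conj(p1))
             else c(p1, complex(real = pp$mate[ord[s]]))
    b <- Re(poly_from_roots(zpair))
    a <- Re(poly_from_roots(ppair))
    sos[s, ] <- c(b, a)
  }
  sos <- sos[rev(seq_len(nsec)), , drop = FALSE]  # least-peaked section first
  sos[nsec, 1:3] <- sos[nsec, 1:3] * zpk$k
  sos
}

#' Design a digital IIR filter as second-order sections
#'
#' Supports the three designs of the spike-band/MUA chain: an even-order
#' Butterworth band-pass and Chebyshev type II low-pass/high-pass filters
#' with a prescribed stopband attenuation.
#'
#' @param type one of `"butter_bandpass"`, `"cheby2_lowpass"`,
#'   `"cheby2_highpass"`.
#' @param order filter order of the analog prototype (total order for the
#'   low/high-pass designs; a band-pass doubles it).
#' @param freq corner frequency in Hz (length 2 for the band-pass).
#' @param fs sampling rate in Hz.
#' @param rs stopband attenuation in dB (Chebyshev II designs only).
#' @return numeric matrix with 6 columns (`b0 b1 b2 a0 a1 a2`), one row per
#'   biquad section, normalized to `a0 = 1`.
#' @export
design_sos <- function(type, order, freq, fs, rs = NULL) {
  stopifnot(order >= 1, fs > 0, all(freq > 0), all(freq < fs / 2))
  zpk <- switch(type,
    butter_bandpass = {
      stopifnot(length(freq) == 2)
      w <- prewarp(freq, fs)
      f <- lp2bp_zpk(butter_prototype(order), sqrt(prod(w)), diff(w))
      bilinear_zpk(f, fs)
    },
    cheby2_lowpass = {
      stopifnot(length(freq) == 1, !is.null(rs))
      bilinear_zpk(lp2lp_zpk(cheby2_prototype(order, rs), prewarp(freq, fs)), fs)
    },
    cheby2_highpass = {
      stopifnot(length(freq) == 1, !is.null(rs))
      bilinear_zpk(lp2hp_zpk(cheby2_prototype(order, rs), prewarp(freq, fs)), fs)
    },
    stop("unknown design type: ", type)
  )
  if (any(abs(zpk$p) >= 1))
    stop("unstable design '", type, "' at fs = ", fs, " Hz")
  sos <- zpk_to_sos(zpk)
  sos[, 1:3] <- sos[, 1:3] / sos[, 4]
  sos[, 4:6] <- sos[, 4:6] / sos[, 4]
  sos
}

#' Frequency response of an SOS cascade
#'
#' @param sos section matrix from [design_sos()].
#' @param f frequencies in Hz at which to evaluate.
#' @param fs sampling rate in Hz.
#' @return complex response at each frequency.
#' @export
sos_freq_response <- function(sos, f, fs) {
  w <- exp(-1i * 2 * pi * f / fs)
  h <- rep(1 + 0i, length(f))
  for (s in seq_len(nrow(sos))) {
    num <- sos[s, 1] + sos[s, 2] * w + sos[s, 3] * w^2
    den <- sos[s, 4] + sos[s, 5] * w + sos[s, 6] * w^2
    h <- h * num / den
  }
  h
}

#' Apply an SOS cascade causally (single pass)
#'
#' @param sos section matrix.
#' @param x numeric vector, or channels-by-time matrix (filtered per row).
#' @return filtered data, same shape as `x`.
#' @export
sos_filter <- function(sos, x) {
  if (is.matrix(x)) {
    out <- x
    for (i in seq_len(nrow(x))) out[i, ] <- cpp_sosfilt(sos, x[i, ])
    out
  } else {
    cpp_sosfilt(sos, x)
  }
}

# Kaiser-windowed sinc low-pass for the polyphase resampler.
kaiser_lowpass <- function(numtaps, cutoff, beta) {
  n <- seq(0, numtaps - 1) - (numtaps - 1) / 2
  h <- cutoff * ifelse(n == 0, 1, sin(pi * cutoff * n) / (pi * cutoff * n))
  m <- (numtaps - 1) / 2
  w <- besselI(beta * sqrt(pmax(0, 1 - (n / m)^2)), 0) / besselI(beta, 0)
  h * w
}

#' Rational polyphase resampling
#'
#' Resamples by the rational factor `L/M` with a Kaiser-windowed sinc
#' anti-aliasing filter, delay-compensated so output sample `m` falls at
#' input time `m*M/(L*rate)`.
#'
#' @param x numeric vector or channels-by-time matrix.
#' @param L,M upsampling and downsampling integer factors.
#' @param half_len_mult filter half-length in multiples of `max(L, M)`.
#' @param beta Kaiser window shape parameter.
#' @return resampled data with `round(n * L / M)` time samples.
#' @export
resample_rational <- function(x, L, M, half_len_mult = 12, beta = 8.0) {
  stopifnot(L >= 1, M >= 1)
  g <- gcd_int(L, M); L <- L / g; M <- M / g
  if (L == 1 && M == 1) return(x)
  half <- half_len_mult * max(L, M)
  h <- L * kaiser_lowpass(2 * half + 1, 1 / max(L, M), beta)
  # normalize each polyphase branch to unit DC gain so constants pass exactly
  for (ph in seq_len(L) - 1) {
    idx <- seq(ph + 1, length(h), by = L)
    s <- sum(h[idx])
    if (abs(s) > 1e-12) h[idx] <- h[idx] / s
  }
  one <- function(v) {
    n_out <- round(length(v) * L / M)
    cpp_resample_fir(v, h, as.integer(L), as.integer(M), n_out, as.integer(half))
  }
  if (is.matrix(x)) t(apply(x, 1, one)) else one(x)
}

gcd_int <- function(a, b) if (b == 0) a else gcd_int(b, a %% b)
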
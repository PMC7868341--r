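# IIR filter design and application.
#
# Self-contained digital filter design (elliptic and Butterworth bandpass
# via analog prototype -> lowpass-to-bandpass transform -> bilinear
# transform). High-order narrowband IIR filters are numerically fragile in
# single transfer-function (b, a) form, so designed filters are stored and
# applied as cascaded second-order sections (SOS). Elliptic prototypes use
# Jacobi elliptic functions evaluated through descending Landen recursions.

# ---- Jacobi elliptic helpers -------------------------------------------

# Descending Landen sequence of moduli k_1, k_2, ... until negligible.
ell_landen <- function(k, tol = .Machine$double.eps) {
  v <- numeric(0)
  while (k > tol && length(v) < 20) {
    k <- (k / (1 + sqrt(1 - k^2)))^2
    v <- c(v, k)
  }
  v
}

# Complete elliptic integral K(k) via the arithmetic-geometric mean.
ell_K <- function(k) {
  if (k >= 1) stop("modulus must be < 1")
  a <- 1; b <- sqrt(1 - k^2)
  while (abs(a - b) > .Machine$double.eps * a) {
    t <- (a + b) / 2
    b <- sqrt(a * b)
    a <- t
  }
  pi / (2 * a)
}

# cd(u*K, k) with argument normalized by the quarter period; u may be complex.
ell_cde <- function(u, k) {
  v <- ell_landen(k)
  w <- cos(u * pi / 2)
  for (n in rev(seq_along(v))) {
    w <- (1 + v[n]) * w / (1 + v[n] * w^2)
  }
  w
}

# sn(u*K, k), normalized argument; u may be complex.
ell_sne <- function(u, k) {
  v <- ell_landen(k)
  w <- sin(u * pi / 2)
  for (n in rev(seq_along(v))) {
    w <- (1 + v[n]) * w / (1 + v[n] * w^2)
  }
  w
}

# Inverse sn, normalized by K: returns u with sn(u*K, k) = w; complex-safe.
ell_asne <- function(w, k) {
  v <- ell_landen(k)
  kp <- k
  for (n in seq_along(v)) {
    w <- 2 * w / ((1 + v[n]) * (1 + sqrt(1 - kp^2 * w^2)))
    kp <- v[n]
  }
  2 / pi * asin(w)
}

# Solve the elliptic degree equation for the modulus k given order N and
# discrimination parameter k1 (exact solution in the complementary plane).
ell_degree <- function(N, k1) {
  k1p <- sqrt(1 - k1^2)
  L <- floor(N / 2)
  u <- (2 * seq_len(L) - 1) / N
  kp <- k1p^N * prod(Re(ell_sne(u, k1p)))^4
  sqrt(1 - kp^2)
}

# ---- Analog prototypes (zero-pole-gain, lowpass, edge at 1 rad/s) ------

# Elliptic lowpass prototype of order n with rp dB passband ripple and
# rs dB stopband attenuation.
ellip_proto <- function(n, rp, rs) {
  eps_p <- sqrt(10^(rp / 10) - 1)
  eps_s <- sqrt(10^(rs / 10) - 1)
  k1 <- eps_p / eps_s
  k <- ell_degree(n, k1)
  L <- floor(n / 2)
  u <- (2 * seq_len(L) - 1) / n

  zeros <- complex(0)
  if (L > 0) {
    zeta <- Re(ell_cde(u, k))
    z <- 1i / (k * zeta)
    zeros <- c(z, Conj(z))
  }
  # v0 is real: inverse sn of a purely imaginary argument is imaginary
  v0 <- Re(-1i * ell_asne(1i / eps_p, k1) / n)
  p <- 1i * ell_cde(u - 1i * v0, k)
  poles <- c(p, Conj(p))
  if (n %% 2 == 1) {
    p0 <- 1i * ell_sne(1i * v0, k)
    poles <- c(poles, complex(real = Re(p0), imaginary = 0))
  }
  h0 <- if (n %% 2 == 0) 10^(-rp / 20) else 1
  gain <- h0 * Re(prod(-poles) / prod(-zeros))
  list(z = zeros, p = poles, k = gain)
}

# Butterworth lowpass prototype.
butter_proto <- function(n) {
  m <- seq_len(n)
  theta <- pi * (2 * m - 1) / (2 * n) + pi / 2
  poles <- complex(modulus = 1, argument = theta)
  list(z = complex(0), p = poles, k = 1)
}

# ---- Transforms ---------------------------------------------------------

# Lowpass (edge 1 rad/s) to bandpass with center w0, bandwidth bw (rad/s).
lp2bp_zpk <- function(zpk, w0, bw) {
  deg <- length(zpk$p) - length(zpk$z)
  map <- function(s) {
    a <- s * bw / 2
    d <- sqrt(a^2 - as.complex(w0^2))
    c(a + d, a - d)
  }
  z <- unlist(lapply(as.complex(zpk$z), map))
  if (is.null(z)) z <- complex(0)
  z <- c(z, rep(0 + 0i, deg))
  p <- unlist(lapply(as.complex(zpk$p), map))
  list(z = z, p = p, k = zpk$k * bw^deg)
}

# Bilinear transform at sampling rate fs (zpk in, digital zpk out).
bilinear_zpk <- function(zpk, fs) {
  fs2 <- 2 * fs
  deg <- length(zpk$p) - length(zpk$z)
  zd <- (fs2 + zpk$z) / (fs2 - zpk$z)
  pd <- (fs2 + zpk$p) / (fs2 - zpk$p)
  kd <- zpk$k * Re(prod(fs2 - zpk$z) / prod(fs2 - zpk$p))
  zd <- c(zd, rep(-1 + 0i, deg))
  list(z = zd, p = pd, k = kd)
}

poly_from_roots <- function(r) {
  p <- 1 + 0i
  for (ri in r) p <- c(p, 0) - c(0, p * ri)
  p
}

# Group roots into conjugate / real pairs. Returns a list of length-2
# complex vectors (a lone real root yields a length-1 element).
conj_pairs <- function(r, tol = 1e-8) {
  re <- sort(Re(r[abs(Im(r)) <= tol]))
  up <- r[Im(r) > tol]
  pairs <- lapply(up, function(z) c(z, Conj(z)))
  i <- 1
  while (i < length(re) + 1) {
    if (i + 1 <= length(re)) {
      pairs <- c(pairs, list(complex(real = re[c(i, i + 1)], imaginary = 0)))
      i <- i + 2
    } else {
      pairs <- c(pairs, list(complex(real = re[i], imaginary = 0)))
      i <- i + 1
    }
  }
  pairs
}

# Convert zero-pole-gain form to second-order sections. Pole pairs closest
# to the unit circle are matched with their nearest zero pairs to keep each
# biquad well conditioned. Returns an L x 6 matrix (b0 b1 b2 a0 a1 a2).
zpk2sos <- function(zpk) {
  zp <- conj_pairs(zpk$z)
  pp <- conj_pairs(zpk$p)
  stopifnot(length(zp) <= length(pp))
  # order pole pairs: closest to unit circle first
  ord <- order(vapply(pp, function(p) min(1 - Mod(p)), numeric(1)))
  pp <- pp[ord]
  sos <- matrix(0, nrow = length(pp), ncol = 6)
  for (i in seq_along(pp)) {
    p <- pp[[i]]
    if (length(zp) > 0) {
      d <- vapply(zp, function(z) min(Mod(z[1] - p[1]), Mod(z[1] - p[length(p)])),
                  numeric(1))
      j <- which.min(d)
      z <- zp[[j]]
      zp <- zp[-j]
    } else {
      z <- complex(0)
    }
    bq <- Re(poly_from_roots(z))
    aq <- Re(poly_from_roots(p))
    sos[i, seq_along(bq)] <- bq
    sos[i, 3 + seq_along(aq)] <- aq
  }
  # distribute the overall gain across sections to keep magnitudes tame
  g <- abs(zpk$k)^(1 / nrow(sos))
  sos[, 1:3] <- sos[, 1:3] * g
  if (zpk$k < 0) sos[1, 1:3] <- -sos[1, 1:3]
  sos
}

#' Design a digital elliptic bandpass filter
#'
#' Designs a stable elliptic (Cauer) IIR bandpass filter by the analog
#' prototype / bilinear transform route. `order` is the order of the final
#' bandpass filter (the lowpass prototype has order `order / 2`), matching
#' the convention in which a "10th order" 8--12 Hz bandpass uses a 5th
#' order prototype. The filter is represented as cascaded second-order
#' sections; a single (b, a) form of this order is numerically unusable
#' for narrow bands.
#'
#' @param order Even bandpass filter order.
#' @param band Numeric length-2, passband edges in Hz.
#' @param fs Sampling rate in Hz.
#' @param rp Passband ripple in dB (default 0.5).
#' @param rs Stopband attenuation in dB (default 50).
#' @return Object of class `iir_filter_design`: list with `sos` (L x 6
#'   matrix of second-order sections), `zpk`, and the design parameters.
#' @export
#' @examples
#' flt <- ellip_bandpass(10, c(8, 12), fs = 1000)
#' abs(sos_freq_response(flt$sos, 10, fs = 1000))
ellip_bandpass <- function(order, band, fs, rp = 0.5, rs = 50) {
  check_band(band, fs)
  if (order %% 2 != 0) stop("bandpass order must be even")
  proto <- ellip_proto(order / 2, rp, rs)
  des <- design_bandpass_from_proto(proto, band, fs)
  des$order <- order; des$band <- band; des$fs <- fs
  des$rp <- rp; des$rs <- rs; des$family <- "ellip"
  class(des) <- "iir_filter_design"
  des
}

#' Design a digital Butterworth bandpass filter
#'
#' @inheritParams ellip_bandpass
#' @return Object of class `iir_filter_design` (see [ellip_bandpass()]).
#' @export
butter_bandpass <- function(order, band, fs) {
  check_band(band, fs)
  if (order %% 2 != 0) stop("bandpass order must be even")
  proto <- butter_proto(order / 2)
  des <- design_bandpass_from_proto(proto, band, fs)
  des$order <- order; des$band <- band; des$fs <- fs
  des$family <- "butter"
  class(des) <- "iir_filter_design"
  des
}

check_band <- function(band, fs) {
  stopifnot(length(band) == 2, band[1] > 0, band[2] > band[1], band[2] < fs / 2)
  invisible(band)
}

design_bandpass_from_proto <- function(proto, band, fs) {
  # pre-warp band edges for the bilinear transform
  w <- 2 * fs * tan(pi * band / fs)
  w0 <- sqrt(w[1] * w[2])
  bw <- w[2] - w[1]
  zpk <- lp2bp_zpk(proto, w0, bw)
  zpkd <- bilinear_zpk(zpk, fs)
  if (any(Mod(zpkd$p) >= 1)) stop("unstable filter design")
  list(sos = zpk2sos(zpkd), zpk = zpkd)
}

#' Filter stability check
#'
#' @param flt An `iir_filter_design` object or an SOS matrix.
#' @return TRUE when all poles lie strictly inside the unit circle.
#' @export
filter_is_stable <- function(flt) {
  sos <- if (is.list(flt)) flt$sos else flt
  for (i in seq_len(nrow(sos))) {
    a <- sos[i, 4:6]
    if (any(Mod(polyroot(rev(a))) >= 1)) return(FALSE)
  }
  TRUE
}

#' Complex frequency response of an SOS filter cascade
#'
#' @param sos L x 6 second-order-section matrix.
#' @param f Frequencies in Hz at which to evaluate.
#' @param fs Sampling rate in Hz.
#' @return Complex response at each frequency.
#' @export
sos_freq_response <- function(sos, f, fs) {
  z1 <- exp(-1i * 2 * pi * f / fs)
  h <- rep(1 + 0i, length(f))
  for (i in seq_len(nrow(sos))) {
    num <- sos[i, 1] + sos[i, 2] * z1 + sos[i, 3] * z1^2
    den <- sos[i, 4] + sos[i, 5] * z1 + sos[i, 6] * z1^2
    h <- h * num / den
  }
  h
}

#' Apply an IIR filter causally (zero initial state)
#'
#' Forward pass only, implemented with the compiled recursions in
#' \code{stats::filter}; accepts an `iir_filter_design`, an SOS matrix, or
#' explicit `b`, `a` vectors via [ba_filter()].
#'
#' @param flt An `iir_filter_design` object or an L x 6 SOS matrix.
#' @param x Numeric signal.
#' @return Filtered signal, same length as `x`.
#' @export
sos_filter <- function(flt, x) {
  sos <- if (is.list(flt)) flt$sos else flt
  for (i in seq_len(nrow(sos))) {
    x <- ba_filter(sos[i, 1:3], sos[i, 4:6], x)
  }
  x
}

#' Apply a single-stage IIR filter given b, a coefficients
#'
#' @param b,a Filter coefficients (`a[1]` must be nonzero).
#' @param x Numeric signal, or a matrix whose columns are filtered
#'   independently.
#' @return Filtered signal, same shape as `x` (zero initial state).
#' @export
ba_filter <- function(b, a, x) {
  b <- b / a[1]; a <- a / a[1]
  nb <- length(b)
  if (is.matrix(x)) {
    xp <- rbind(matrix(0, nb - 1, ncol(x)), x)
    yma <- unclass(stats::filter(xp, b, method = "convolution", sides = 1))
    yma <- yma[-seq_len(nb - 1), , drop = FALSE]
    if (length(a) > 1) {
      y <- unclass(stats::filter(yma, -a[-1], method = "recursive"))
      matrix(as.numeric(y), nrow(x), ncol(x))
    } else {
      matrix(as.numeric(yma), nrow(x), ncol(x))
    }
  } else {
    xp <- c(rep(0, nb - 1), x)
    yma <- stats::filter(xp, b, method = "convolution", sides = 1)
    yma <- as.numeric(yma)[-seq_len(nb - 1)]
    if (length(a) > 1) {
      as.numeric(stats::filter(yma, -a[-1], method = "recursive"))
    } else {
      yma
    }
  }
}

#' Zero-phase (forward-backward) filtering
#'
#' Filters forward and then backward so the net group delay is zero; signal
#' edges are protected with an odd (point-reflected) extension long enough
#' to absorb the transient of narrowband filters.
#'
#' @param flt An `iir_filter_design` object or SOS matrix.
#' @param x Numeric signal.
#' @param padlen Extension length in samples; default
#'   `min(floor((length(x) - 1) / 2), 2000)`.
#' @return Zero-phase filtered signal.
#' @export
sos_filtfilt <- function(flt, x, padlen = NULL) {
  if (is.matrix(x)) {
    n <- nrow(x)
    if (n < 24) stop("signal too short to filter")
    if (is.null(padlen)) padlen <- min(floor((n - 1) / 2), 2000L)
    pre <- 2 * matrix(x[1, ], padlen, ncol(x), byrow = TRUE) -
      x[seq(padlen + 1, 2), , drop = FALSE]
    post <- 2 * matrix(x[n, ], padlen, ncol(x), byrow = TRUE) -
      x[seq(n - 1, n - padlen), , drop = FALSE]
    xe <- rbind(pre, x, post)
    y <- sos_filter(flt, xe)
    y <- y[rev(seq_len(nrow(y))), , drop = FALSE]
    y <- sos_filter(flt, y)
    y <- y[rev(seq_len(nrow(y))), , drop = FALSE]
    y[seq(padlen + 1, padlen + n), , drop = FALSE]
  } else {
    n <- length(x)
    if (n < 24) stop("signal too short to filter")
    if (is.null(padlen)) padlen <- min(floor((n - 1) / 2), 2000L)
    pre <- 2 * x[1] - x[seq(padlen + 1, 2)]
    post <- 2 * x[n] - x[seq(n - 1, n - padlen)]
    xe <- c(pre, x, post)
    y <- sos_filter(flt, xe)
    y <- rev(sos_filter(flt, rev(y)))
    y[seq(padlen + 1, padlen + n)]
  }
}

#' Analytic signal via the FFT
#'
#' @param x Real signal.
#' @return Complex analytic signal (same length).
#' @export
hilbert_analytic <- function(x) {
  n <- length(x)
  X <- stats::fft(x)
  h <- numeric(n)
  if (n %% 2 == 0) {
    h[1] <- 1; h[n / 2 + 1] <- 1
    h[2:(n / 2)] <- 2
  } else {
    h[1] <- 1
    h[2:((n + 1) / 2)] <- 2
  }
  stats::fft(X * h, inverse = TRUE) / n
}

#' Wrap phase to [-pi, pi)
#'
#' @param phi Phase in radians.
#' @return Wrapped phase.
#' @export
wrap_phase <- function(phi) {
  (phi + pi) %% (2 * pi) - pi
}
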
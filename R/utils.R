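## Internal numerical helpers shared across modules.

# Derive a child seed from a base seed; keeps results below .Machine's
# 32-bit integer range so set.seed() never overflows.
childSeed <- function(seed, k) {
  as.integer((as.numeric(seed) * 48271 + k * 1299721) %% 2147483629L)
}

# Construct an EpochSet, filling a default trial/channel table when absent.
newEpochSet <- function(data, times, fs, channels, trials, subject = "S01") {
  methods::new("EpochSet", data = data, times = times, fs = fs,
               channels = channels, trials = trials, subject = subject)
}

# Uniform time axis in ms for a window at sampling rate fs; 0 is a sample.
epochTimeAxis <- function(window, fs) {
  step <- 1000 / fs
  n0 <- round(window[1] / step)
  n1 <- round(window[2] / step)
  seq(n0, n1) * step
}

# Smallest 5-smooth (2^a 3^b 5^c) integer >= n: mixed-radix FFT lengths are
# substantially faster here than the next power of two.
goodFFTLength <- function(n) {
  best <- Inf
  p5 <- 1
  while (p5 < n * 2) {
    p35 <- p5
    while (p35 < n * 2) {
      m <- p35
      while (m < n) m <- m * 2
      if (m < best) best <- m
      p35 <- p35 * 3
    }
    p5 <- p5 * 5
  }
  as.integer(best)
}

# Frequency response H(e^{i w}) of a rational filter at frequencies f (Hz).
filterResponse <- function(b, a, f, fs) {
  w <- 2 * pi * f / fs
  ew <- exp(-1i * outer(w, seq_along(b) - 1))
  num <- drop(ew %*% b)
  ew <- exp(-1i * outer(w, seq_along(a) - 1))
  den <- drop(ew %*% a)
  num / den
}

# Zero-phase filtering of the columns of a matrix (time x traces) by the
# squared magnitude response |H|^2 of one or more rational filters: the
# transfer function a forward-backward pass realizes. Applied in the
# frequency domain (vectorized across traces) with even reflection padding
# to suppress edge transients.
zeroPhaseFilterMatrix <- function(x, coefs, fs, padFactor = 1) {
  x <- as.matrix(x)
  n <- nrow(x)
  npad <- max(16L, min(n - 1L, ceiling(n * padFactor)))
  top <- x[(npad + 1):2, , drop = FALSE]
  bot <- x[(n - 1):(n - npad), , drop = FALSE]
  xp <- rbind(top, x, bot)
  nt <- nrow(xp)
  nfft <- goodFFTLength(nt)
  if (nfft > nt) xp <- rbind(xp, matrix(0, nfft - nt, ncol(xp)))
  fgrid <- (seq_len(nfft) - 1) * fs / nfft
  H2 <- rep(1 + 0i, nfft)
  for (cf in coefs) {
    h <- filterResponse(cf$b, cf$a, fgrid, fs)
    H2 <- H2 * (Mod(h)^2)
  }
  X <- stats::mvfft(xp)
  Y <- X * H2
  y <- Re(stats::mvfft(Y, inverse = TRUE)) / nfft
  y[(npad + 1):(npad + n), , drop = FALSE]
}

# Butterworth band-pass (4th order) + biquad notch (Q) coefficient sets.
designBandpassNotch <- function(band, notch, fs, order = 4, Q = 35) {
  if (band[2] >= fs / 2) stop("band edge at or above Nyquist")
  coefs <- list()
  bp <- signal::butter(order, band / (fs / 2), type = "pass")
  coefs$bandpass <- list(b = bp$b, a = bp$a)
  if (!is.null(notch) && is.finite(notch)) {
    if (notch >= fs / 2) stop("notch frequency at or above Nyquist")
    w0 <- 2 * pi * notch / fs
    alpha <- sin(w0) / (2 * Q)
    b <- c(1, -2 * cos(w0), 1)
    a <- c(1 + alpha, -2 * cos(w0), 1 - alpha)
    coefs$notch <- list(b = b / a[1], a = a / a[1])
  }
  coefs
}

# Ratio of modified Bessel functions I1/I0: mean resultant length of a
# von Mises distribution with concentration kappa.
besselRatioA <- function(kappa) {
  r <- ifelse(kappa > 600,
              1 - 1 / (2 * kappa) - 1 / (8 * kappa^2),
              besselI(kappa, 1, expon.scaled = TRUE) /
                besselI(kappa, 0, expon.scaled = TRUE))
  r[kappa == 0] <- 0
  r
}

# Inverse of besselRatioA: concentration giving target mean resultant
# length r in [0, 1). r >= 0.999 is mapped to a large finite kappa.
plvToKappa <- function(r) {
  vapply(r, function(ri) {
    if (ri <= 0) return(0)
    if (ri >= 0.999) return(2000)
    stats::uniroot(function(k) besselRatioA(k) - ri,
                   lower = 1e-8, upper = 2000, tol = 1e-9)$root
  }, numeric(1))
}

# von Mises sampler (Best & Fisher rejection algorithm), mean 0.
rvonmises <- function(n, kappa) {
  if (kappa <= 1e-8) return(stats::runif(n, -pi, pi))
  if (kappa >= 1e6) return(rep(0, n))
  a <- 1 + sqrt(1 + 4 * kappa^2)
  b <- (a - sqrt(2 * a)) / (2 * kappa)
  r <- (1 + b^2) / (2 * b)
  out <- numeric(n)
  got <- 0L
  while (got < n) {
    m <- n - got
    u1 <- stats::runif(m); u2 <- stats::runif(m); u3 <- stats::runif(m)
    z <- cos(pi * u1)
    f <- (1 + r * z) / (r + z)
    cc <- kappa * (r - f)
    ok <- (cc * (2 - cc) - u2 > 0) | (log(cc / u2) + 1 - cc >= 0)
    k <- sum(ok)
    if (k) {
      out[(got + 1):(got + k)] <- sign(u3[ok] - 0.5) * acos(pmin(1, pmax(-1, f[ok])))
      got <- got + k
    }
  }
  out
}

# Linear interpolation of a per-segment step function with raised-cosine
# ramps of width `ramp` ms at interior boundaries. `breaks` has length
# nseg + 1; `values` length nseg. Returns value at each time in t.
smoothStep <- function(t, breaks, values, ramp = 50) {
  nseg <- length(values)
  y <- values[pmin(nseg, pmax(1, findInterval(t, breaks, all.inside = TRUE)))]
  if (ramp > 0 && nseg > 1) {
    for (i in 2:nseg) {
      b <- breaks[i]
      in_ramp <- t >= (b - ramp / 2) & t <= (b + ramp / 2)
      if (any(in_ramp)) {
        u <- (t[in_ramp] - (b - ramp / 2)) / ramp
        w <- 0.5 - 0.5 * cos(pi * u)
        y[in_ramp] <- (1 - w) * values[i - 1] + w * values[i]
      }
    }
  }
  y
}
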
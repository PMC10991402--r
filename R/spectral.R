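#' Complex Morlet time-frequency decomposition
#'
#' Convolves each trial with complex Morlet wavelets
#' \eqn{w(t) = (\sigma_t \sqrt{\pi})^{-1/2} e^{-t^2/2\sigma_t^2} e^{i 2\pi f t}}
#' with \eqn{\sigma_t = \mathrm{cycles}/(2\pi f)}, unit-energy normalized,
#' on a 1 Hz grid from 4 to 50 Hz by default. Convolution is computed in
#' the frequency domain, vectorized over trials. Samples closer to an epoch
#' edge than the wavelet half-length (3 standard deviations) are flagged
#' invalid in the \code{valid} mask rather than silently returned.
#'
#' @param x trials x time numeric matrix (one channel or ROI series), or a
#'   vector (single trial).
#' @param times sample times, ms.
#' @param fs sampling rate, Hz.
#' @param freqs analysis frequencies, Hz; must stay below Nyquist.
#' @param cycles wavelet cycles.
#' @return a \linkS4class{TFDecomposition}.
#' @examples
#' t <- seq(-1000, 1000)
#' x <- rbind(sin(2 * pi * 20 * t / 1000))
#' tf <- morletTF(x, t, 1000, freqs = 15:25)
#' @export
morletTF <- function(x, times, fs, freqs = 4:50, cycles = 3) {
  if (is.vector(x)) x <- matrix(x, nrow = 1)
  if (any(freqs >= fs / 2)) stop("analysis frequency at or above Nyquist")
  if (any(freqs <= 0)) stop("analysis frequencies must be positive")
  nt <- nrow(x); nT <- ncol(x)
  if (nT != length(times)) stop("x columns must match times")
  dt <- 1 / fs
  sigmas <- cycles / (2 * pi * freqs)
  half <- ceiling(3 * sigmas * fs)             # half-length in samples
  nfft <- goodFFTLength(nT + 2 * max(half))
  X <- stats::mvfft(rbind(t(x), matrix(0, nfft - nT, nt)))  # nfft x trials
  coef <- array(0i, c(nt, length(freqs), nT))
  valid <- matrix(TRUE, length(freqs), nT)
  for (j in seq_along(freqs)) {
    f <- freqs[j]; s <- sigmas[j]; h <- half[j]
    tk <- (seq(-h, h)) * dt
    w <- exp(-tk^2 / (2 * s^2)) * exp(2i * pi * f * tk)
    w <- w / sqrt(sum(Mod(w)^2))               # unit energy
    wk <- complex(real = 0, imaginary = 0) * numeric(nfft)
    # kernel centred at lag 0 (wrap negative lags to the tail)
    wk[1:(h + 1)] <- w[(h + 1):(2 * h + 1)]
    wk[(nfft - h + 1):nfft] <- w[1:h]
    Wf <- stats::fft(wk)
    Y <- stats::mvfft(X * Wf, inverse = TRUE) / nfft
    coef[, j, ] <- t(Y[seq_len(nT), , drop = FALSE])
    if (h >= 1) {
      edge <- min(h, nT)
      valid[j, seq_len(edge)] <- FALSE
      valid[j, seq(nT - edge + 1, nT)] <- FALSE
    }
  }
  methods::new("TFDecomposition", coef = coef, freqs = as.numeric(freqs),
               times = times, valid = valid, cycles = cycles)
}

#' Phase-locking value between two decompositions
#'
#' \deqn{PLV(f,t) = \left| \frac{1}{N}\sum_{n=1}^{N}
#'   e^{i(\phi_a(n,f,t) - \phi_b(n,f,t))} \right|}
#' over trials. 1 indicates perfectly locked phase difference, values near
#' \eqn{\sqrt{\pi}/(2\sqrt{N})} are the finite-sample floor for independent
#' phases. Invariant to any common phase rotation and to a fixed phase
#' offset between the signals.
#'
#' @param tfA,tfB \linkS4class{TFDecomposition}s with identical trials,
#'   frequencies and times.
#' @return list with \code{plv} (frequency x time matrix in [0,1]),
#'   \code{freqs}, \code{times}, and \code{valid} (conjunction of both
#'   masks).
#' @export
plv <- function(tfA, tfB) {
  if (!all(dim(tfA@coef) == dim(tfB@coef)))
    stop("decompositions must share trials, frequencies and times")
  if (dim(tfA@coef)[1] == 0) stop("no trials")
  if (max(abs(tfA@freqs - tfB@freqs)) > 1e-9 ||
      max(abs(tfA@times - tfB@times)) > 1e-9)
    stop("frequency or time axes differ")
  z <- tfA@coef * Conj(tfB@coef)
  m <- Mod(z)
  m[m == 0] <- 1                                # zero coefficient: no phase
  u <- z / m
  pl <- Mod(colMeans(u))                        # over trials -> freq x time
  list(plv = matrix(pl, dim(z)[2], dim(z)[3]),
       freqs = tfA@freqs, times = tfA@times,
       valid = tfA@valid & tfB@valid)
}

# Batched PLV maps between two ROI trial series, split by a trial grouping
# (condition). One FFT pass over all trials of both series per frequency;
# numerically identical to morletTF() + plv() per group, without
# materializing per-trial coefficient arrays.
plvPair <- function(a, b, times, fs, groups, freqs = 4:50, cycles = 3,
                    timeSubset = NULL) {
  stopifnot(all(dim(a) == dim(b)))
  n <- nrow(a); nT <- ncol(a)
  if (any(freqs >= fs / 2)) stop("analysis frequency at or above Nyquist")
  sigmas <- cycles / (2 * pi * freqs)
  half <- ceiling(3 * sigmas * fs)
  nfft <- goodFFTLength(nT + 2 * max(half))
  X <- stats::mvfft(rbind(cbind(t(a), t(b)),
                          matrix(0, nfft - nT, 2 * n)))
  if (is.null(timeSubset)) timeSubset <- seq_len(nT)
  lv <- unique(groups)
  out <- lapply(lv, function(g) matrix(NA_real_, length(freqs), nT))
  names(out) <- lv
  gidx <- lapply(lv, function(g) which(groups == g))
  valid <- matrix(TRUE, length(freqs), nT)
  Wfs <- morletSpectra(nfft, freqs, cycles, fs)
  for (j in seq_along(freqs)) {
    h <- half[j]
    Y <- stats::mvfft(X * Wfs[[j]], inverse = TRUE)[timeSubset, ,
                                                    drop = FALSE] / nfft
    z <- Y[, seq_len(n), drop = FALSE] *
      Conj(Y[, n + seq_len(n), drop = FALSE])
    m <- Mod(z); m[m == 0] <- 1
    u <- z / m
    for (g in seq_along(lv))
      out[[g]][j, timeSubset] <- Mod(rowMeans(u[, gidx[[g]], drop = FALSE]))
    if (h >= 1) {
      edge <- min(h, nT)
      valid[j, seq_len(edge)] <- FALSE
      valid[j, seq(nT - edge + 1, nT)] <- FALSE
    }
  }
  lapply(out, function(p) list(plv = p, freqs = as.numeric(freqs),
                               times = times, valid = valid))
}

# Cached FFT-domain Morlet wavelets (unit energy, centred at lag zero).
morletSpectraCache <- new.env(parent = emptyenv())
morletSpectra <- function(nfft, freqs, cycles, fs) {
  key <- paste(nfft, cycles, fs, paste(range(freqs), collapse = "-"),
               length(freqs), sep = "|")
  hit <- morletSpectraCache[[key]]
  if (!is.null(hit)) return(hit)
  dt <- 1 / fs
  sigmas <- cycles / (2 * pi * freqs)
  half <- ceiling(3 * sigmas * fs)
  out <- lapply(seq_along(freqs), function(j) {
    f <- freqs[j]; s <- sigmas[j]; h <- half[j]
    tk <- (seq(-h, h)) * dt
    w <- exp(-tk^2 / (2 * s^2)) * exp(2i * pi * f * tk)
    w <- w / sqrt(sum(Mod(w)^2))
    wk <- rep(0i, nfft)
    wk[1:(h + 1)] <- w[(h + 1):(2 * h + 1)]
    wk[(nfft - h + 1):nfft] <- w[1:h]
    stats::fft(wk)
  })
  morletSpectraCache[[key]] <- out
  out
}

#' Default frequency bands and task-phase windows
#'
#' Bands: theta 4-7, alpha 8-13, beta 14-30, gamma 31-50 Hz (shared edges
#' assigned to the lower band so no bin is counted twice). Task phases:
#' preparation -850..-350 ms (fixation on screen), cue elaboration
#' -150..-1 ms, TMS perturbation +10..+150 ms (starting after the excised
#' pulse segment), task response +150..+650 ms.
#'
#' @return named list of 2-vectors (Hz or ms).
#' @export
plvBands <- function() {
  list(theta = c(4, 7), alpha = c(8, 13), beta = c(14, 30), gamma = c(31, 50))
}

#' @rdname plvBands
#' @export
taskPhases <- function() {
  list(preparation = c(-850, -350), cue_elaboration = c(-150, -1),
       tms_perturbation = c(10, 150), task_response = c(150, 650))
}

#' Average a PLV map into band x task-phase cells
#'
#' Joint arithmetic mean over the integer frequency bins of each band and
#' the samples of each phase window, excluding edge-invalid (frequency,
#' time) bins.
#'
#' @param plvFT result of \code{plv()}.
#' @param bands named list of frequency ranges, Hz (inclusive).
#' @param phases named list of time windows, ms (inclusive).
#' @return data.frame with columns \code{phase}, \code{band}, \code{plv}.
#' @export
bandPhaseAverage <- function(plvFT, bands = plvBands(), phases = taskPhases()) {
  out <- expand.grid(phase = names(phases), band = names(bands),
                     stringsAsFactors = FALSE)
  out$plv <- NA_real_
  for (r in seq_len(nrow(out))) {
    b <- bands[[out$band[r]]]
    p <- phases[[out$phase[r]]]
    if (p[2] <= p[1]) stop("empty phase window: ", out$phase[r])
    fi <- which(plvFT$freqs >= b[1] & plvFT$freqs <= b[2])
    ti <- which(plvFT$times >= p[1] & plvFT$times <= p[2])
    if (!length(fi) || !length(ti))
      stop("band or window outside the decomposition grid")
    v <- plvFT$valid[fi, ti, drop = FALSE]
    cell <- plvFT$plv[fi, ti, drop = FALSE]
    if (!any(v)) stop("no valid time-frequency bins in ", out$phase[r],
                      " x ", out$band[r])
    out$plv[r] <- mean(cell[v])
  }
  out
}
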
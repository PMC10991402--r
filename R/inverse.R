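#' Build a toy distributed source model
#'
#' Constructs a desk-scale forward model: current sources on a spherical
#' shell under the sensor montage, with a smooth distance-decay gain from
#' each source to each electrode. Two anatomical regions of interest are
#' defined around the hand area of the left primary motor cortex
#' (M1, MNI-like (-31.3, -15.4, 75.8) mm) and the supplementary motor area
#' (SMA, (-10, -2, 77) mm); the ROI centres are always included as grid
#' points and membership is every source within \code{roiRadius} mm.
#'
#' The gain is \eqn{g_{cs} = \exp(-d_{cs}^2 / 2\sigma^2)} (distance in mm)
#' with a small seeded multiplicative perturbation for generic conditioning,
#' and columns scaled to unit maximum so one unit of source current yields
#' on the order of one microvolt at the closest sensor.
#'
#' @param channels sensor montage data.frame (defaults to
#'   \code{standardMontage()}).
#' @param nSources number of sources on the shell (including the two ROI
#'   centres). Kept at or below the channel count so the leadfield has full
#'   column rank.
#' @param shellRadius source shell radius, mm.
#' @param sigma gain decay scale, mm.
#' @param roiRadius ROI membership radius, mm (localization accuracy of the
#'   minimum-norm inverse at this scale is about 1.5-2 cm).
#' @param snr assumed signal-to-noise ratio for inverse regularization.
#' @param seed integer seed for the gain perturbation.
#' @return a \linkS4class{SourceModel} (noise covariance initialized to the
#'   identity; replace via \code{estimateNoiseCov}).
#' @examples
#' mdl <- buildToyModel(nSources = 20, seed = 1)
#' dim(leadfield(mdl))
#' @export
buildToyModel <- function(channels = standardMontage(), nSources = 60,
                          shellRadius = 80, sigma = 18, roiRadius = 15,
                          snr = 3, seed = 1) {
  if (nSources < 2) stop("need at least 2 sources (the two ROI centres)")
  roiCentres <- rbind(M1 = c(-31.3, -15.4, 75.8), SMA = c(-10, -2, 77))
  nGrid <- nSources - 2L
  pos <- roiCentres
  if (nGrid > 0) {
    # Fibonacci spiral on the upper hemisphere: quasi-uniform, deterministic
    k <- seq_len(nGrid)
    ga <- pi * (3 - sqrt(5))
    zfrac <- 0.15 + 0.85 * (k - 0.5) / nGrid   # keep off the equator rim
    th <- ga * k
    r <- sqrt(1 - zfrac^2)
    grid <- cbind(cos(th) * r, sin(th) * r, zfrac) * shellRadius
    pos <- rbind(roiCentres, grid)
  }
  rownames(pos) <- NULL
  epos <- as.matrix(channels[, c("x", "y", "z")])
  d2 <- outer(rowSums(epos^2), rep(1, nrow(pos))) +
    outer(rep(1, nrow(epos)), rowSums(pos^2)) - 2 * epos %*% t(pos)
  d2[d2 < 0] <- 0
  L <- exp(-d2 / (2 * sigma^2))
  # small deterministic gain perturbation (breaks exact symmetries, keeps
  # full rank); a function of geometry and seed only, so channels sharing a
  # position share a leadfield row
  L <- L * (1 + 0.01 * sin(d2 * 0.37 * (1 + (seed %% 97))))
  L <- sweep(L, 2, apply(abs(L), 2, max), "/")
  cd <- sqrt(rowSums(sweep(pos, 2, roiCentres["M1", ])^2))
  roiM1 <- which(cd <= roiRadius)
  cd <- sqrt(rowSums(sweep(pos, 2, roiCentres["SMA", ])^2))
  roiSMA <- setdiff(which(cd <= roiRadius), roiM1)
  methods::new("SourceModel", leadfield = L, positions = pos,
               channels = channels,
               rois = list(M1 = as.integer(roiM1), SMA = as.integer(roiSMA)),
               noiseCov = diag(nrow(L)), snr = snr)
}

#' Estimate sensor noise covariance from a pre-stimulus baseline
#'
#' Empirical channel covariance pooled over trials and over samples of the
#' baseline window (default -850..-350 ms, the interval between fixation
#' onset and fixation offset, before any cue or pulse), with diagonal
#' loading \eqn{\epsilon\,\mathrm{tr}(C)/n_{chan}} for invertibility.
#'
#' @param epochs an \linkS4class{EpochSet}.
#' @param window baseline window, ms.
#' @param eps diagonal loading fraction.
#' @return channels x channels covariance matrix.
#' @export
estimateNoiseCov <- function(epochs, window = c(-850, -350), eps = 0.05) {
  idx <- which(epochs@times >= window[1] & epochs@times <= window[2])
  if (length(idx) < 2) stop("baseline window contains too few samples")
  d <- epochs@data[, , idx, drop = FALSE]
  nch <- dim(d)[2]
  # stack trials x samples as observations
  m <- matrix(aperm(d, c(2, 1, 3)), nrow = nch)
  m <- m - rowMeans(m)
  C <- tcrossprod(m) / (ncol(m) - 1)
  load <- eps * sum(diag(C)) / max(nch, 1)
  if (load <= 0) load <- eps            # degenerate (e.g. all-zero) data
  C + diag(nch) * load
}

#' Minimum-norm inverse kernel
#'
#' Tikhonov-regularized linear inverse
#' \eqn{K = R L^T (L R L^T + \lambda^2 C)^{-1}} with identity source
#' covariance \eqn{R} and \eqn{\lambda^2 =
#' \mathrm{tr}(L L^T) / (\mathrm{tr}(C)\, \mathrm{SNR}^2)}.
#'
#' @param model a \linkS4class{SourceModel}.
#' @param lambda2 optional explicit regularization (overrides the SNR rule;
#'   pass a small value such as 1e-10 for the near-noiseless limit).
#' @return sources x channels kernel matrix.
#' @export
mnKernel <- function(model, lambda2 = NULL) {
  L <- model@leadfield
  C <- model@noiseCov
  G <- tcrossprod(L)
  if (is.null(lambda2)) {
    trC <- sum(diag(C))
    if (trC <= 0) stop("noise covariance has non-positive trace")
    lambda2 <- sum(diag(G)) / (trC * model@snr^2)
  }
  A <- G + lambda2 * C
  Ai <- tryCatch(solve(A), error = function(e)
    stop("singular system matrix L R L^T + lambda^2 C: ", conditionMessage(e)))
  t(L) %*% Ai
}

#' Minimum-norm source estimate
#'
#' Applies the minimum-norm kernel to sensor data. The map is linear:
#' \code{minimumNorm(a*y1 + b*y2)} equals
#' \code{a*minimumNorm(y1) + b*minimumNorm(y2)} up to floating-point
#' rounding.
#'
#' @param data an \linkS4class{EpochSet}, or a channels x time matrix.
#' @param model a \linkS4class{SourceModel}.
#' @param lambda2 optional explicit regularization, see \code{mnKernel}.
#' @return a \linkS4class{SourceEstimate} (for an EpochSet input) or a
#'   sources x time matrix (for a matrix input).
#' @export
minimumNorm <- function(data, model, lambda2 = NULL) {
  K <- mnKernel(model, lambda2)
  if (is.matrix(data)) return(K %*% data)
  d <- data@data
  nt <- dim(d)[1]; ns <- ncol(model@leadfield); nT <- dim(d)[3]
  # channels x (trial*time) in one multiply
  m <- matrix(aperm(d, c(2, 1, 3)), nrow = dim(d)[2])
  est <- K %*% m
  arr <- aperm(array(est, c(ns, nt, nT)), c(2, 1, 3))
  methods::new("SourceEstimate", data = arr, times = data@times, fs = data@fs)
}

#' Region-of-interest time series with sign alignment
#'
#' Summarizes the sources of one ROI into a single per-trial time series.
#' Minimum-norm currents within an ROI can carry arbitrary relative signs;
#' sources are sign-aligned to the ROI's first principal direction (left
#' singular vector of the source x time-by-trial matrix) before averaging,
#' so anti-correlated copies of one waveform reinforce rather than cancel.
#' The overall sign is fixed so the alignment vector has non-negative sum.
#'
#' @param est a \linkS4class{SourceEstimate} or a sources x time matrix.
#' @param model a \linkS4class{SourceModel}.
#' @param roi ROI name (one of \code{names(roiIndices(model))}).
#' @return trials x time matrix (or a single time series for matrix input).
#' @export
roiTimeseries <- function(est, model, roi = "M1") {
  idx <- model@rois[[roi]]
  if (is.null(idx) || !length(idx)) stop("unknown or empty ROI: ", roi)
  if (is.matrix(est)) {
    x <- est[idx, , drop = FALSE]
    s <- roiSigns(x)
    return(drop(colMeans(x * s)))
  }
  d <- est@data[, idx, , drop = FALSE]
  nt <- dim(d)[1]; nT <- dim(d)[3]
  x <- matrix(aperm(d, c(2, 1, 3)), nrow = length(idx))  # src x (trial*time)
  s <- roiSigns(x)
  out <- colMeans(x * s)
  matrix(out, nt, nT)
}

# First principal direction sign vector for a sources x samples matrix.
roiSigns <- function(x) {
  if (nrow(x) == 1) return(1)
  u <- svd(x, nu = 1, nv = 0)$u[, 1]
  if (sum(u) < 0) u <- -u
  s <- sign(u)
  s[s == 0] <- 1
  s
}
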
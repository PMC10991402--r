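## Independent component cleaning of epoched EEG.

# Symmetric fixed-point ICA (tanh contrast) on whitened data.
# X: channels x samples, centered. Returns unmixing W (comps x channels)
# and mixing A (channels x comps) so that X ~ A %*% (W %*% X).
fastIcaCore <- function(X, nComp, maxIter = 200, tol = 1e-6, seed = 1) {
  nch <- nrow(X); ns <- ncol(X)
  mu <- rowMeans(X)
  Xc <- X - mu
  C <- tcrossprod(Xc) / ns
  e <- eigen(C, symmetric = TRUE)
  keep <- seq_len(nComp)
  D <- e$values[keep]
  if (any(D <= 1e-12 * max(D))) stop("data rank below requested components")
  K <- diag(1 / sqrt(D), nComp) %*% t(e$vectors[, keep, drop = FALSE])
  Z <- K %*% Xc
  set.seed(childSeed(seed, 77L))
  W <- matrix(stats::rnorm(nComp * nComp), nComp)
  W <- symDecorrelate(W)
  for (it in seq_len(maxIter)) {
    WZ <- W %*% Z
    G <- tanh(WZ)
    gp <- rowMeans(1 - G^2)
    W1 <- (G %*% t(Z)) / ns - diag(gp, nComp) %*% W
    W1 <- symDecorrelate(W1)
    delta <- max(abs(abs(rowSums(W1 * W)) - 1))
    W <- W1
    if (delta < tol) break
  }
  unmix <- W %*% K                      # comps x channels
  mix <- t(e$vectors[, keep, drop = FALSE] %*% diag(sqrt(D), nComp))
  A <- t(mix) %*% t(W)                  # channels x comps
  list(W = unmix, A = A, center = mu, converged = it < maxIter, iter = it)
}

symDecorrelate <- function(W) {
  s <- svd(W)
  s$u %*% t(s$v)
}

#' Independent component cleaning
#'
#' Decomposes the concatenated epochs into independent components
#' (symmetric fixed-point algorithm, tanh contrast) and zeroes components
#' matched by automatic flag rules before back-projection:
#' \describe{
#'   \item{decay}{variance concentrated in 10-50 ms after the pulse
#'     (residual amplifier recovery / cranial muscle twitch): the
#'     component's variance fraction in that window exceeds the window's
#'     length fraction by \code{decayRatio}.}
#'   \item{ocular}{scalp loading concentrated at frontopolar channels
#'     (ratio rule), or topography correlating above \code{templateCor}
#'     with a supplied blink template.}
#'   \item{muscle}{spectral power fraction above 30 Hz exceeding
#'     \code{musclePowerFrac}.}
#' }
#' On real recordings this matching is done by eye; the automatic rules are
#' a documented, reproducible surrogate.
#'
#' @param epochs an \linkS4class{EpochSet}.
#' @param rules list of thresholds: \code{decayRatio} (default 5),
#'   \code{frontalRatio} (default 3), \code{musclePowerFrac} (default
#'   0.6), \code{templateCor} (default 0.8), and optionally
#'   \code{blinkTemplate} (channel weight vector).
#' @param nComp number of components (default: number of channels).
#' @param flagAll flag every component (mostly for testing back-projection).
#' @param seed seed for the ICA initialization.
#' @return list with \code{epochs} (cleaned), \code{report}
#'   (\code{"PreprocReport"} with removed component indices and reasons),
#'   and \code{decomposition} (unmixing/mixing matrices and component
#'   topographies).
#' @export
icaClean <- function(epochs, rules = list(), nComp = NULL, flagAll = FALSE,
                     seed = 1) {
  defaults <- list(decayRatio = 5, frontalRatio = 3, musclePowerFrac = 0.6,
                   templateCor = 0.8, blinkTemplate = NULL)
  rules <- utils::modifyList(defaults, rules)
  d <- epochs@data
  nt <- dim(d)[1]; nch <- dim(d)[2]; nT <- dim(d)[3]
  if (nt * nT <= nch)
    stop("need more time points than channels for the decomposition")
  X <- matrix(aperm(d, c(2, 1, 3)), nrow = nch)     # chan x (trial*time)
  if (is.null(nComp)) nComp <- nch
  dec <- tryCatch(fastIcaCore(X, nComp, seed = seed), error = function(e) e)
  if (inherits(dec, "error")) {
    warning("IC decomposition failed (", conditionMessage(dec),
            "); data passed through unchanged")
    report <- structure(list(subject = epochs@subject,
                             removedComponents = integer(),
                             reasons = character(),
                             failed = TRUE), class = "PreprocReport")
    return(list(epochs = epochs, report = report, decomposition = NULL))
  }
  S <- dec$W %*% (X - dec$center)                   # comps x samples
  # sample order in X: trial fastest, then time
  sampTimes <- rep(epochs@times, each = nt)
  inWin <- sampTimes >= 10 & sampTimes <= 50
  winFrac <- mean(inWin)
  frontal <- grepl("^(Fp|AF)", epochs@channels$name)
  flagged <- integer(); reasons <- character()
  fs <- epochs@fs
  for (k in seq_len(nrow(S))) {
    sk <- S[k, ]
    topo <- dec$A[, k]
    reason <- NULL
    vFrac <- sum(sk[inWin]^2) / max(sum(sk^2), 1e-300)
    if (winFrac > 0 && vFrac / winFrac > rules$decayRatio)
      reason <- c(reason, "decay")
    if (any(frontal) && any(!frontal)) {
      fr <- mean(abs(topo[frontal])) / max(mean(abs(topo[!frontal])), 1e-300)
      tplOk <- !is.null(rules$blinkTemplate) &&
        abs(stats::cor(topo, rules$blinkTemplate)) > rules$templateCor
      if (fr > rules$frontalRatio || tplOk) reason <- c(reason, "ocular")
    }
    ## high-frequency power fraction from a trial-wise periodogram
    skm <- matrix(sk, nt, nT)
    sp <- Mod(stats::mvfft(t(skm)))^2               # time-freq per trial
    fgrid <- (seq_len(nT) - 1) * fs / nT
    hi <- fgrid > 30 & fgrid <= fs / 2
    lo <- fgrid <= fs / 2
    pf <- sum(sp[hi, ]) / max(sum(sp[lo, ]), 1e-300)
    if (pf > rules$musclePowerFrac) reason <- c(reason, "muscle")
    if (flagAll) reason <- c(reason, "flagAll")
    if (!is.null(reason)) {
      flagged <- c(flagged, k)
      reasons <- c(reasons, paste(reason, collapse = "+"))
    }
  }
  Sclean <- S
  if (length(flagged)) Sclean[flagged, ] <- 0
  Xclean <- dec$A %*% Sclean + dec$center
  out <- epochs
  out@data <- aperm(array(Xclean, c(nch, nt, nT)), c(2, 1, 3))
  report <- structure(list(subject = epochs@subject,
                           removedComponents = flagged,
                           reasons = reasons,
                           converged = dec$converged), class = "PreprocReport")
  list(epochs = out, report = report,
       decomposition = list(W = dec$W, A = dec$A))
}
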
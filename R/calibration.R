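## Numerical calibration of the planted coupling map.
##
## The generator controls the phase-difference distribution between the two
## ROI sources exactly (von Mises concentration, analytic mean resultant
## length). What the analysis chain measures is attenuated and floored:
## the minimum-norm inverse mixes the two sources (spatial crosstalk), the
## baseline-estimated noise covariance is signal-inflated (raising the
## regularization), projected sensor noise perturbs the phases, and the
## finite trial count imposes a Rayleigh floor. The generator therefore
## maps requested coupling targets through the inverse of a measured
## calibration curve, so that the PLV recovered by the default analysis
## chain approximates the requested target. The frozen grid below was
## produced by `calibratePlvMap()` at the default generator settings
## (50 trials per cell, 62-channel montage, toy model defaults).

# plant grid and per-band measured chain-level PLV at those plants
chainPlvCalibration <- list(
  plant = c(0, 0.25, 0.5, 0.75, 1),
  measured = rbind(
    theta = c(0.1902, 0.3633, 0.5273, 0.7238, 0.9143),
    alpha = c(0.1900, 0.3239, 0.5085, 0.6995, 0.9030),
    beta  = c(0.1844, 0.3210, 0.4717, 0.6409, 0.8307),
    gamma = c(0.1765, 0.2945, 0.4157, 0.5666, 0.7209))
)

# Monotone inverse of the calibration curve: requested target -> coupling
# to plant. Targets below the measurement floor map to 0, above the
# ceiling to 1.
plantForTarget <- function(band, target) {
  cal <- chainPlvCalibration
  m <- cal$measured[band, ]
  fn <- stats::splinefun(m, cal$plant, method = "hyman")
  pmin(1, pmax(0, fn(pmin(max(m), pmax(min(m), target)))))
}

#' Measure the chain-level coupling calibration curve
#'
#' Plants a uniform coupling value (all bands, all task phases, both
#' conditions) with the analytic von Mises map, runs the default
#' measurement chain (demeaned epochs, baseline noise covariance,
#' minimum-norm ROI series, Morlet phase-locking, band/phase averaging),
#' and reports the measured PLV per band. The package's frozen
#' calibration grid is the output of this function at the default
#' generator settings; rerun it after changing the forward model, the
#' oscillation amplitudes or the noise levels.
#'
#' @param plants coupling values to plant.
#' @param nTrialsPerCell trials per cell of the session used for the
#'   measurement.
#' @param nChannels montage size.
#' @param seeds one session per seed is averaged per grid point.
#' @param truth baseline \code{groundTruth()}; its coupling fields are
#'   overridden per grid point and calibration is bypassed.
#' @return matrix band x plant of measured PLV.
#' @export
calibratePlvMap <- function(plants = c(0, 0.25, 0.5, 0.75, 1),
                            nTrialsPerCell = 50, nChannels = 62,
                            seeds = 1:2, truth = groundTruth()) {
  out <- matrix(NA_real_, 4, length(plants),
                dimnames = list(rownames(truth$plvDiff), plants))
  zero <- matrix(0, 4, 4, dimnames = dimnames(truth$plvDiff))
  for (j in seq_along(plants)) {
    acc <- 0
    for (sd_ in seeds) {
      tr <- truth
      tr$plvBase <- plants[j]
      tr$plvDiff <- zero
      tr$subjectDiffSd <- 0
      tr$subjectBaseSd <- 0
      tr$plvCalibration <- "none"
      cfg <- sessionConfig(nTrialsPerCell = nTrialsPerCell, fsRaw = 1000,
                           fsOut = 1000, nChannels = nChannels, seed = sd_)
      ses <- generateSession(cfg, tr)
      ep <- demeanEpochs(ses$epochs)
      mdl <- ses$model
      mdl@noiseCov <- estimateNoiseCov(ep)
      K <- mnKernel(mdl)
      tms <- which(trialInfo(ep)$tms)
      d <- ep@data[tms, , , drop = FALSE]
      m <- matrix(aperm(d, c(2, 1, 3)), nrow = dim(d)[2])
      est <- K %*% m
      grp <- trialInfo(ep)$condition[tms]
      sA <- subtractEvoked(roiRows(est, mdl, "SMA", length(tms), dim(d)[3]),
                           grp)
      sB <- subtractEvoked(roiRows(est, mdl, "M1", length(tms), dim(d)[3]),
                           grp)
      pl <- plvPair(sA, sB, ep@times, ep@fs,
                    groups = rep("all", length(tms)))
      bp <- bandPhaseAverage(pl[["all"]])
      acc <- acc + vapply(rownames(out), function(b)
        mean(bp$plv[bp$band == b]), numeric(1))
    }
    out[, j] <- acc / length(seeds)
  }
  out
}

# ROI trial series from a sources x (trial*time) estimate matrix.
roiRows <- function(est, model, roi, ntr, nT) {
  idx <- model@rois[[roi]]
  x <- est[idx, , drop = FALSE]
  if (nrow(x) > 1) {
    s <- roiSigns(x)
    x <- colMeans(x * s)
  }
  matrix(x, ntr, nT)
}
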
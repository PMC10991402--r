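#' @import methods
NULL

#' EpochSet: epoched multichannel EEG with trial metadata
#'
#' Container for segmented EEG around a TMS pulse (or the equivalent
#' no-stimulation marker). Data are stored trial x channel x time in
#' microvolts; the time axis is in milliseconds with 0 at the pulse.
#'
#' @slot data numeric array, trial x channel x time (uV).
#' @slot times numeric vector of sample times (ms), strictly increasing and
#'   uniformly spaced at 1000/fs.
#' @slot fs sampling rate in Hz.
#' @slot channels data.frame with columns \code{name}, \code{x}, \code{y},
#'   \code{z} (montage positions, mm).
#' @slot trials data.frame of per-trial metadata; must contain columns
#'   \code{condition} ("Go"/"NoGo") and \code{tms} (logical). Behavioural
#'   columns \code{rt}, \code{fa}, \code{miss} are added by the generator.
#' @slot subject subject identifier (length-1 character).
#'
#' @export
setClass("EpochSet",
  representation(
    data = "array",
    times = "numeric",
    fs = "numeric",
    channels = "data.frame",
    trials = "data.frame",
    subject = "character"
  )
)

setValidity("EpochSet", function(object) {
  msg <- character()
  d <- dim(object@data)
  if (length(d) != 3L)
    msg <- c(msg, "data must be a 3-d array (trial x channel x time)")
  else {
    if (d[2] != nrow(object@channels))
      msg <- c(msg, "channel dimension does not match channel table")
    if (d[3] != length(object@times))
      msg <- c(msg, "time dimension does not match times vector")
    if (d[1] != nrow(object@trials))
      msg <- c(msg, "trial dimension does not match trial table")
  }
  if (length(object@times) > 1) {
    dt <- diff(object@times)
    if (any(dt <= 0)) msg <- c(msg, "times must be strictly increasing")
    step <- 1000 / object@fs
    if (max(abs(dt - step)) > 1e-6 * step)
      msg <- c(msg, "times must be uniform at 1000/fs ms")
  }
  if (!all(c("name", "x", "y", "z") %in% names(object@channels)))
    msg <- c(msg, "channels must have columns name, x, y, z")
  if (!all(c("condition", "tms") %in% names(object@trials)))
    msg <- c(msg, "trials must have columns condition and tms")
  if (length(msg)) msg else TRUE
})

#' SourceModel: toy distributed forward model
#'
#' A smooth distance-decay leadfield from a shell of current sources to the
#' sensor montage, with region-of-interest (ROI) index sets for the primary
#' motor cortex (M1) and the supplementary motor area (SMA), a sensor noise
#' covariance and the regularization signal-to-noise ratio used by the
#' minimum-norm inverse.
#'
#' @slot leadfield channels x sources gain matrix.
#' @slot positions sources x 3 matrix of source positions (mm, MNI-like).
#' @slot channels data.frame of sensor montage (name, x, y, z).
#' @slot rois named list of integer vectors indexing sources (e.g. M1, SMA).
#' @slot noiseCov channels x channels symmetric positive semi-definite matrix.
#' @slot snr assumed amplitude signal-to-noise ratio for regularization.
#'
#' @export
setClass("SourceModel",
  representation(
    leadfield = "matrix",
    positions = "matrix",
    channels = "data.frame",
    rois = "list",
    noiseCov = "matrix",
    snr = "numeric"
  )
)

setValidity("SourceModel", function(object) {
  msg <- character()
  if (nrow(object@leadfield) != nrow(object@channels))
    msg <- c(msg, "leadfield rows must match channels")
  if (ncol(object@leadfield) != nrow(object@positions))
    msg <- c(msg, "leadfield columns must match source positions")
  if (nrow(object@noiseCov) != nrow(object@leadfield) ||
      ncol(object@noiseCov) != nrow(object@leadfield))
    msg <- c(msg, "noise covariance must be channels x channels")
  if (max(abs(object@noiseCov - t(object@noiseCov))) > 1e-8)
    msg <- c(msg, "noise covariance must be symmetric")
  idx <- unlist(object@rois)
  if (length(idx) && (any(idx < 1) || any(idx > ncol(object@leadfield))))
    msg <- c(msg, "ROI indices out of range")
  if (length(object@rois) >= 2 &&
      length(intersect(object@rois[[1]], object@rois[[2]])))
    msg <- c(msg, "ROI index sets must be disjoint")
  if (object@snr <= 0) msg <- c(msg, "snr must be positive")
  if (length(msg)) msg else TRUE
})

#' SourceEstimate: distributed current estimates
#'
#' @slot data numeric array, trial x source x time (arbitrary current units).
#' @slot times numeric vector (ms).
#' @slot fs sampling rate (Hz).
#'
#' @export
setClass("SourceEstimate",
  representation(data = "array", times = "numeric", fs = "numeric")
)

setValidity("SourceEstimate", function(object) {
  d <- dim(object@data)
  if (length(d) != 3L) return("data must be trial x source x time")
  if (d[3] != length(object@times)) return("time dimension mismatch")
  TRUE
})

#' TFDecomposition: complex Morlet time-frequency coefficients
#'
#' @slot coef complex array, trial x frequency x time.
#' @slot freqs analysis frequencies (Hz).
#' @slot times sample times (ms).
#' @slot valid logical matrix frequency x time; FALSE where the wavelet
#'   support extends past the epoch edge.
#' @slot cycles wavelet cycles (time/frequency trade-off).
#'
#' @export
setClass("TFDecomposition",
  representation(
    coef = "array",
    freqs = "numeric",
    times = "numeric",
    valid = "matrix",
    cycles = "numeric"
  )
)

setValidity("TFDecomposition", function(object) {
  d <- dim(object@coef)
  if (length(d) != 3L) return("coef must be trial x frequency x time")
  if (d[2] != length(object@freqs)) return("frequency dimension mismatch")
  if (d[3] != length(object@times)) return("time dimension mismatch")
  if (!all(dim(object@valid) == d[2:3])) return("valid mask dimension mismatch")
  TRUE
})

#' EvokedSet: averaged task-evoked and TMS-evoked responses
#'
#' Holds, per condition, the average of TMS trials (TERP: superposition of
#' the task event-related response and the TMS-evoked response), the average
#' of no-TMS trials (ERP), and their pointwise difference (TEP), plus the
#' extracted peak table.
#'
#' @slot terp named list (condition) of channel x time matrices (uV).
#' @slot erp named list (condition) of channel x time matrices (uV).
#' @slot tep named list (condition) of channel x time matrices (uV).
#' @slot times time axis (ms).
#' @slot channels montage data.frame.
#' @slot peaks data.frame of extracted peaks (component, condition, cluster,
#'   amplitude, latency).
#'
#' @export
setClass("EvokedSet",
  representation(
    terp = "list",
    erp = "list",
    tep = "list",
    times = "numeric",
    channels = "data.frame",
    peaks = "data.frame"
  )
)

setValidity("EvokedSet", function(object) {
  for (cond in names(object@tep)) {
    if (!cond %in% names(object@terp) || !cond %in% names(object@erp))
      return("tep conditions must exist in terp and erp")
    if (max(abs(object@tep[[cond]] -
                (object@terp[[cond]] - object@erp[[cond]]))) > 1e-8)
      return("tep must equal terp - erp pointwise")
  }
  TRUE
})
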
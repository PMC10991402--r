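#' @include AllClasses.R
NULL

#' Accessors for EpochSet and friends
#'
#' Small accessor generics in the Bioconductor style: user code should reach
#' data through these rather than through slots.
#'
#' @param x an object.
#' @param ... passed to methods.
#' @return the requested component.
#' @name accessors
NULL

#' @rdname accessors
#' @export
setGeneric("epochData", function(x, ...) standardGeneric("epochData"))

#' @rdname accessors
#' @export
setGeneric("epochTimes", function(x, ...) standardGeneric("epochTimes"))

#' @rdname accessors
#' @export
setGeneric("samplingRate", function(x, ...) standardGeneric("samplingRate"))

#' @rdname accessors
#' @export
setGeneric("channelInfo", function(x, ...) standardGeneric("channelInfo"))

#' @rdname accessors
#' @export
setGeneric("trialInfo", function(x, ...) standardGeneric("trialInfo"))

#' @rdname accessors
#' @export
setGeneric("nTrials", function(x, ...) standardGeneric("nTrials"))

#' @rdname accessors
#' @export
setGeneric("nChannels", function(x, ...) standardGeneric("nChannels"))

#' @rdname accessors
#' @export
setGeneric("leadfield", function(x, ...) standardGeneric("leadfield"))

#' @rdname accessors
#' @export
setGeneric("roiIndices", function(x, ...) standardGeneric("roiIndices"))

#' @rdname accessors
#' @export
setGeneric("peakTable", function(x, ...) standardGeneric("peakTable"))

#' @rdname accessors
#' @export
setMethod("epochData", "EpochSet", function(x, ...) x@data)

#' @rdname accessors
#' @export
setMethod("epochTimes", "EpochSet", function(x, ...) x@times)

#' @rdname accessors
#' @export
setMethod("samplingRate", "EpochSet", function(x, ...) x@fs)

#' @rdname accessors
#' @export
setMethod("channelInfo", "EpochSet", function(x, ...) x@channels)

#' @rdname accessors
#' @export
setMethod("trialInfo", "EpochSet", function(x, ...) x@trials)

#' @rdname accessors
#' @export
setMethod("nTrials", "EpochSet", function(x, ...) dim(x@data)[1])

#' @rdname accessors
#' @export
setMethod("nChannels", "EpochSet", function(x, ...) dim(x@data)[2])

#' @rdname accessors
#' @export
setMethod("epochTimes", "TFDecomposition", function(x, ...) x@times)

#' @rdname accessors
#' @export
setMethod("epochTimes", "SourceEstimate", function(x, ...) x@times)

#' @rdname accessors
#' @export
setMethod("leadfield", "SourceModel", function(x, ...) x@leadfield)

#' @rdname accessors
#' @export
setMethod("channelInfo", "SourceModel", function(x, ...) x@channels)

#' @rdname accessors
#' @export
setMethod("roiIndices", "SourceModel", function(x, ...) x@rois)

#' @rdname accessors
#' @export
setMethod("peakTable", "EvokedSet", function(x, ...) x@peaks)

setMethod("show", "EpochSet", function(object) {
  d <- dim(object@data)
  cat("EpochSet:", d[1], "trials x", d[2], "channels x", d[3], "samples\n")
  cat("  subject:", object@subject,
      " fs:", object@fs, "Hz  window:",
      object@times[1], "..", object@times[length(object@times)], "ms\n")
  tb <- table(object@trials$condition, ifelse(object@trials$tms, "TMS", "noTMS"))
  print(tb)
  invisible(object)
})

setMethod("show", "SourceModel", function(object) {
  cat("SourceModel:", nrow(object@leadfield), "channels x",
      ncol(object@leadfield), "sources\n")
  cat("  ROIs:", paste(sprintf("%s(%d)", names(object@rois),
                               lengths(object@rois)), collapse = ", "),
      " snr:", object@snr, "\n")
  invisible(object)
})

setMethod("show", "TFDecomposition", function(object) {
  d <- dim(object@coef)
  cat("TFDecomposition:", d[1], "trials x", d[2], "frequencies x",
      d[3], "samples (cycles =", object@cycles, ")\n")
  cat("  freqs:", min(object@freqs), "..", max(object@freqs), "Hz\n")
  invisible(object)
})

setMethod("show", "EvokedSet", function(object) {
  cat("EvokedSet: conditions", paste(names(object@tep), collapse = ", "), "\n")
  if (nrow(object@peaks)) {
    cat("  peaks:\n")
    print(object@peaks, row.names = FALSE)
  }
  invisible(object)
})
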
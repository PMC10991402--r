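#' Average evoked response for a condition
#'
#' Arithmetic mean over the selected trials, per channel and time point.
#'
#' @param epochs an \linkS4class{EpochSet}.
#' @param condition "Go" or "NoGo" (NULL: both).
#' @param tms logical: average TMS trials (TRUE) or no-TMS trials (FALSE);
#'   NULL averages both.
#' @return channels x time matrix (uV).
#' @export
averageEvoked <- function(epochs, condition = NULL, tms = NULL) {
  tr <- trialInfo(epochs)
  sel <- rep(TRUE, nrow(tr))
  if (!is.null(condition)) sel <- sel & tr$condition == condition
  if (!is.null(tms)) sel <- sel & tr$tms == tms
  if (!any(sel)) stop("no trials match the selection")
  d <- epochs@data[sel, , , drop = FALSE]
  colMeans(d, dims = 1)
}

#' Isolate the TMS-evoked response by subtraction
#'
#' The average of TMS trials (TERP) superimposes the task event-related
#' response and the TMS-evoked response; subtracting the no-TMS average
#' (ERP) of the same condition isolates the pure TMS-evoked potential
#' (TEP), exactly so when the two responses compose additively.
#'
#' @param terp,erp channels x time matrices with matching shape.
#' @return channels x time TEP matrix.
#' @export
isolateTep <- function(terp, erp) {
  if (!all(dim(terp) == dim(erp))) stop("terp and erp shapes differ")
  terp - erp
}

#' Build an EvokedSet from epochs
#'
#' Computes per-condition TERP (TMS trials), ERP (no-TMS trials) and TEP =
#' TERP - ERP, then extracts TEP and ERP peaks on the requested channel
#' clusters.
#'
#' @param epochs an \linkS4class{EpochSet} (after preprocessing).
#' @param tepCluster,erpCluster channel-name vectors for the
#'   cluster-averaged extraction traces.
#' @return an \linkS4class{EvokedSet}.
#' @export
evokedSet <- function(epochs, tepCluster = c("Fz", "FCz", "FC1", "C1", "C3"),
                      erpCluster = c("AFz", "Fz", "F1", "F2", "FCz", "FC1",
                                     "FC2", "Cz")) {
  conds <- sort(unique(trialInfo(epochs)$condition))
  terp <- lapply(conds, function(cc) averageEvoked(epochs, cc, tms = TRUE))
  erp <- lapply(conds, function(cc) averageEvoked(epochs, cc, tms = FALSE))
  names(terp) <- names(erp) <- conds
  tep <- Map(isolateTep, terp, erp)
  peaks <- rbind(
    do.call(rbind, lapply(conds, function(cc)
      extractTepPeaks(tep[[cc]], epochs@times, channels = epochs@channels,
                      cluster = tepCluster, condition = cc))),
    do.call(rbind, lapply(conds, function(cc)
      extractErpPeaks(erp[[cc]], epochs@times, channels = epochs@channels,
                      cluster = erpCluster, condition = cc))))
  methods::new("EvokedSet", terp = terp, erp = erp, tep = tep,
               times = epochs@times, channels = epochs@channels,
               peaks = peaks)
}

#' Default time windows of interest
#'
#' TEP components: P30 10-40 ms, P60 40-70 ms, N100 70-130 ms post-pulse.
#' ERP components: FIX-P1 -850..-750, FIX-N1 -750..-600 (fixation), CUE-N1
#' -150..-100, CUE-P1 -100..0, CUE-N2 0..300 ms (cue).
#'
#' @return named list of ms pairs.
#' @export
tepTois <- function() {
  list(P30 = c(10, 40), P60 = c(40, 70), N100 = c(70, 130))
}

#' @rdname tepTois
#' @export
erpWindows <- function() {
  list("FIX-P1" = c(-850, -750), "FIX-N1" = c(-750, -600),
       "CUE-N1" = c(-150, -100), "CUE-P1" = c(-100, 0),
       "CUE-N2" = c(0, 300))
}

# Mean trace over a named channel cluster.
clusterTrace <- function(waveform, channels, cluster) {
  ci <- match(cluster, channels$name)
  if (anyNA(ci)) stop("cluster channels missing from montage: ",
                      paste(cluster[is.na(ci)], collapse = ", "))
  colMeans(waveform[ci, , drop = FALSE])
}

#' Extract TEP peaks (maximum-absolute rule)
#'
#' Per component, the amplitude is the maximum absolute value of the
#' cluster-averaged trace within the component's window of interest and
#' the latency is its time; on exact ties the earlier sample wins (a flat
#' zero trace therefore reports the window start).
#'
#' @param tep channels x time TEP matrix.
#' @param times time axis, ms.
#' @param tois named list of windows (default \code{tepTois()}).
#' @param channels montage data.frame.
#' @param cluster channel names averaged into the extraction trace.
#' @param condition label copied into the output.
#' @return data.frame (component, condition, cluster, amplitude, latency).
#' @export
extractTepPeaks <- function(tep, times, tois = tepTois(), channels, cluster,
                            condition = NA_character_) {
  tr <- clusterTrace(tep, channels, cluster)
  res <- lapply(names(tois), function(comp) {
    w <- tois[[comp]]
    ti <- which(times >= w[1] & times <= w[2])
    if (!length(ti)) stop("empty window of interest: ", comp)
    a <- abs(tr[ti])
    k <- which.max(a)                          # first maximum on ties
    data.frame(component = comp, condition = condition,
               cluster = paste(cluster, collapse = "+"),
               amplitude = a[k], latency = times[ti[k]],
               value = tr[ti[k]], stringsAsFactors = FALSE)
  })
  do.call(rbind, res)
}

#' Extract ERP peaks (peak-to-peak rule)
#'
#' Per component window, the amplitude is the peak-to-peak range (maximum
#' minus minimum) of the cluster-averaged trace; the latency reported is
#' the time of the extremum with the larger absolute value.
#'
#' @inheritParams extractTepPeaks
#' @param erp channels x time ERP matrix.
#' @param windows named list of windows (default \code{erpWindows()}).
#' @return data.frame (component, condition, cluster, amplitude, latency).
#' @export
extractErpPeaks <- function(erp, times, windows = erpWindows(), channels,
                            cluster, condition = NA_character_) {
  tr <- clusterTrace(erp, channels, cluster)
  res <- lapply(names(windows), function(comp) {
    w <- windows[[comp]]
    ti <- which(times >= w[1] & times <= w[2])
    if (!length(ti)) stop("empty window: ", comp)
    seg <- tr[ti]
    iMax <- which.max(seg); iMin <- which.min(seg)
    iPk <- if (abs(seg[iMax]) >= abs(seg[iMin])) iMax else iMin
    data.frame(component = comp, condition = condition,
               cluster = paste(cluster, collapse = "+"),
               amplitude = seg[iMax] - seg[iMin], latency = times[ti[iPk]],
               value = seg[iPk], stringsAsFactors = FALSE)
  })
  do.call(rbind, res)
}
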
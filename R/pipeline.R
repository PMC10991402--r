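#' Analysis configuration
#'
#' Collects every stage parameter of the end-to-end analysis with defaults
#' matching the emulated protocol: 1-80 Hz band-pass with 50 Hz notch,
#' downsampling to 1000 Hz, pulse excision over -1..+10 ms, baseline noise
#' covariance over -850..-350 ms, minimum-norm regularization at SNR 3,
#' Morlet cycles 3 on 4-50 Hz, the four task-phase windows, TEP/ERP
#' windows of interest, 3000 permutations, and the 10-consecutive-sample
#' rule for source-waveform tests.
#'
#' @param nSubjects,nTrialsPerCell,fsRaw,fsOut,epochWindow,nChannels,seed
#'   see \code{sessionConfig()}.
#' @param truth a \code{groundTruth()} describing the simulated study.
#' @param rejectionRate see \code{sessionConfig()}.
#' @param span,flank pulse excision parameters (ms).
#' @param band,notch filter parameters (Hz).
#' @param rejectThreshold trial rejection threshold (uV peak-to-peak).
#' @param ica run independent-component cleaning (logical); synthetic
#'   sessions plant no ocular/muscle sources by default, so the stage
#'   defaults off.
#' @param covWindow baseline window for the noise covariance (ms).
#' @param nPerm permutations for cluster and runs tests.
#' @param minRun consecutive-sample rule for source-waveform tests.
#' @param runsWindow source-waveform comparison window (ms).
#' @param deferLinear exploit linearity of filtering, excision,
#'   downsampling and the inverse map to apply them to trial averages and
#'   ROI series instead of every sensor trace (identical results up to
#'   floating-point reordering when the noise covariance is shared; the
#'   deferred path estimates it before filtering). Cuts the cost of large
#'   simulated studies substantially.
#' @param stages named logical list switching report sections
#'   (connectivity, evoked, clusterStats, runsStats, anova, behaviour,
#'   correlations, regression).
#' @return list of class \code{"AnalysisConfig"}.
#' @export
analysisConfig <- function(nSubjects = 22, nTrialsPerCell = 100,
                           fsRaw = 5000, fsOut = 1000,
                           epochWindow = c(-1000, 1000), nChannels = 62,
                           seed = 1, truth = groundTruth(),
                           rejectionRate = 0,
                           span = c(-1, 10), flank = 20,
                           band = c(1, 80), notch = 50,
                           rejectThreshold = 500, ica = FALSE,
                           covWindow = c(-850, -350),
                           nPerm = 3000, minRun = 10,
                           runsWindow = c(-100, 300),
                           deferLinear = FALSE,
                           stages = list()) {
  stageDefaults <- list(connectivity = TRUE, evoked = TRUE,
                        clusterStats = TRUE, runsStats = TRUE, anova = TRUE,
                        behaviour = TRUE, correlations = TRUE,
                        regression = TRUE)
  structure(list(
    session = sessionConfig(nSubjects = nSubjects,
                            nTrialsPerCell = nTrialsPerCell, fsRaw = fsRaw,
                            fsOut = fsOut, epochWindow = epochWindow,
                            nChannels = nChannels,
                            rejectionRate = rejectionRate, seed = seed),
    truth = truth,
    span = span, flank = flank, band = band, notch = notch,
    rejectThreshold = rejectThreshold, ica = ica, covWindow = covWindow,
    nPerm = nPerm, minRun = minRun, runsWindow = runsWindow,
    deferLinear = deferLinear,
    stages = utils::modifyList(stageDefaults, stages),
    seed = as.integer(seed)), class = "AnalysisConfig")
}

# ---- per-subject processing -------------------------------------------

# Full path: every preprocessing stage on every sensor trace.
processSubjectFull <- function(ses, config) {
  ep <- ses$epochs
  ep <- exciseInterpolate(ep, config$span, config$flank)
  ep <- bandpassNotch(ep, config$band, config$notch)
  ep <- downsampleEpochs(ep, config$session$fsOut)
  ep <- demeanEpochs(ep)
  rej <- rejectTrials(ep, config$rejectThreshold)
  ep <- rej$epochs
  icaReport <- NULL
  if (isTRUE(config$ica)) {
    ic <- icaClean(ep, seed = config$seed)
    ep <- ic$epochs
    icaReport <- ic$report
  }
  model <- ses$model
  model@noiseCov <- estimateNoiseCov(ep, config$covWindow)
  K <- mnKernel(model)
  subjectMeasures(ep, model, K, config, rej$report, icaReport)
}

# Deferred path: excision and rejection on raw traces (both cheap), then
# filtering/downsampling/demeaning applied only to condition averages and
# ROI series, which the linearity of those operators licenses.
processSubjectDeferred <- function(ses, config) {
  ep <- exciseInterpolate(ses$epochs, config$span, config$flank)
  rej <- rejectTrials(ep, config$rejectThreshold)
  ep <- rej$epochs
  model <- ses$model
  model@noiseCov <- estimateNoiseCov(ep, config$covWindow)
  K <- mnKernel(model)
  fs <- ep@fs
  tr <- trialInfo(ep)
  conds <- sort(unique(tr$condition))

  # ROI trial series straight from the kernel rows of each ROI (the
  # inverse is linear, so only those rows are ever needed here), then
  # filter/downsample/demean the per-trial series
  roiSeries <- list()
  tmsIdx <- which(tr$tms)
  ntr <- dim(ep@data)[1]; nch <- dim(ep@data)[2]; nT <- dim(ep@data)[3]
  d2 <- ep@data
  dim(d2) <- c(ntr * nch, nT)
  for (roi in names(model@rois)) {
    idx <- model@rois[[roi]]
    rowsOf <- function(ch) (ch - 1L) * ntr
    # est_s[trial, time] for each ROI source via kernel row combination
    est <- matrix(0, length(idx) , length(tmsIdx) * nT)
    for (k in seq_along(idx)) {
      acc <- matrix(0, length(tmsIdx), nT)
      for (ch in seq_len(nch))
        acc <- acc + K[idx[k], ch] * d2[tmsIdx + rowsOf(ch), , drop = FALSE]
      est[k, ] <- acc
    }
    series <- if (length(idx) == 1) matrix(est, length(tmsIdx), nT) else {
      s <- roiSigns(est)
      matrix(colMeans(est * s), length(tmsIdx), nT)
    }
    x <- filterMatrix(t(series), fs, config$band, config$notch)
    dsr <- downsampleMatrix(x, ep@times, fs, config$session$fsOut)
    x <- sweep(dsr$x, 2, colMeans(dsr$x))
    roiSeries[[roi]] <- list(series = t(x), times = dsr$times,
                             trials = tr[tmsIdx, , drop = FALSE])
  }

  # condition averages at sensor level in one grouped pass, then filter
  cell <- interaction(tr$condition, ifelse(tr$tms, "tms", "notms"),
                      sep = "_", drop = FALSE)
  Gm <- stats::model.matrix(~ 0 + cell)
  Gm <- sweep(t(Gm), 1, colSums(Gm), "/")            # cells x trials
  d3 <- ep@data
  dim(d3) <- c(ntr, nch * nT)
  cellAvg <- Gm %*% d3                               # cells x (chan*time)
  avg <- list()
  for (cc in conds) for (tmsFlag in c(TRUE, FALSE)) {
    nm <- paste0(cc, "_", if (tmsFlag) "tms" else "notms")
    w <- matrix(cellAvg[paste0("cell", nm), ], nch, nT)
    x <- filterMatrix(t(w), fs, config$band, config$notch)
    dsr <- downsampleMatrix(x, ep@times, fs, config$session$fsOut)
    x <- sweep(dsr$x, 2, colMeans(dsr$x))
    avg[[nm]] <- list(wave = t(x), times = dsr$times)
  }
  outTimes <- avg[[1]]$times
  terp <- lapply(conds, function(cc) avg[[paste0(cc, "_tms")]]$wave)
  erp <- lapply(conds, function(cc) avg[[paste0(cc, "_notms")]]$wave)
  names(terp) <- names(erp) <- conds
  tep <- Map(isolateTep, terp, erp)
  ev <- methods::new("EvokedSet", terp = terp, erp = erp, tep = tep,
                     times = outTimes, channels = ep@channels,
                     peaks = evokedPeaksFrom(tep, erp, outTimes,
                                             ep@channels, config))
  measuresFromPieces(ev, roiSeries, tr, model, K, config, outTimes,
                     rej$report, NULL)
}

evokedPeaksFrom <- function(tep, erp, times, channels, config) {
  conds <- names(tep)
  tepCluster <- config$truth$tepCluster
  erpCluster <- config$truth$erpCluster
  rbind(
    do.call(rbind, lapply(conds, function(cc)
      extractTepPeaks(tep[[cc]], times, channels = channels,
                      cluster = tepCluster, condition = cc))),
    do.call(rbind, lapply(conds, function(cc)
      extractErpPeaks(erp[[cc]], times, channels = channels,
                      cluster = erpCluster, condition = cc))))
}

# Shared measurement block for the full path.
subjectMeasures <- function(ep, model, K, config, rejReport, icaReport) {
  tr <- trialInfo(ep)
  tmsIdx <- which(tr$tms)
  roiSeries <- list()
  if (length(tmsIdx)) {
    sub <- ep
    sub@data <- ep@data[tmsIdx, , , drop = FALSE]
    sub@trials <- tr[tmsIdx, , drop = FALSE]
    se <- minimumNorm(sub, model)
    for (roi in names(model@rois))
      roiSeries[[roi]] <- list(series = roiTimeseries(se, model, roi),
                               times = ep@times,
                               trials = sub@trials)
  }
  ev <- evokedSet(ep, tepCluster = config$truth$tepCluster,
                  erpCluster = config$truth$erpCluster)
  measuresFromPieces(ev, roiSeries, tr, model, K, config, ep@times,
                     rejReport, icaReport)
}

# From an EvokedSet + ROI trial series to the per-subject measures the
# group stage consumes.
measuresFromPieces <- function(ev, roiSeries, trials, model, K, config,
                               times, rejReport, icaReport) {
  conds <- names(ev@tep)
  # PLV per condition
  plvRows <- NULL
  if (isTRUE(config$stages$connectivity) && length(roiSeries) >= 2) {
    fsOut <- config$session$fsOut
    rts <- roiSeries[[1]]$times
    inWin <- rep(FALSE, length(rts))
    for (p in taskPhases()) inWin <- inWin | (rts >= p[1] & rts <= p[2])
    # induced activity: remove the per-condition evoked mean from each ROI
    # series so deterministic evoked components cannot masquerade as
    # oscillatory phase coupling
    grp <- roiSeries[[1]]$trials$condition
    sA <- subtractEvoked(roiSeries[["SMA"]]$series, grp)
    sB <- subtractEvoked(roiSeries[["M1"]]$series, grp)
    pls <- plvPair(sA, sB, rts, fsOut, groups = grp,
                   timeSubset = which(inWin))
    for (cc in intersect(conds, names(pls))) {
      bp <- bandPhaseAverage(pls[[cc]])
      bp$condition <- cc
      plvRows <- rbind(plvRows, bp)
    }
  }
  # per-channel TEP amplitudes within each window of interest
  tepChannel <- list()
  for (comp in names(tepTois())) {
    w <- tepTois()[[comp]]
    ti <- which(times >= w[1] & times <= w[2])
    tepChannel[[comp]] <- vapply(conds, function(cc)
      apply(abs(ev@tep[[cc]][, ti, drop = FALSE]), 1, max),
      numeric(nrow(ev@channels)))
  }
  # ROI waveforms of the TEP for the runs test
  roiWave <- NULL
  if (length(roiSeries) >= 2) {
    wi <- which(times >= config$runsWindow[1] & times <= config$runsWindow[2])
    roiWave <- list(times = times[wi])
    for (roi in names(model@rois)) {
      roiWave[[roi]] <- lapply(conds, function(cc) {
        est <- K %*% ev@tep[[cc]]
        roiTimeseries(est, model, roi)[wi]
      })
      names(roiWave[[roi]]) <- conds
    }
  }
  # behavioural summaries
  bh <- NULL
  if (isTRUE(config$stages$behaviour)) {
    sumFor <- function(sel) {
      go <- sel & trials$condition == "Go"
      nogo <- sel & trials$condition == "NoGo"
      c(rt = mean(trials$rt[go & !trials$miss], na.rm = TRUE),
        fa = 100 * mean(trials$fa[nogo]),
        miss = 100 * mean(trials$miss[go]))
    }
    bh <- rbind(tms = sumFor(trials$tms), notms = sumFor(!trials$tms),
                total = sumFor(rep(TRUE, nrow(trials))))
  }
  list(plv = plvRows, tepChannel = tepChannel, peaks = ev@peaks,
       roiWave = roiWave, behaviour = bh, evoked = ev,
       rejection = rejReport, ica = icaReport)
}

# ---- group-level assembly ---------------------------------------------

#' Behavioural comparison of TMS and no-TMS trials
#'
#' Per-subject mean reaction time, false-alarm and miss percentages, split
#' by TMS presence, each compared with the normality-gated paired test.
#'
#' @param behaviourList list of per-subject 3 x 3 summaries (rows tms /
#'   notms / total, columns rt / fa / miss), as produced by
#'   \code{runFull()}, or a data.frame with columns \code{subject},
#'   \code{condition}, \code{tms}, \code{rt}, \code{fa}, \code{miss}
#'   (trial-level, one subject per \code{subject} level).
#' @return data.frame: measure, TMS and no-TMS group means, grand mean,
#'   statistic, p, test used.
#' @export
runBehavioural <- function(behaviourList) {
  if (is.data.frame(behaviourList)) {
    split_ <- split(behaviourList, behaviourList$subject)
    behaviourList <- lapply(split_, function(tr) {
      sumFor <- function(sel) {
        go <- sel & tr$condition == "Go"
        nogo <- sel & tr$condition == "NoGo"
        c(rt = mean(tr$rt[go & !tr$miss], na.rm = TRUE),
          fa = 100 * mean(tr$fa[nogo]),
          miss = 100 * mean(tr$miss[go]))
      }
      rbind(tms = sumFor(tr$tms), notms = sumFor(!tr$tms),
            total = sumFor(rep(TRUE, nrow(tr))))
    })
  }
  out <- lapply(c("rt", "fa", "miss"), function(ms) {
    tmsV <- vapply(behaviourList, function(b) b["tms", ms], numeric(1))
    noV <- vapply(behaviourList, function(b) b["notms", ms], numeric(1))
    totV <- vapply(behaviourList, function(b) b["total", ms], numeric(1))
    pt <- pairedTest(tmsV, noV)
    data.frame(measure = ms, tms = mean(tmsV), notms = mean(noV),
               total = mean(totV), totalSd = stats::sd(totV),
               statistic = pt$statistic, p = pt$p, test = pt$method,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, out)
}

#' Run the full analysis pipeline on a simulated study
#'
#' Generates the configured multi-subject study and runs every stage in
#' order: preprocessing, noise covariance and minimum-norm inverse, ROI
#' phase-locking connectivity by task phase and condition, TERP/ERP/TEP
#' decomposition with peak extraction, cluster-based sensor statistics on
#' the TEP windows, consecutive-timepoint source-waveform tests,
#' repeated-measures ANOVA on the PLV table with Sidak post-hocs, the
#' behavioural TMS/no-TMS comparison, RT-connectivity correlations, and
#' the stepwise regression predicting the N100 modulation from the 16
#' band x phase PLV modulations. Deterministic under a fixed seed.
#'
#' @param config an \code{analysisConfig()}.
#' @param outDir optional directory: when given, all tables are written as
#'   tidy CSVs plus a JSON provenance record via \code{writeReport()}.
#' @return list of class \code{"AnalysisReport"}.
#' @export
runFull <- function(config, outDir = NULL) {
  stopifnot(inherits(config, "AnalysisConfig"))
  mon <- montageSubset(config$session$nChannels)
  model <- buildToyModel(channels = mon, seed = config$seed)
  nSub <- config$session$nSubjects
  subjects <- sprintf("S%02d", seq_len(nSub))
  meas <- vector("list", nSub)
  subjectTruth <- vector("list", nSub)
  for (s in seq_len(nSub)) {
    ses <- generateSession(config$session, config$truth, subject = s,
                           model = model)
    sp <- ses$truth$subjectParams
    subjectTruth[[s]] <- data.frame(
      subject = subjects[s],
      n100Diff = sp$n100Diff, rtMean = sp$rtMean,
      thetaCueDiff = sp$plvDiff["theta", "cue_elaboration"],
      gammaCueDiff = sp$plvDiff["gamma", "cue_elaboration"],
      thetaTmsDiff = sp$plvDiff["theta", "tms_perturbation"],
      gammaTmsDiff = sp$plvDiff["gamma", "tms_perturbation"],
      stringsAsFactors = FALSE)
    meas[[s]] <- if (isTRUE(config$deferLinear))
      processSubjectDeferred(ses, config) else
        processSubjectFull(ses, config)
    rm(ses)
  }
  report <- list(config = config, subjects = subjects,
                 subjectTruth = do.call(rbind, subjectTruth))

  # PLV table
  plvTab <- NULL
  if (isTRUE(config$stages$connectivity)) {
    plvTab <- do.call(rbind, lapply(seq_len(nSub), function(s) {
      x <- meas[[s]]$plv
      if (is.null(x)) return(NULL)
      x$subject <- subjects[s]
      x
    }))
    report$plv <- plvTab
  }
  # behavioural stage
  if (isTRUE(config$stages$behaviour))
    report$behaviour <- runBehavioural(lapply(meas, `[[`, "behaviour"))
  # ANOVA + post-hocs on PLV
  if (isTRUE(config$stages$anova) && !is.null(plvTab) && nSub >= 2) {
    report$anova <- rmAnova(plvTab, dv = "plv",
                            within = c("phase", "condition", "band"))
    ph <- NULL
    for (phs in unique(plvTab$phase)) {
      sub <- plvTab[plvTab$phase == phs, ]
      rows <- lapply(unique(sub$band), function(bd) {
        go <- sub$plv[sub$band == bd & sub$condition == "Go"]
        nogo <- sub$plv[sub$band == bd & sub$condition == "NoGo"]
        pt <- pairedTest(nogo, go)
        data.frame(phase = phs, band = bd, diff = mean(nogo - go),
                   se = stats::sd(nogo - go) / sqrt(length(go)),
                   statistic = pt$statistic, p = pt$p,
                   stringsAsFactors = FALSE)
      })
      rows <- do.call(rbind, rows)
      rows$pSidak <- sidakPosthoc(rows$p, m = nrow(rows))
      ph <- rbind(ph, rows)
    }
    report$posthoc <- ph
  }
  # cluster statistics per TEP component
  if (isTRUE(config$stages$clusterStats) && nSub >= 2) {
    report$clusters <- lapply(names(tepTois()), function(comp) {
      a <- t(vapply(meas, function(m) m$tepChannel[[comp]][, "NoGo"],
                    numeric(config$session$nChannels)))
      b <- t(vapply(meas, function(m) m$tepChannel[[comp]][, "Go"],
                    numeric(config$session$nChannels)))
      clusterPermutation(a, b, channels = mon, nPerm = config$nPerm,
                         seed = childSeed(config$seed, 5L))
    })
    names(report$clusters) <- names(tepTois())
  }
  # runs statistics per ROI
  if (isTRUE(config$stages$runsStats) && nSub >= 2 &&
      !is.null(meas[[1]]$roiWave)) {
    report$runs <- lapply(names(model@rois), function(roi) {
      a <- t(vapply(meas, function(m) m$roiWave[[roi]][["NoGo"]],
                    numeric(length(meas[[1]]$roiWave$times))))
      b <- t(vapply(meas, function(m) m$roiWave[[roi]][["Go"]],
                    numeric(length(meas[[1]]$roiWave$times))))
      runsPermutation(a, b, times = meas[[1]]$roiWave$times,
                      minRun = config$minRun, nPerm = config$nPerm,
                      seed = childSeed(config$seed, 7L))
    })
    names(report$runs) <- names(model@rois)
  }
  # peak tables
  report$peaks <- do.call(rbind, lapply(seq_len(nSub), function(s) {
    p <- meas[[s]]$peaks
    p$subject <- subjects[s]
    p
  }))
  # per-subject N100 modulation + PLV modulations
  if (!is.null(plvTab)) {
    modTab <- plvModulations(plvTab)
    n100 <- n100Modulation(report$peaks)
    report$modulations <- merge(modTab, n100, by = "subject")
    if (isTRUE(config$stages$correlations) && nSub >= 3) {
      rtBySub <- vapply(meas, function(m) m$behaviour["total", "rt"],
                        numeric(1))
      report$correlations <- do.call(rbind, lapply(
        names(plvBands()), function(bd) {
          v <- report$modulations[[paste0(bd, "_cue_elaboration")]]
          ct <- correlateGated(rtBySub, v)
          data.frame(measure = "rt", band = bd, phase = "cue_elaboration",
                     r = ct$r, p = ct$p, method = ct$method,
                     stringsAsFactors = FALSE)
        }))
    }
    if (isTRUE(config$stages$regression)) {
      predCols <- setdiff(names(report$modulations),
                          c("subject", "n100Mod"))
      report$regression <- stepwiseRegression(
        report$modulations$n100Mod,
        report$modulations[, predCols, drop = FALSE])
    }
  }
  report$rejection <- lapply(meas, `[[`, "rejection")
  report$provenance <- list(seed = config$seed,
                            package = "tmsgonogo",
                            version = as.character(utils::packageVersion("tmsgonogo")),
                            nSubjects = nSub)
  class(report) <- "AnalysisReport"
  if (!is.null(outDir)) writeReport(report, outDir)
  report
}

# Remove the group-mean (evoked) waveform from each trial of a trials x
# time series.
subtractEvoked <- function(series, groups) {
  for (g in unique(groups)) {
    i <- which(groups == g)
    series[i, ] <- sweep(series[i, , drop = FALSE], 2,
                         colMeans(series[i, , drop = FALSE]))
  }
  series
}

# NoGo - Go PLV differences in wide per-subject form.
plvModulations <- function(plvTab) {
  wide <- NULL
  for (s in unique(plvTab$subject)) {
    sub <- plvTab[plvTab$subject == s, ]
    row <- list(subject = s)
    for (bd in unique(sub$band)) for (phs in unique(sub$phase)) {
      go <- sub$plv[sub$band == bd & sub$phase == phs &
                      sub$condition == "Go"]
      nogo <- sub$plv[sub$band == bd & sub$phase == phs &
                        sub$condition == "NoGo"]
      row[[paste0(bd, "_", phs)]] <- nogo - go
    }
    wide <- rbind(wide, as.data.frame(row, stringsAsFactors = FALSE))
  }
  wide
}

# NoGo - Go N100 amplitude modulation per subject (absolute amplitudes).
n100Modulation <- function(peaks) {
  sub <- peaks[peaks$component == "N100", ]
  out <- lapply(unique(sub$subject), function(s) {
    go <- sub$amplitude[sub$subject == s & sub$condition == "Go"]
    nogo <- sub$amplitude[sub$subject == s & sub$condition == "NoGo"]
    data.frame(subject = s, n100Mod = nogo - go, stringsAsFactors = FALSE)
  })
  do.call(rbind, out)
}

#' @export
print.AnalysisReport <- function(x, ...) {
  cat("AnalysisReport:", length(x$subjects), "subjects\n")
  if (!is.null(x$behaviour)) {
    cat("\nBehaviour (TMS vs no-TMS):\n")
    print(x$behaviour, row.names = FALSE)
  }
  if (!is.null(x$anova)) {
    cat("\nPLV repeated-measures ANOVA:\n")
    print(x$anova, row.names = FALSE)
  }
  if (!is.null(x$clusters)) {
    for (comp in names(x$clusters)) {
      cat("\nCluster test,", comp, ":",
          nrow(x$clusters[[comp]]$clusters), "cluster(s)\n")
      if (nrow(x$clusters[[comp]]$clusters))
        print(x$clusters[[comp]]$clusters, row.names = FALSE)
    }
  }
  if (!is.null(x$regression)) {
    cat("\nStepwise regression (N100 modulation ~ PLV modulations):\n")
    cat("  selected:", paste(x$regression$selected, collapse = ", "), "\n")
  }
  invisible(x)
}

#' Write an analysis report to disk
#'
#' Tidy CSV per table plus a JSON provenance record (seed, package
#' version, configuration echo). Re-running the same configuration and
#' seed reproduces the files byte for byte.
#'
#' @param report an \code{"AnalysisReport"}.
#' @param outDir output directory (created if needed).
#' @return \code{outDir}, invisibly.
#' @export
writeReport <- function(report, outDir) {
  dir.create(outDir, showWarnings = FALSE, recursive = TRUE)
  wcsv <- function(x, name) {
    if (!is.null(x))
      utils::write.csv(x, file.path(outDir, paste0(name, ".csv")),
                       row.names = FALSE)
  }
  wcsv(report$plv, "plv")
  wcsv(report$behaviour, "behaviour")
  wcsv(report$anova, "anova")
  wcsv(report$posthoc, "posthoc")
  wcsv(report$peaks, "peaks")
  wcsv(report$modulations, "modulations")
  wcsv(report$correlations, "correlations")
  if (!is.null(report$clusters))
    for (comp in names(report$clusters))
      wcsv(report$clusters[[comp]]$clusters, paste0("clusters_", comp))
  if (!is.null(report$runs))
    for (roi in names(report$runs))
      wcsv(report$runs[[roi]]$spans, paste0("runs_", roi))
  if (!is.null(report$regression)) {
    wcsv(report$regression$coefficients, "regression_coefficients")
    writeLines(paste("selected:",
                     paste(report$regression$selected, collapse = ", ")),
               file.path(outDir, "regression_selected.txt"))
  }
  cfg <- report$config
  prov <- list(seed = report$provenance$seed,
               package = report$provenance$package,
               version = report$provenance$version,
               nSubjects = report$provenance$nSubjects,
               config = list(session = unclass(cfg$session),
                             band = cfg$band, notch = cfg$notch,
                             span = cfg$span, nPerm = cfg$nPerm,
                             minRun = cfg$minRun,
                             deferLinear = cfg$deferLinear))
  jsonlite::write_json(prov, file.path(outDir, "provenance.json"),
                       auto_unbox = TRUE, digits = NA, force = TRUE)
  yaml::write_yaml(prov$config, file.path(outDir, "config.yaml"))
  invisible(outDir)
}
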
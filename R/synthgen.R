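#' Session configuration for the synthetic Go/NoGo TMS-EEG generator
#'
#' Defaults reproduce the acquisition protocol the generator emulates:
#' 62 channels sampled at 5000 Hz, epochs from -1000 to +1000 ms around the
#' TMS pulse (analysis rate 1000 Hz after downsampling), and 100 trials per
#' cell of the Go/NoGo x TMS/noTMS design (400 trials in total).
#'
#' @param nSubjects number of subjects in a study.
#' @param nTrialsPerCell trials per condition cell (>= 1).
#' @param fsRaw acquisition sampling rate, Hz.
#' @param fsOut analysis sampling rate after downsampling, Hz; must divide
#'   \code{fsRaw}.
#' @param epochWindow epoch limits in ms; must span 0 (the pulse).
#' @param nChannels number of montage channels used (leading subset of the
#'   62-channel template).
#' @param rejectionRate fraction of trials planted with a gross movement
#'   artifact, to exercise trial rejection (the emulated recordings lose
#'   under 5% of trials to rejection).
#' @param seed integer seed; fixed seed gives bit-identical sessions.
#' @return a list of class \code{"SessionConfig"}.
#' @export
sessionConfig <- function(nSubjects = 1, nTrialsPerCell = 100, fsRaw = 5000,
                          fsOut = 1000, epochWindow = c(-1000, 1000),
                          nChannels = 62, rejectionRate = 0, seed = 1) {
  if (nTrialsPerCell < 1) stop("nTrialsPerCell must be >= 1")
  if (epochWindow[1] >= 0 || epochWindow[2] <= 0)
    stop("epochWindow must span the TMS pulse at 0 ms")
  if (fsRaw %% fsOut != 0)
    stop("fsRaw must be divisible by fsOut")
  if (rejectionRate < 0 || rejectionRate >= 1)
    stop("rejectionRate must be in [0, 1)")
  mon <- standardMontage()
  if (nChannels < 2 || nChannels > nrow(mon))
    stop("nChannels must be between 2 and ", nrow(mon))
  structure(list(nSubjects = nSubjects, nTrialsPerCell = nTrialsPerCell,
                 fsRaw = fsRaw, fsOut = fsOut, epochWindow = epochWindow,
                 nChannels = nChannels, rejectionRate = rejectionRate,
                 seed = as.integer(seed)),
            class = "SessionConfig")
}

#' Ground truth for the synthetic generator
#'
#' Defines everything the generator plants: TMS-evoked components (P30,
#' P60, N100), task event-related components (FIX-P1, FIX-N1, CUE-N1,
#' CUE-P1, CUE-N2), band- and task-phase-specific phase coupling between
#' the SMA and M1 sources, behavioural outcome distributions, and the
#' linear links tying per-subject coupling modulation to the N100
#' modulation and to reaction time.
#'
#' Default effect magnitudes are the condition differences this paradigm is
#' known to produce: an N100 that is 0.884 uV larger (more negative) in
#' NoGo over a left fronto-central cluster, a CUE-N2 that is 1.386 uV
#' larger in Go, NoGo-Go phase-locking differences of +0.060 (theta) and
#' -0.018 (gamma) during cue elaboration, +0.071 (theta), -0.061 (alpha)
#' and -0.073 (beta) during the TMS perturbation, and +0.023 / -0.028 /
#' -0.052 (theta/alpha/beta) during the task response; reaction times of
#' 531 +/- 75 ms, 0.76% false alarms and 2.87% misses; and N100-link
#' coefficients of 8.957 (theta) and 11.304 (gamma) uV per PLV unit for
#' coupling measured during the TMS perturbation.
#'
#' @param tepAmpGo,tepAmpNoGo named amplitudes (uV) for P30/P60/N100 in each
#'   condition, as cluster-average peaks. \code{NA} in
#'   \code{tepAmpNoGo["N100"]} (the default) means "derive per subject from
#'   the N100 link model".
#' @param tepWidth,erpWidth Gaussian component widths (ms, sd).
#' @param erpAmpGo,erpAmpNoGo ERP component amplitudes (uV, cluster-average
#'   peak) per condition.
#' @param plvBase mean baseline coupling (PLV target) common to all bands.
#' @param plvDiff 4 x 4 matrix (band x phase) of NoGo-Go coupling
#'   differences.
#' @param carriers band carrier frequencies, Hz.
#' @param oscAmp source oscillation amplitudes per band (uV-equivalent at
#'   the best-coupled sensor).
#' @param sourceNoiseSd white background noise added to each ROI source.
#' @param sensorNoiseSd white sensor noise (uV); the default emulates the
#'   residual trial noise of cleaned TMS-EEG recordings.
#' @param subjectDiffSd,subjectBaseSd between-subject sd of the planted
#'   coupling differences and baselines.
#' @param n100Link list: target mean NoGo-Go N100 difference (uV) and the
#'   theta/gamma regression coefficients tying the per-subject difference
#'   to coupling differences during the TMS perturbation, plus residual sd.
#' @param behaviour list of behavioural parameters: RT intercept and trial
#'   sd (ms), FA and MISS rates, the RT coefficient on the subject's gamma
#'   coupling difference during cue elaboration (ms per PLV unit; negative
#'   plants the inverse RT-gamma relation), and the subject-level RT sd.
#' @param plvCalibration "chain" (default) passes coupling targets through
#'   the inverse of the numerically measured chain calibration curve, so
#'   the PLV recovered by the default analysis chain approximates the
#'   requested target; "none" plants the analytic von Mises map directly
#'   (exact at the phase-difference level).
#' @param artifact list: TMS pulse artifact amplitude (uV) and decay time
#'   constant (ms); blink amplitude (uV), per-trial blink probability, and
#'   muscle amplitude for component-cleaning tests.
#' @return a list of class \code{"GroundTruth"}.
#' @export
groundTruth <- function(
    tepAmpGo = c(P30 = 5, P60 = 3.5, N100 = -4),
    tepAmpNoGo = c(P30 = 5, P60 = 3.5, N100 = NA),
    tepWidth = c(P30 = 8, P60 = 10, N100 = 15),
    erpAmpGo = c("FIX-P1" = 3, "FIX-N1" = -2.5, "CUE-N1" = -2,
                 "CUE-P1" = 3, "CUE-N2" = -4.386),
    erpAmpNoGo = c("FIX-P1" = 3, "FIX-N1" = -2.5, "CUE-N1" = -2,
                   "CUE-P1" = 2.2, "CUE-N2" = -3),
    erpWidth = c("FIX-P1" = 15, "FIX-N1" = 20, "CUE-N1" = 12,
                 "CUE-P1" = 18, "CUE-N2" = 30),
    plvBase = 0.45,
    plvDiff = defaultPlvDiff(),
    carriers = c(theta = 5.5, alpha = 10, beta = 20, gamma = 40),
    oscAmp = c(theta = 4, alpha = 5, beta = 4, gamma = 3),
    sourceNoiseSd = 0.6,
    sensorNoiseSd = 2,
    subjectDiffSd = 0.1,
    subjectBaseSd = 0.03,
    n100Link = list(targetDiff = 0.884, thetaBeta = 8.957,
                    gammaBeta = 11.304, noiseSd = 0.3),
    behaviour = list(rtIntercept = 531, rtSd = 75, faRate = 0.0076,
                     missRate = 0.0287, rtGammaCueCoef = -150,
                     rtSubjectSd = 26),
    plvCalibration = c("chain", "none"),
    artifact = list(tmsAmp = 2000, tau = 3, blinkAmp = 0, blinkRate = 0,
                    muscleAmp = 0)) {
  tepLatency <- c(P30 = 30, P60 = 60, N100 = 100)
  erpLatency <- c("FIX-P1" = -800, "FIX-N1" = -680, "CUE-N1" = -120,
                  "CUE-P1" = -50, "CUE-N2" = 150)
  stopifnot(all(plvDiff >= -1 & plvDiff <= 1),
            plvBase >= 0, plvBase <= 1,
            all(is.finite(c(tepAmpGo, erpAmpGo, erpAmpNoGo))))
  structure(list(
    tep = data.frame(name = names(tepLatency), latency = tepLatency,
                     width = tepWidth[names(tepLatency)],
                     ampGo = tepAmpGo[names(tepLatency)],
                     ampNoGo = tepAmpNoGo[names(tepLatency)],
                     row.names = NULL, stringsAsFactors = FALSE),
    erp = data.frame(name = names(erpLatency), latency = erpLatency,
                     width = erpWidth[names(erpLatency)],
                     ampGo = erpAmpGo[names(erpLatency)],
                     ampNoGo = erpAmpNoGo[names(erpLatency)],
                     row.names = NULL, stringsAsFactors = FALSE),
    tepCluster = c("Fz", "FCz", "FC1", "C1", "C3"),
    erpCluster = c("AFz", "Fz", "F1", "F2", "FCz", "FC1", "FC2", "Cz"),
    plvBase = plvBase, plvDiff = plvDiff,
    carriers = carriers, oscAmp = oscAmp,
    sourceNoiseSd = sourceNoiseSd, sensorNoiseSd = sensorNoiseSd,
    subjectDiffSd = subjectDiffSd, subjectBaseSd = subjectBaseSd,
    n100Link = n100Link, behaviour = behaviour, artifact = artifact,
    plvCalibration = match.arg(plvCalibration)
  ), class = "GroundTruth")
}

#' Default planted coupling differences (NoGo - Go) per band and task phase
#'
#' @return 4 x 4 numeric matrix, rows theta/alpha/beta/gamma, columns
#'   preparation / cue_elaboration / tms_perturbation / task_response.
#' @export
defaultPlvDiff <- function() {
  m <- matrix(0, 4, 4, dimnames = list(
    c("theta", "alpha", "beta", "gamma"),
    c("preparation", "cue_elaboration", "tms_perturbation", "task_response")))
  m["theta", "cue_elaboration"] <- 0.060
  m["gamma", "cue_elaboration"] <- -0.018
  m["theta", "tms_perturbation"] <- 0.071
  m["alpha", "tms_perturbation"] <- -0.061
  m["beta", "tms_perturbation"] <- -0.073
  m["theta", "task_response"] <- 0.023
  m["alpha", "task_response"] <- -0.028
  m["beta", "task_response"] <- -0.052
  m
}

# Scalp topography from leadfield columns of ROI sources, normalized so the
# signed mean over the reference cluster is 1 (peaks extracted as cluster
# averages then recover planted amplitudes directly).
topoFromRois <- function(model, weights, cluster) {
  w <- numeric(nrow(model@leadfield))
  for (roi in names(weights))
    w <- w + weights[[roi]] * rowMeans(model@leadfield[, model@rois[[roi]],
                                                       drop = FALSE])
  ci <- match(cluster, model@channels$name)
  ci <- ci[!is.na(ci)]
  if (!length(ci)) stop("normalization cluster absent from montage")
  m <- mean(w[ci])
  if (abs(m) < 1e-12) stop("degenerate topography: zero cluster mean")
  w / m
}

# Draw per-subject planted parameters. Consumes a fixed number of draws.
drawSubjectParams <- function(truth) {
  bands <- rownames(truth$plvDiff); phases <- colnames(truth$plvDiff)
  diff <- truth$plvDiff +
    matrix(stats::rnorm(16, 0, truth$subjectDiffSd), 4, 4)
  dimnames(diff) <- dimnames(truth$plvDiff)
  base <- truth$plvBase + matrix(stats::rnorm(16, 0, truth$subjectBaseSd), 4, 4)
  dimnames(base) <- dimnames(truth$plvDiff)
  go <- base - diff / 2
  go[] <- pmin(0.95, pmax(0.02, go))
  nogo <- base + diff / 2
  nogo[] <- pmin(0.95, pmax(0.02, nogo))
  lk <- truth$n100Link
  intercept <- lk$targetDiff -
    lk$thetaBeta * truth$plvDiff["theta", "tms_perturbation"] -
    lk$gammaBeta * truth$plvDiff["gamma", "tms_perturbation"]
  n100Diff <- intercept +
    lk$thetaBeta * diff["theta", "tms_perturbation"] +
    lk$gammaBeta * diff["gamma", "tms_perturbation"] +
    stats::rnorm(1, 0, lk$noiseSd)
  bh <- truth$behaviour
  rtMean <- bh$rtIntercept +
    bh$rtGammaCueCoef * (diff["gamma", "cue_elaboration"] -
                           truth$plvDiff["gamma", "cue_elaboration"]) +
    stats::rnorm(1, 0, bh$rtSubjectSd)
  list(plvGo = go, plvNoGo = nogo, plvDiff = diff, n100Diff = n100Diff,
       rtMean = rtMean)
}

# Segment boundaries (ms) for the piecewise coupling state. The analysis
# phase windows are interior to these segments: the cue segment extends to
# +10 ms because -1..+10 ms is excised and interpolated downstream.
couplingSegments <- function() {
  list(breaks = c(-1000, -850, -350, -150, 10, 150, 650, 1000.001),
       phase = c(NA, "preparation", NA, "cue_elaboration",
                 "tms_perturbation", "task_response", NA))
}

#' Generate one synthetic Go/NoGo TMS-EEG session
#'
#' Produces a full single-subject session at the acquisition rate: per-trial
#' multichannel epochs containing task event-related components (all
#' trials), TMS-evoked components and a pulse artifact (TMS trials),
#' band-limited SMA/M1 source oscillations with task-phase- and
#' condition-dependent phase coupling mixed to the sensors through the toy
#' leadfield, white sensor noise, and behavioural outcomes linearly tied to
#' the subject's planted coupling modulation.
#'
#' Phase coupling is implemented by sharing the band carrier between the
#' two ROI sources and adding a trial-wise von Mises phase offset whose
#' concentration is the analytic inverse of the mean-resultant-length map
#' at the target PLV; the offset is piecewise constant over task-phase
#' segments with short raised-cosine transitions.
#'
#' @param config a \code{sessionConfig()}.
#' @param truth a \code{groundTruth()}.
#' @param subject subject index (changes the derived seed and label).
#' @param model optional \linkS4class{SourceModel}; defaults to the package
#'   toy model on the configured montage, which downstream analysis should
#'   share so forward and inverse modelling are consistent.
#' @return list with elements \code{epochs} (\linkS4class{EpochSet}, trial
#'   metadata includes behaviour), \code{trials} (the same trial table),
#'   \code{truth} (input truth augmented with the per-subject drawn
#'   parameters in \code{$subjectParams}), and \code{model}.
#' @examples
#' cfg <- sessionConfig(nTrialsPerCell = 4, fsRaw = 500, fsOut = 500,
#'                      nChannels = 16, seed = 7)
#' ses <- generateSession(cfg, groundTruth())
#' ses$epochs
#' @export
generateSession <- function(config, truth, subject = 1, model = NULL) {
  stopifnot(inherits(config, "SessionConfig"), inherits(truth, "GroundTruth"))
  mon <- montageSubset(config$nChannels)
  if (is.null(model))
    model <- buildToyModel(channels = mon, seed = config$seed)
  if (nrow(model@channels) != nrow(mon))
    stop("model montage does not match configured channel count")
  set.seed(childSeed(config$seed, 1000L + subject))
  times <- epochTimeAxis(config$epochWindow, config$fsRaw)
  nT <- length(times)
  nch <- nrow(mon)
  ncell <- config$nTrialsPerCell
  trials <- data.frame(
    condition = rep(c("Go", "NoGo", "Go", "NoGo"), each = ncell),
    tms = rep(c(TRUE, TRUE, FALSE, FALSE), each = ncell),
    stringsAsFactors = FALSE)
  ord <- sample.int(nrow(trials))
  trials <- trials[ord, , drop = FALSE]
  rownames(trials) <- NULL
  ntr <- nrow(trials)

  sp <- drawSubjectParams(truth)

  # ---- sensor noise first (fixed draw count => component additivity) ----
  arr <- array(stats::rnorm(ntr * nT * nch, 0, truth$sensorNoiseSd),
               c(ntr, nT, nch))  # internal layout: trial x time x channel

  # ---- deterministic evoked components -------------------------------
  erpTopo <- topoFromRois(model, list(SMA = 1), truth$erpCluster)
  tepTopo <- list(
    P30 = topoFromRois(model, list(M1 = 1), truth$tepCluster),
    P60 = topoFromRois(model, list(M1 = 1), truth$tepCluster),
    N100 = topoFromRois(model, list(M1 = 0.4, SMA = 0.6), truth$tepCluster))
  tepAmps <- truth$tep
  if (is.na(tepAmps$ampNoGo[tepAmps$name == "N100"]))
    tepAmps$ampNoGo[tepAmps$name == "N100"] <-
      tepAmps$ampGo[tepAmps$name == "N100"] - sp$n100Diff
  # per-cell total component field (time x channel), added in one slice op
  gauss <- function(amp, latency, width)
    amp * exp(-(times - latency)^2 / (2 * width^2))
  cellField <- function(cond, tms) {
    F <- matrix(0, nT, nch)
    ampcol <- if (cond == "Go") "ampGo" else "ampNoGo"
    for (k in seq_len(nrow(truth$erp))) {
      e <- truth$erp[k, ]
      if (e[[ampcol]] != 0)
        F <- F + outer(gauss(e[[ampcol]], e$latency, e$width), erpTopo)
    }
    if (tms) for (k in seq_len(nrow(tepAmps))) {
      e <- tepAmps[k, ]
      if (e[[ampcol]] != 0)
        F <- F + outer(gauss(e[[ampcol]], e$latency, e$width),
                       tepTopo[[e$name]])
    }
    F
  }
  for (cond in c("Go", "NoGo")) for (tms in c(TRUE, FALSE)) {
    idx <- which(trials$condition == cond & trials$tms == tms)
    if (!length(idx)) next
    F <- cellField(cond, tms)
    if (max(abs(F)) == 0) next
    arr[idx, , ] <- arr[idx, , , drop = FALSE] +
      array(rep(F, each = length(idx)), c(length(idx), nT, nch))
  }
  iGo <- which(trials$condition == "Go")
  iNoGo <- which(trials$condition == "NoGo")

  # ---- phase-coupled band oscillations -------------------------------
  seg <- couplingSegments()
  nseg <- length(seg$phase)
  W <- vapply(seq_len(nseg), function(j) {
    v <- rep(0, nseg); v[j] <- 1
    smoothStep(times, seg$breaks, v, ramp = 50)
  }, numeric(nT))                               # time x segment
  lfSMA <- model@leadfield[, model@rois[["SMA"]][1]]
  lfM1 <- model@leadfield[, model@rois[["M1"]][1]]
  segKappa <- function(cond) {
    tgt <- if (cond == "Go") sp$plvGo else sp$plvNoGo
    vapply(seq_len(nseg), function(j) {
      ph <- seg$phase[j]
      r <- vapply(rownames(tgt), function(b)
        if (is.na(ph)) truth$plvBase else tgt[b, ph], numeric(1))
      r
    }, numeric(4))                              # band x segment
  }
  kGo <- segKappa("Go"); kNoGo <- segKappa("NoGo")
  bands <- names(truth$carriers)
  srcNoiseA <- matrix(stats::rnorm(ntr * nT, 0, truth$sourceNoiseSd), ntr, nT)
  srcNoiseB <- matrix(stats::rnorm(ntr * nT, 0, truth$sourceNoiseSd), ntr, nT)
  oscA <- srcNoiseA; oscB <- srcNoiseB
  for (b in bands) {
    f <- truth$carriers[[b]]
    amp <- truth$oscAmp[[b]]
    phi0 <- stats::runif(ntr, -pi, pi)
    jit <- matrix(0, ntr, nseg)
    cal <- identical(truth$plvCalibration, "chain")
    for (j in seq_len(nseg)) {
      rGo <- kGo[match(b, bands), j]
      rNoGo <- kNoGo[match(b, bands), j]
      if (cal) {
        rGo <- plantForTarget(b, rGo)
        rNoGo <- plantForTarget(b, rNoGo)
      }
      kapGo <- plvToKappa(rGo)
      kapNoGo <- plvToKappa(rNoGo)
      jj <- numeric(ntr)
      jj[iGo] <- rvonmises(length(iGo), kapGo)
      jj[iNoGo] <- rvonmises(length(iNoGo), kapNoGo)
      jit[, j] <- jj
    }
    if (amp == 0) next
    theta <- outer(phi0, rep(1, nT)) +
      matrix(2 * pi * f * times / 1000, ntr, nT, byrow = TRUE)
    dphi <- jit %*% t(W)                        # trial x time
    oscA <- oscA + amp * cos(theta)
    oscB <- oscB + amp * cos(theta + dphi)
  }
  # mix the two ROI source series to the sensors (channel-wise)
  for (c in seq_len(nch))
    arr[, , c] <- arr[, , c] + lfSMA[c] * oscA + lfM1[c] * oscB

  # ---- gross artifact trials (rejection knob) ------------------------
  artTrial <- rep(FALSE, ntr)
  if (config$rejectionRate > 0) {
    artTrial <- stats::runif(ntr) < config$rejectionRate
    if (any(artTrial)) {
      nbad <- sum(artTrial)
      drift <- t(apply(matrix(stats::rnorm(nbad * nT, 0, 40), nbad, nT), 1, cumsum))
      if (nbad == 1) drift <- matrix(drift, 1, nT)
      for (c in seq_len(nch))
        arr[artTrial, , c] <- arr[artTrial, , c] + drift
    }
  }
  # ---- blink components (for IC cleaning tests) ----------------------
  blinkTopo <- blinkTemplate(mon)
  if (truth$artifact$blinkAmp > 0 && truth$artifact$blinkRate > 0) {
    hasBlink <- stats::runif(ntr) < truth$artifact$blinkRate
    lat <- stats::runif(ntr, times[1] + 200, times[nT] - 200)
    for (i in which(hasBlink)) {
      g <- truth$artifact$blinkAmp * exp(-(times - lat[i])^2 / (2 * 60^2))
      arr[i, , ] <- arr[i, , ] + outer(g, blinkTopo)
    }
  }
  trials$artifactTrial <- artTrial

  data <- aperm(arr, c(1, 3, 2))                # trial x channel x time
  trials <- generateBehaviour(truth, sp, trials)
  epochs <- newEpochSet(data, times, config$fsRaw, mon, trials,
                        subject = sprintf("S%02d", subject))
  if (truth$artifact$tmsAmp > 0)
    epochs <- injectTmsArtifact(epochs, params = list(
      amp = truth$artifact$tmsAmp, tau = truth$artifact$tau))
  truth$subjectParams <- sp
  list(epochs = epochs, trials = trialInfo(epochs), truth = truth,
       model = model)
}

#' Generate a multi-subject study
#'
#' @param config a \code{sessionConfig()} with \code{nSubjects} set.
#' @param truth a \code{groundTruth()}.
#' @param model optional shared \linkS4class{SourceModel}.
#' @return list of per-subject session lists (see \code{generateSession}).
#' @export
generateStudy <- function(config, truth, model = NULL) {
  if (is.null(model)) {
    mon <- montageSubset(config$nChannels)
    model <- buildToyModel(channels = mon, seed = config$seed)
  }
  lapply(seq_len(config$nSubjects), function(s)
    generateSession(config, truth, subject = s, model = model))
}

# Frontal blink topography: weights decaying away from the forehead.
blinkTemplate <- function(channels) {
  front <- c(0, 95, 20)   # just above the nasion
  d <- sqrt((channels$x - front[1])^2 + (channels$y - front[2])^2 +
              (channels$z - front[3])^2)
  exp(-d^2 / (2 * 45^2))
}

#' Attach behavioural outcomes to a trial table
#'
#' Go trials receive a reaction time drawn around the subject's mean RT
#' (itself linearly tied to the subject's planted gamma coupling
#' modulation during cue elaboration) and a miss flag at the configured
#' rate (missed trials have no RT); NoGo trials receive a false-alarm flag
#' at the configured rate.
#'
#' @param truth a \code{groundTruth()}.
#' @param subjectParams the per-subject parameter draw (as produced inside
#'   \code{generateSession}; must contain \code{rtMean}).
#' @param trials trial table with a \code{condition} column.
#' @return the trial table with \code{rt}, \code{fa}, \code{miss} columns.
#' @export
generateBehaviour <- function(truth, subjectParams, trials) {
  bh <- truth$behaviour
  if (bh$faRate < 0 || bh$missRate < 0 || bh$rtSd < 0)
    stop("behaviour rates and sds must be non-negative")
  n <- nrow(trials)
  trials$rt <- NA_real_
  trials$fa <- FALSE
  trials$miss <- FALSE
  isGo <- trials$condition == "Go"
  trials$miss[isGo] <- stats::runif(sum(isGo)) < bh$missRate
  got <- isGo & !trials$miss
  trials$rt[got] <- subjectParams$rtMean + stats::rnorm(sum(got), 0, bh$rtSd)
  trials$fa[!isGo] <- stats::runif(sum(!isGo)) < bh$faRate
  trials
}

#' Inject a TMS pulse artifact
#'
#' Adds a large decaying transient over -1..+10 ms on TMS trials only (the
#' segment downstream preprocessing excises and re-interpolates). Channel
#' weights vary deterministically across the montage.
#'
#' @param epochs an \linkS4class{EpochSet} whose trial table has a
#'   \code{tms} column.
#' @param params list with \code{amp} (uV) and \code{tau} (ms decay
#'   constant); \code{amp = 0} returns the input unchanged.
#' @param span artifact span in ms.
#' @return the modified \linkS4class{EpochSet}.
#' @export
injectTmsArtifact <- function(epochs, params = list(amp = 2000, tau = 3),
                              span = c(-1, 10)) {
  if (params$amp == 0) return(epochs)
  tmsIdx <- which(trialInfo(epochs)$tms)
  if (!length(tmsIdx)) return(epochs)
  times <- epochs@times
  ti <- which(times >= span[1] & times <= span[2])
  if (!length(ti)) return(epochs)
  nch <- nChannels(epochs)
  wch <- 1 + 0.3 * sin(seq_len(nch))
  g <- params$amp * exp(-(times[ti] - span[1]) / params$tau)
  patch <- outer(wch, g)                       # channel x span
  d <- epochs@data
  d[tmsIdx, , ti] <- d[tmsIdx, , ti] +
    array(rep(patch, each = length(tmsIdx)),
          c(length(tmsIdx), nch, length(ti)))
  epochs@data <- d
  epochs
}

#' Save / load a session container
#'
#' Sessions persist as an RDS payload (epoch array and model) with a JSON
#' sidecar carrying the trial table and ground-truth parameters, so trial
#' metadata stays human-readable.
#'
#' @param session a session list from \code{generateSession}.
#' @param path directory to write into (created if needed).
#' @return \code{saveSession}: the path, invisibly. \code{loadSession}: the
#'   session list.
#' @export
saveSession <- function(session, path) {
  dir.create(path, showWarnings = FALSE, recursive = TRUE)
  saveRDS(list(epochs = session$epochs, model = session$model),
          file.path(path, "session.rds"))
  sidecar <- list(trials = session$trials,
                  truth = rapply(unclass(session$truth), unclass, how = "replace"))
  jsonlite::write_json(sidecar, file.path(path, "session.json"),
                       auto_unbox = TRUE, digits = NA, force = TRUE)
  invisible(path)
}

#' @rdname saveSession
#' @export
loadSession <- function(path) {
  payload <- readRDS(file.path(path, "session.rds"))
  sidecar <- jsonlite::read_json(file.path(path, "session.json"),
                                 simplifyVector = TRUE)
  list(epochs = payload$epochs, model = payload$model,
       trials = trialInfo(payload$epochs), truthSidecar = sidecar$truth)
}
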
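# Shared fixtures and independent oracles, all generated in code.

# Small, fast session settings used throughout the unit tests.
quickConfig <- function(nTrialsPerCell = 6, fsRaw = 500, nChannels = 12,
                        seed = 1, ...) {
  sessionConfig(nTrialsPerCell = nTrialsPerCell, fsRaw = fsRaw,
                fsOut = fsRaw, nChannels = nChannels, seed = seed, ...)
}

# Ground truth with every stochastic and planted element switched off;
# named arguments in ... override individual fields.
silentTruth <- function(...) {
  base <- list(
    tepAmpGo = c(P30 = 0, P60 = 0, N100 = 0),
    tepAmpNoGo = c(P30 = 0, P60 = 0, N100 = 0),
    erpAmpGo = c("FIX-P1" = 0, "FIX-N1" = 0, "CUE-N1" = 0, "CUE-P1" = 0,
                 "CUE-N2" = 0),
    erpAmpNoGo = c("FIX-P1" = 0, "FIX-N1" = 0, "CUE-N1" = 0, "CUE-P1" = 0,
                   "CUE-N2" = 0),
    oscAmp = c(theta = 0, alpha = 0, beta = 0, gamma = 0),
    sourceNoiseSd = 0, sensorNoiseSd = 0,
    subjectDiffSd = 0, subjectBaseSd = 0,
    n100Link = list(targetDiff = 0, thetaBeta = 0, gammaBeta = 0,
                    noiseSd = 0),
    behaviour = list(rtIntercept = 531, rtSd = 0, faRate = 0, missRate = 0,
                     rtGammaCueCoef = 0, rtSubjectSd = 0),
    artifact = list(tmsAmp = 0, tau = 3, blinkAmp = 0, blinkRate = 0,
                    muscleAmp = 0))
  do.call(groundTruth, utils::modifyList(base, list(...)))
}

# Build an EpochSet directly from an array (bypassing the generator).
epochsFromArray <- function(data, fs = 1000, tms = NULL, condition = NULL,
                            window = NULL) {
  ntr <- dim(data)[1]; nch <- dim(data)[2]; nT <- dim(data)[3]
  if (is.null(window)) window <- c(-(nT - 1) / 2, (nT - 1) / 2) * 1000 / fs
  times <- seq(window[1], window[2], length.out = nT)
  mon <- if (nch >= 10) montageSubset(nch) else
    standardMontage()[seq_len(nch), , drop = FALSE]
  if (is.null(tms)) tms <- rep(TRUE, ntr)
  if (is.null(condition)) condition <- rep(c("Go", "NoGo"), length.out = ntr)
  trials <- data.frame(condition = condition, tms = tms,
                       stringsAsFactors = FALSE)
  methods::new("EpochSet", data = data, times = times, fs = fs,
               channels = mon, trials = trials, subject = "S01")
}

# Two-source model with near-diagonal mixing into the first two channels:
# lets tests observe each ROI source almost directly at a sensor.
diagonalToyModel <- function(nChannels = 12) {
  mon <- montageSubset(nChannels)
  L <- matrix(0.01, nChannels, 2)
  L[1, 1] <- 1   # channel 1 sees the SMA source
  L[2, 2] <- 1   # channel 2 sees the M1 source
  methods::new("SourceModel", leadfield = L,
               positions = rbind(c(-10, -2, 77), c(-31.3, -15.4, 75.8)),
               channels = mon, rois = list(M1 = 2L, SMA = 1L),
               noiseCov = diag(nChannels), snr = 3)
}

# --- independent oracles -------------------------------------------------

# Exact probability (dynamic programming) that a sequence of `len` iid
# Bernoulli(p) indicators contains a run of at least `k` successes.
runLengthExceedProb <- function(len, p, k) {
  if (k > len) return(0)
  # state = current run length (0..k-1); absorbing state = run >= k
  state <- c(1, numeric(k - 1))
  absorbed <- 0
  for (t in seq_len(len)) {
    newState <- numeric(k)
    newState[1] <- sum(state) * (1 - p)
    newState[2:k] <- state[1:(k - 1)] * p
    absorbed <- absorbed + state[k] * p
    state <- newState
  }
  absorbed
}

# Monte-Carlo distribution of the resultant length of n iid uniform unit
# phasors (the finite-sample PLV floor).
rayleighResultantOracle <- function(n, nsim = 20000, seed = 424242) {
  set.seed(seed)
  vapply(seq_len(nsim), function(i) {
    ph <- stats::runif(n, -pi, pi)
    Mod(mean(exp(1i * ph)))
  }, numeric(1))
}
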
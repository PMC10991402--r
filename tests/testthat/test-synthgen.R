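test_that("session configuration rejects impossible settings", {
  expect_error(sessionConfig(epochWindow = c(100, 1000)), "span the TMS pulse")
  expect_error(sessionConfig(fsRaw = 5000, fsOut = 1024), "divisible")
  expect_error(sessionConfig(nTrialsPerCell = 0), ">= 1")
  expect_error(sessionConfig(rejectionRate = -0.1), "rejectionRate")
  expect_error(groundTruth(plvBase = 2), "plvBase")
})

test_that("silent truth yields all-zero epochs and the design keeps the 4 x n cell structure", {
  ses <- generateSession(quickConfig(), silentTruth())
  expect_true(all(epochData(ses$epochs) == 0))
  tb <- table(trialInfo(ses$epochs)$condition, trialInfo(ses$epochs)$tms)
  expect_true(all(tb == 6))
  # the emulated protocol: 100 trials per cell, 400 in total
  cfg <- sessionConfig()
  expect_identical(cfg$nTrialsPerCell, 100)
  ses2 <- generateSession(sessionConfig(nTrialsPerCell = 100, fsRaw = 250,
                                        fsOut = 250, nChannels = 12),
                          silentTruth())
  tb2 <- table(trialInfo(ses2$epochs)$condition, trialInfo(ses2$epochs)$tms)
  expect_equal(as.vector(tb2), c(100, 100, 100, 100))
})

test_that("sessions are bit-identical under a fixed seed and additive over component sets", {
  cfg <- quickConfig(seed = 42)
  tr <- groundTruth()
  a <- generateSession(cfg, tr)
  b <- generateSession(cfg, tr)
  expect_identical(epochData(a$epochs), epochData(b$epochs))
  expect_identical(trialInfo(a$epochs), trialInfo(b$epochs))

  # additivity: with noise and oscillations off, a TEP-only and an ERP-only
  # truth sum to the combined truth under matching seeds
  tepOnly <- silentTruth(tepAmpGo = c(P30 = 5, P60 = 3.5, N100 = -4),
                         tepAmpNoGo = c(P30 = 5, P60 = 3.5, N100 = -4.884))
  erpOnly <- silentTruth(erpAmpGo = c("FIX-P1" = 3, "FIX-N1" = -2.5,
                                      "CUE-N1" = -2, "CUE-P1" = 3,
                                      "CUE-N2" = -4.386))
  both <- silentTruth(tepAmpGo = c(P30 = 5, P60 = 3.5, N100 = -4),
                      tepAmpNoGo = c(P30 = 5, P60 = 3.5, N100 = -4.884),
                      erpAmpGo = c("FIX-P1" = 3, "FIX-N1" = -2.5,
                                   "CUE-N1" = -2, "CUE-P1" = 3,
                                   "CUE-N2" = -4.386))
  eA <- epochData(generateSession(cfg, tepOnly)$epochs)
  eB <- epochData(generateSession(cfg, erpOnly)$epochs)
  eAB <- epochData(generateSession(cfg, both)$epochs)
  expect_equal(eAB, eA + eB, tolerance = 1e-12)
})

test_that("behavioural outcomes follow the configured linear model and rates", {
  trials <- data.frame(condition = rep(c("Go", "NoGo"), each = 10000),
                       stringsAsFactors = FALSE)
  tr <- groundTruth()
  tr$behaviour$rtSd <- 0
  set.seed(1)
  out <- generateBehaviour(tr, list(rtMean = 531), trials)
  expect_true(all(out$rt[out$condition == "Go" & !out$miss] == 531))
  expect_true(all(is.na(out$rt[out$condition == "NoGo"])))

  # CLT bound on the RT mean at the configured 531 +/- 75 ms
  tr2 <- groundTruth()
  tr2$behaviour$missRate <- 0
  set.seed(2)
  out2 <- generateBehaviour(tr2, list(rtMean = 531), trials)
  rt <- out2$rt[out2$condition == "Go"]
  expect_lt(abs(mean(rt) - 531), 3 * 75 / sqrt(10000))
  expect_lt(abs(sd(rt) - 75), 5)

  # FA count binomially consistent with rate 0.0076 over 10,000 NoGo trials
  nFA <- sum(out2$fa[out2$condition == "NoGo"])
  ci <- qbinom(c(0.0005, 0.9995), 10000, 0.0076)
  expect_gte(nFA, ci[1]); expect_lte(nFA, ci[2])
  expect_error(generateBehaviour(silentTruth(
    behaviour = list(rtIntercept = 531, rtSd = 75, faRate = -1,
                     missRate = 0, rtGammaCueCoef = 0, rtSubjectSd = 0)),
    list(rtMean = 531), trials), "non-negative")
})

test_that("the pulse artifact is confined to TMS trials and the excision span", {
  ses <- generateSession(quickConfig(), silentTruth())
  ep0 <- ses$epochs
  expect_identical(epochData(injectTmsArtifact(ep0, list(amp = 0, tau = 3))),
                   epochData(ep0))
  ep <- injectTmsArtifact(ep0, list(amp = 1000, tau = 3))
  d <- epochData(ep)
  tms <- trialInfo(ep)$tms
  times <- epochTimes(ep)
  inSpan <- times >= -1 & times <= 10
  expect_true(all(d[!tms, , ] == 0))
  mx_in <- max(abs(d[tms, , inSpan]))
  mx_out <- max(abs(d[tms, , !inSpan]), 1e-12)
  expect_gte(mx_in / mx_out, 10)
})

test_that("downstream PLV is monotone in the planted coupling strength", {
  # near-diagonal two-source model: sensors 1 and 2 observe the two ROI
  # sources directly, so the measured PLV reflects the planted von Mises
  # coupling without inverse-model crosstalk
  mdl <- diagonalToyModel(12)
  grid <- c(0, 0.25, 0.5, 0.75, 1)
  got <- vapply(grid, function(r) {
    pd <- matrix(0, 4, 4, dimnames = dimnames(defaultPlvDiff()))
    tr <- silentTruth(plvBase = r, plvDiff = pd,
                      oscAmp = c(theta = 3, alpha = 0, beta = 0, gamma = 0),
                      plvCalibration = "none")
    cfg <- sessionConfig(nTrialsPerCell = 25, fsRaw = 250, fsOut = 250,
                         nChannels = 12, seed = 7)
    ses <- generateSession(cfg, tr, model = mdl)
    d <- epochData(ses$epochs)
    tfA <- morletTF(d[, 1, ], epochTimes(ses$epochs), 250, freqs = 4:7)
    tfB <- morletTF(d[, 2, ], epochTimes(ses$epochs), 250, freqs = 4:7)
    p <- plv(tfA, tfB)
    mean(p$plv[p$valid])
  }, numeric(1))
  expect_true(all(diff(got) > 0))
  expect_gt(got[5], 0.95)            # full coupling measures near 1
  expect_lt(got[1], 0.35)            # independence sits near the floor
})

test_that("the rejection knob plants the configured fraction of gross-artifact trials", {
  cfg <- quickConfig(nTrialsPerCell = 50, rejectionRate = 0.04, seed = 9)
  tr <- silentTruth(sensorNoiseSd = 1)
  ses <- generateSession(cfg, tr)
  res <- rejectTrials(ses$epochs, threshold = 500)
  planted <- sum(trialInfo(ses$epochs)$artifactTrial)
  ci <- qbinom(c(0.0005, 0.9995), 200, 0.04)
  expect_gte(planted, ci[1]); expect_lte(planted, ci[2])
  expect_identical(sort(res$report$rejectedIdx),
                   which(trialInfo(ses$epochs)$artifactTrial))
})

test_that("sessions round-trip through the on-disk container", {
  ses <- generateSession(quickConfig(seed = 5), groundTruth())
  path <- file.path(tempdir(), "ses-roundtrip")
  saveSession(ses, path)
  back <- loadSession(path)
  expect_identical(epochData(back$epochs), epochData(ses$epochs))
  expect_identical(trialInfo(back$epochs), trialInfo(ses$epochs))
  expect_true(file.exists(file.path(path, "session.json")))
  unlink(path, recursive = TRUE)
})
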
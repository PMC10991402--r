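test_that("cubic excision reproduces smooth signals and removes confined spikes", {
  fs <- 1000
  times <- seq(-200, 200)
  nT <- length(times)
  mk <- function(trace) {
    d <- array(rep(trace, each = 2), c(2, 1, nT))
    epochsFromArray(d, fs = fs, tms = c(TRUE, FALSE), window = c(-200, 200))
  }
  # a cubic polynomial is reconstructed exactly
  cub <- 2 + 0.01 * times - 1e-4 * times^2 + 2e-6 * times^3
  out <- exciseInterpolate(mk(cub))
  expect_equal(epochData(out)[1, 1, ], cub, tolerance = 1e-9)
  # constant signal with a large spike inside the span -> constant again
  spiky <- rep(3, nT); spiky[times >= 0 & times <= 5] <- 1000
  out2 <- exciseInterpolate(mk(spiky))
  expect_equal(epochData(out2)[1, 1, ], rep(3, nT), tolerance = 1e-9)
  # non-TMS trials untouched
  expect_identical(epochData(out2)[2, 1, ], spiky)
  # sinusoid: interpolation error bounded by the directly fitted cubic
  sine <- sin(2 * pi * 10 * times / 1000)
  out3 <- exciseInterpolate(mk(sine), span = c(-1, 10), flank = 20)
  spanIdx <- which(times >= -1 & times <= 10)
  flankIdx <- which((times >= -21 & times < -1) | (times > 10 & times <= 30))
  fit <- lm(y ~ poly(t, 3, raw = TRUE),
            data = data.frame(y = sine[flankIdx], t = times[flankIdx]))
  oracle <- predict(fit, newdata = data.frame(t = times[spanIdx]))
  expect_equal(epochData(out3)[1, 1, spanIdx], unname(oracle),
               tolerance = 1e-8)
  # span at the epoch edge has no flanking support
  expect_error(exciseInterpolate(mk(sine), span = c(-200, -190)),
               "epoch edge")
})

test_that("band-pass plus notch meets its magnitude and phase contract", {
  fs <- 1000
  times <- seq(-1000, 1000)
  tone <- function(f) sin(2 * pi * f * times / 1000)
  mk <- function(trace) epochsFromArray(array(trace, c(1, 1, length(times))),
                                        fs = fs, tms = FALSE)
  mid <- abs(times) < 700                  # away from edges
  amp <- function(f) {
    out <- bandpassNotch(mk(tone(f)))
    max(abs(epochData(out)[1, 1, mid]))
  }
  expect_gt(amp(10), 10^(-1 / 20))         # >= -1 dB at 10 Hz
  expect_gt(amp(20), 10^(-1 / 20))         # >= -1 dB at 20 Hz
  expect_lt(abs(amp(10) - 1), 0.12)
  # notch: steady-state residual in the epoch centre (outside the ring-in
  # transient of the narrow notch, whose time constant is ~0.22 s)
  ctr <- abs(times) <= 300
  resid50 <- max(abs(epochData(bandpassNotch(mk(tone(50))))[1, 1, ctr]))
  expect_lte(resid50, 0.1)                 # <= -20 dB at the notch
  # DC is removed by the high-pass edge
  dc <- bandpassNotch(mk(rep(5, length(times))))
  expect_lt(abs(mean(epochData(dc)[1, 1, mid])), 0.05)
  # zero phase: cross-correlation with the input peaks at lag 0
  y <- epochData(bandpassNotch(mk(tone(10))))[1, 1, mid]
  cc <- ccf(y, tone(10)[mid], lag.max = 20, plot = FALSE)
  expect_equal(as.vector(cc$lag)[which.max(cc$acf)], 0)
})

test_that("downsampling preserves passband amplitude and the time origin", {
  times <- seq(-1000, 1000, by = 0.2)      # 5000 Hz
  tone <- sin(2 * pi * 10 * times / 1000)
  ep <- epochsFromArray(array(tone, c(1, 1, length(times))), fs = 5000,
                        tms = FALSE, window = c(-1000, 1000))
  expect_identical(length(epochTimes(ep)), 10001L)
  down <- downsampleEpochs(ep, 1000)
  expect_identical(length(epochTimes(down)), 2001L)
  expect_true(0 %in% epochTimes(down))
  mid <- abs(epochTimes(down)) < 700
  expect_lt(abs(max(abs(epochData(down)[1, 1, mid])) - 1), 0.02)
  # fsOut equal to fs is the identity
  expect_identical(epochData(downsampleEpochs(ep, 5000)), epochData(ep))
})

test_that("demeaning zeroes every trial-channel trace and is idempotent", {
  set.seed(3)
  d <- array(rnorm(4 * 3 * 100, mean = 7), c(4, 3, 100))
  ep <- epochsFromArray(d, fs = 100, window = c(-495, 495))
  out <- demeanEpochs(ep)
  expect_lt(max(abs(rowMeans(epochData(out), dims = 2))), 1e-10)
  expect_equal(epochData(demeanEpochs(out)), epochData(out),
               tolerance = 1e-14)
  cst <- epochsFromArray(array(7, c(1, 1, 50)), fs = 100, window = c(-245, 245))
  expect_true(all(epochData(demeanEpochs(cst)) == 0))
})

test_that("trial rejection drops exactly the trials breaching the threshold", {
  set.seed(4)
  d <- array(rnorm(6 * 4 * 200, sd = 20), c(6, 4, 200))
  d[3, 2, 100] <- 10000
  ep <- epochsFromArray(d, fs = 200, window = c(-497.5, 497.5))
  res <- rejectTrials(ep, threshold = 500)
  expect_identical(res$report$rejectedIdx, 3L)
  expect_identical(nTrials(res$epochs), 5L)
  none <- rejectTrials(ep, threshold = Inf)
  expect_identical(nTrials(none$epochs), 6L)
  expect_identical(none$report$nRejected, 0L)
})

test_that("component cleaning reconstructs unflagged data and removes a planted blink", {
  # identity: thresholds no rule can reach -> perfect back-projection
  set.seed(5)
  nch <- 8; ntr <- 6; nT <- 300
  src <- rbind(sin(2 * pi * 7 * (1:(ntr * nT)) / 200),
               sign(sin(2 * pi * 3 * (1:(ntr * nT)) / 200)),
               matrix(rnorm(6 * ntr * nT), 6))
  A <- matrix(rnorm(nch * 8), nch)
  d <- array(0, c(ntr, nch, nT))
  for (i in seq_len(ntr))
    d[i, , ] <- A %*% src[, ((i - 1) * nT + 1):(i * nT)]
  ep <- epochsFromArray(d, fs = 200, window = c(-747.5, 747.5))
  quiet <- icaClean(ep, rules = list(decayRatio = Inf, frontalRatio = Inf,
                                     musclePowerFrac = Inf))
  expect_length(quiet$report$removedComponents, 0)
  expect_equal(epochData(quiet$epochs), epochData(ep), tolerance = 1e-6)

  # flagging everything leaves only the channel means
  allGone <- icaClean(ep, flagAll = TRUE)
  g <- epochData(allGone$epochs)
  chMean <- apply(g, 2, mean)
  resid <- sweep(g, 2, chMean)
  expect_lt(max(abs(resid)), 1e-6 * max(abs(d)))

  # planted frontal blink is identified and suppressed
  cfg <- quickConfig(nTrialsPerCell = 8, fsRaw = 500, nChannels = 12, seed = 6)
  tr <- silentTruth(sensorNoiseSd = 2,
                    oscAmp = c(theta = 3, alpha = 3, beta = 2, gamma = 1),
                    artifact = list(tmsAmp = 0, tau = 3, blinkAmp = 120,
                                    blinkRate = 0.8, muscleAmp = 0))
  ses <- generateSession(cfg, tr)
  tpl <- tmsgonogo:::blinkTemplate(channelInfo(ses$epochs))
  res <- icaClean(ses$epochs, rules = list(blinkTemplate = tpl,
                                           decayRatio = Inf,
                                           musclePowerFrac = Inf))
  expect_gt(length(res$report$removedComponents), 0)
  topo <- res$decomposition$A[, res$report$removedComponents, drop = FALSE]
  expect_gt(max(abs(cor(topo, tpl))), 0.9)
  # variance along the blink topography drops by >= 80%
  proj <- function(e) {
    m <- matrix(aperm(epochData(e), c(2, 1, 3)), nrow = nChannels(e))
    var(drop(crossprod(tpl, m)))
  }
  expect_lt(proj(res$epochs) / proj(ses$epochs), 0.2)
})
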
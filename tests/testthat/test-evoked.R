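test_that("evoked averaging follows the averaging law", {
  set.seed(31)
  nT <- 200
  sig <- sin(2 * pi * 5 * seq_len(nT) / nT)
  # identical trials average to the trial itself
  d <- array(rep(sig, each = 4), c(4, 1, nT))
  ep <- epochsFromArray(d, fs = 100, condition = rep("Go", 4),
                        tms = rep(TRUE, 4), window = c(-995, 995))
  expect_equal(averageEvoked(ep, "Go", TRUE)[1, ], sig, tolerance = 1e-12)
  # a trial and its negation cancel
  d2 <- array(0, c(2, 1, nT))
  d2[1, 1, ] <- sig
  d2[2, 1, ] <- -sig
  ep2 <- epochsFromArray(d2, fs = 100, condition = rep("Go", 2),
                         window = c(-995, 995))
  expect_true(all(abs(averageEvoked(ep2, "Go")) < 1e-12))
  # white-noise residual shrinks like sigma/sqrt(N)
  N <- 400; sigma <- 2
  d3 <- array(rep(sig, each = N), c(N, 1, nT)) +
    array(rnorm(N * nT, 0, sigma), c(N, 1, nT))
  ep3 <- epochsFromArray(d3, fs = 100, condition = rep("Go", N),
                         window = c(-995, 995))
  resid <- averageEvoked(ep3, "Go")[1, ] - sig
  expect_lt(abs(sd(resid) / (sigma / sqrt(N)) - 1), 0.25)
  expect_error(averageEvoked(ep3, "NoGo"), "no trials")
})

test_that("TEP isolation is the exact inverse of additive composition", {
  expect_equal(isolateTep(matrix(1:6, 2), matrix(0, 2, 3)), matrix(1:6, 2))
  expect_true(all(isolateTep(matrix(1:6, 2), matrix(1:6, 2)) == 0))
  expect_error(isolateTep(matrix(0, 2, 3), matrix(0, 3, 2)), "shapes")

  # noiseless generator with narrow components: exact recovery of the
  # planted TMS-evoked field, reconstructed independently from the truth
  tr <- silentTruth(tepAmpGo = c(P30 = 5, P60 = 3.5, N100 = -4),
                    tepAmpNoGo = c(P30 = 5, P60 = 3.5, N100 = -4.884),
                    tepWidth = c(P30 = 3, P60 = 3, N100 = 3))
  cfg <- sessionConfig(nTrialsPerCell = 3, fsRaw = 1000, fsOut = 1000,
                       nChannels = 20, seed = 8)
  ses <- generateSession(cfg, tr)
  ep <- ses$epochs
  ev <- evokedSet(ep)
  expect_equal(ev@tep$Go, ev@terp$Go - ev@erp$Go, tolerance = 1e-12)
  # independent reconstruction of the planted field on the cluster trace
  mon <- channelInfo(ep)
  ci <- match(c("Fz", "FCz", "FC1", "C1", "C3"), mon$name)
  L <- leadfield(ses$model)
  w <- 0.4 * rowMeans(L[, roiIndices(ses$model)$M1, drop = FALSE])
  expected <- function(amp, lat) {
    g <- exp(-(epochTimes(ep) - lat)^2 / (2 * 3^2))
    amp * g   # cluster-mean-normalized topography contributes 1 by design
  }
  tr30 <- colMeans(ev@tep$Go[ci, , drop = FALSE])
  expect_equal(max(abs(tr30[epochTimes(ep) >= 10 & epochTimes(ep) <= 40])),
               5, tolerance = 1e-9)
})

test_that("TEP peaks use the max-absolute rule with the earlier-sample tie break", {
  times <- seq(-1000, 1000)
  mon <- montageSubset(12)
  cl <- c("Fz", "FCz", "FC1", "C1", "C3")
  mk <- function(trace) matrix(rep(trace, each = 12), 12)
  # planted N100: -5 uV at 100 ms
  tep <- mk(-5 * exp(-(times - 100)^2 / (2 * 15^2)))
  pk <- extractTepPeaks(tep, times, channels = mon, cluster = cl,
                        condition = "Go")
  expect_equal(pk$amplitude[pk$component == "N100"], 5)
  expect_equal(pk$latency[pk$component == "N100"], 100)
  expect_equal(pk$value[pk$component == "N100"], -5)
  # flat zero trace: amplitude 0, latency at the window start
  pk0 <- extractTepPeaks(mk(numeric(length(times))), times, channels = mon,
                         cluster = cl)
  expect_true(all(pk0$amplitude == 0))
  expect_equal(pk0$latency, c(10, 40, 70))
  # two local extrema: the larger absolute value wins; exact ties go to the
  # earlier sample (verified against an exhaustive scan)
  tr2 <- numeric(length(times))
  tr2[times == 80] <- 3; tr2[times == 120] <- -4
  pk2 <- extractTepPeaks(mk(tr2), times, channels = mon, cluster = cl)
  expect_equal(pk2$latency[pk2$component == "N100"], 120)
  tr3 <- numeric(length(times))
  tr3[times == 80] <- 4; tr3[times == 120] <- -4
  pk3 <- extractTepPeaks(mk(tr3), times, channels = mon, cluster = cl)
  toi <- which(times >= 70 & times <= 130)
  scan <- toi[which.max(abs(tr3[toi]))]    # exhaustive-scan oracle
  expect_equal(pk3$latency[pk3$component == "N100"], times[scan])
  expect_equal(pk3$latency[pk3$component == "N100"], 80)
})

test_that("ERP peaks use the peak-to-peak rule over their windows", {
  times <- seq(-1000, 1000)
  mon <- montageSubset(12)
  cl <- c("AFz", "Fz", "F1", "F2", "FCz", "FC1", "FC2", "Cz")
  mk <- function(trace) matrix(rep(trace, each = 12), 12)
  # sinusoid spanning a window: peak-to-peak = 2a
  a <- 3
  erp <- mk(a * sin(2 * pi * (times + 850) / 40))
  pk <- extractErpPeaks(erp, times, channels = mon, cluster = cl)
  expect_equal(pk$amplitude[pk$component == "FIX-P1"], 2 * a,
               tolerance = 1e-3)
  # monotone ramp: |end - start|
  ramp <- mk(0.01 * times)
  pkr <- extractErpPeaks(ramp, times, channels = mon, cluster = cl)
  expect_equal(pkr$amplitude[pkr$component == "CUE-N2"], 0.01 * 300,
               tolerance = 1e-9)
})

test_that("the planted CUE-N2 condition difference is recovered from generated data", {
  # the generated Go/NoGo difference in the CUE-N2 window (planted 1.386 uV
  # via the component amplitudes) is recovered within the averaging CI
  tr <- silentTruth(erpAmpGo = c("FIX-P1" = 3, "FIX-N1" = -2.5,
                                 "CUE-N1" = -2, "CUE-P1" = 3,
                                 "CUE-N2" = -4.386),
                    erpAmpNoGo = c("FIX-P1" = 3, "FIX-N1" = -2.5,
                                   "CUE-N1" = -2, "CUE-P1" = 2.2,
                                   "CUE-N2" = -3),
                    sensorNoiseSd = 1)
  cfg <- sessionConfig(nTrialsPerCell = 40, fsRaw = 1000, fsOut = 1000,
                       nChannels = 20, seed = 9)
  ses <- generateSession(cfg, tr)
  ev <- evokedSet(ses$epochs)
  pk <- peakTable(ev)
  n2 <- pk[pk$component == "CUE-N2", ]
  diffGoNoGo <- n2$amplitude[n2$condition == "Go"] -
    n2$amplitude[n2$condition == "NoGo"]
  # cluster-average noise after 40-trial averaging is ~ 1/sqrt(40*8) uV
  expect_lt(abs(diffGoNoGo - 1.386), 3 * 1 / sqrt(40 * 8) + 0.05)
})
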
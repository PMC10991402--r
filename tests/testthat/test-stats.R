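test_that("the normality-gated paired test keeps its level and picks the right branch", {
  expect_equal(pairedTest(1:10, 1:10)$p, 1)
  # type-I rate under normal differences, n = 22
  set.seed(41)
  rej <- mean(replicate(400, {
    x <- rnorm(22); y <- rnorm(22)
    pairedTest(x, y)$p < 0.05
  }))
  expect_gt(rej, 0.02); expect_lt(rej, 0.09)
  # heavy-tailed differences steer onto the Wilcoxon branch most of the time
  set.seed(42)
  meth <- replicate(60, pairedTest(rcauchy(22), rnorm(22))$method)
  expect_gt(mean(meth == "wilcoxon signed-rank"), 0.5)
})

test_that("cluster permutation finds planted neighbourhood effects and respects exchange symmetry", {
  mon <- standardMontage()
  nb <- channelNeighbours(mon)
  set.seed(43)
  a <- matrix(rnorm(22 * 62), 22)
  expect_identical(nrow(clusterPermutation(a, a, mon, neighbours = nb,
                                           nPerm = 100)$clusters), 0L)
  # plant a shift on a 5-channel fronto-central neighbourhood
  target <- match(c("Fz", "FCz", "FC1", "C1", "C3"), mon$name)
  b <- matrix(rnorm(22 * 62), 22)
  b[, target] <- b[, target] + 1.5
  res <- clusterPermutation(b, a, mon, neighbours = nb, nPerm = 500,
                            seed = 7)
  expect_gt(nrow(res$clusters), 0)
  best <- which.min(res$clusters$p)
  expect_lt(res$clusters$p[best], 0.05)
  hit <- strsplit(res$clusters$channels[best], "\\+")[[1]]
  expect_gte(length(intersect(hit, c("Fz", "FCz", "FC1", "C1", "C3"))), 3)
  # swapping the conditions flips the statistics, not the p-values
  swp <- clusterPermutation(a, b, mon, neighbours = nb, nPerm = 500,
                            seed = 7)
  expect_equal(swp$tObs, -res$tObs, tolerance = 1e-12)
  expect_equal(sort(swp$clusters$p), sort(res$clusters$p), tolerance = 1e-12)
  expect_error(clusterPermutation(a, b, channels = NULL), "neighbourhood")
})

test_that("the consecutive-timepoint rule reports only runs of the required length", {
  set.seed(44)
  a <- matrix(rnorm(22 * 200), 22)
  expect_identical(nrow(runsPermutation(a, a, nPerm = 50)$spans), 0L)
  # planted 30-sample difference window
  b <- a
  b[, 101:130] <- b[, 101:130] + 1.2
  res <- runsPermutation(b, a, times = seq(-99, 100), minRun = 10,
                         nPerm = 200, seed = 3)
  expect_gt(nrow(res$spans), 0)
  expect_true(all(res$spans$nSamples >= 10))
  # the detected span overlaps the plant (samples 101..130 = times 2..31)
  expect_true(any(res$spans$start <= 31 & res$spans$end >= 2))
  expect_length(res$nullLongestRun, 200)
})

test_that("repeated-measures ANOVA matches its closed forms and the mlm oracle", {
  # all cells equal -> F = 0 everywhere
  d0 <- expand.grid(subject = 1:6, phase = c("a", "b"), band = c("x", "y", "z"))
  d0$plv <- 1
  out0 <- rmAnova(d0, "plv", c("phase", "band"))
  expect_true(all(out0$F == 0))
  expect_true(all(out0$p == 1))

  # two-level factor: F equals the squared paired t exactly
  set.seed(45)
  d1 <- expand.grid(subject = 1:12, cond = c("Go", "NoGo"))
  d1$y <- rnorm(24)
  out1 <- rmAnova(d1, "y", "cond", subject = "subject")
  tt <- t.test(d1$y[d1$cond == "Go"], d1$y[d1$cond == "NoGo"], paired = TRUE)
  expect_equal(out1$F, unname(tt$statistic)^2, tolerance = 1e-10)
  expect_equal(out1$p, tt$p.value, tolerance = 1e-10)

  # oracle: base R's mlm machinery on a 2 x 3 within design at n = 22
  set.seed(46)
  n <- 22
  dat <- expand.grid(subject = factor(1:n), A = c("a1", "a2"),
                     B = c("b1", "b2", "b3"))
  dat$y <- rnorm(nrow(dat)) + as.numeric(dat$A) * 0.4 +
    rnorm(nrow(dat), 0, 0.2)
  ours <- rmAnova(dat, "y", c("A", "B"))
  wide <- matrix(NA_real_, n, 6)
  idata <- expand.grid(B = factor(c("b1", "b2", "b3")),
                       A = factor(c("a1", "a2")))[, c("A", "B")]
  for (i in seq_len(n)) for (j in seq_len(6)) {
    wide[i, j] <- dat$y[dat$subject == levels(dat$subject)[i] &
                          dat$A == idata$A[j] & dat$B == idata$B[j]]
  }
  fit <- lm(wide ~ 1)
  # base R's mlm machinery, one within-effect at a time via the
  # orthogonal-transformation (M/X) interface
  mx <- list(A = list(M = ~ A + B, X = ~ B),
             B = list(M = ~ A + B, X = ~ A),
             "A:B" = list(M = ~ A * B, X = ~ A + B))
  for (eff in names(mx)) {
    av <- anova(fit, M = mx[[eff]]$M, X = mx[[eff]]$X, idata = idata,
                test = "Spherical")
    ourRow <- ours[ours$effect == eff, ]
    expect_equal(ourRow$F, av[["F"]][1], tolerance = 1e-8)
    expect_equal(ourRow$p, av[["Pr(>F)"]][1], tolerance = 1e-8)
    expect_equal(ourRow$pGG, av[["G-G Pr"]][1], tolerance = 1e-8)
    if (ourRow$df1 > 1 && !is.na(ourRow$mauchlyP)) {
      mt <- mauchly.test(fit, M = mx[[eff]]$M, X = mx[[eff]]$X,
                         idata = idata)
      expect_equal(ourRow$mauchlyP, mt$p.value, tolerance = 1e-6)
    }
  }
  expect_true(all(ours$petaSq >= 0 & ours$petaSq <= 1))
})

test_that("Sidak adjustment matches the product closed form", {
  expect_equal(sidakPosthoc(0, m = 7), 0)
  expect_equal(sidakPosthoc(0.017, m = 1), 0.017)
  expect_equal(sidakPosthoc(0.01, m = 4), 1 - 0.99^4)
  # brute force: 1 - prod(1 - p) over m identical comparisons
  p <- 0.035; m <- 6
  expect_equal(sidakPosthoc(p, m), 1 - prod(rep(1 - p, m)))
  expect_error(sidakPosthoc(1.4), "lie in")
})

test_that("the gated correlation picks Pearson or Spearman appropriately", {
  set.seed(47)
  x <- rnorm(22)
  r <- correlateGated(x, 2 * x)
  expect_equal(r$r, 1, tolerance = 1e-12)
  expect_identical(r$method, "pearson")
  # heavy-tailed monotone transform: Spearman branch, perfect rank correlation
  xc <- rcauchy(22)
  r2 <- correlateGated(xc, exp(xc) + xc^3)
  expect_identical(r2$method, "spearman")
  expect_equal(r2$r, 1, tolerance = 1e-12)
  # null level
  rej <- mean(replicate(400, correlateGated(rnorm(22), rnorm(22))$p < 0.05))
  expect_gt(rej, 0.02); expect_lt(rej, 0.09)
})

test_that("forward selection recovers dominant predictors and shows the expected null optimism", {
  set.seed(48)
  n <- 40
  X <- as.data.frame(matrix(rnorm(n * 5), n))
  names(X) <- paste0("x", 1:5)
  y <- 3 * X$x1 + rnorm(n, 0, 1e-4)
  fit <- stepwiseRegression(y, X)
  expect_identical(fit$selected, "x1")
  expect_equal(fit$coefficients$beta[fit$coefficients$term == "x1"], 3,
               tolerance = 1e-3)
  # single candidate equal to the response
  fit2 <- suppressWarnings(stepwiseRegression(y, data.frame(z = y)))
  expect_equal(fit2$coefficients$beta[fit2$coefficients$term == "z"], 1,
               tolerance = 1e-10)
  expect_lt(fit2$coefficients$p[fit2$coefficients$term == "z"], 1e-10)
  # selection optimism under the null: P(select >= 1 of 16) ~ 1 - 0.95^16
  set.seed(49)
  anySel <- mean(replicate(150, {
    Xn <- as.data.frame(matrix(rnorm(30 * 16), 30))
    length(stepwiseRegression(rnorm(30), Xn)$selected) > 0
  }))
  expected <- 1 - 0.95^16                 # ~ 0.56
  expect_lt(abs(anySel - expected), 0.15)
})
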
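#' Normality-gated paired comparison
#'
#' Shapiro-Wilk on the paired differences (alpha = 0.05) selects a paired
#' t-test when normality is tenable and a Wilcoxon signed-rank test
#' otherwise. Zero-variance differences (e.g. identical inputs) are a
#' degenerate case reported as p = 1 by convention.
#'
#' @param x,y paired numeric vectors.
#' @param alpha normality gate level.
#' @return list: \code{statistic}, \code{p}, \code{method}.
#' @export
pairedTest <- function(x, y, alpha = 0.05) {
  if (length(x) != length(y)) stop("x and y must be paired")
  d <- x - y
  if (length(d) < 2 || !is.finite(stats::sd(d)) || stats::sd(d) == 0)
    return(list(statistic = 0, p = 1,
                method = "degenerate (zero-variance differences)"))
  swp <- tryCatch(stats::shapiro.test(d)$p.value, error = function(e) 0)
  if (swp >= alpha) {
    tt <- stats::t.test(x, y, paired = TRUE)
    list(statistic = unname(tt$statistic), p = tt$p.value,
         method = "paired t-test")
  } else {
    wt <- suppressWarnings(stats::wilcox.test(x, y, paired = TRUE,
                                              exact = FALSE))
    list(statistic = unname(wt$statistic), p = wt$p.value,
         method = "wilcoxon signed-rank")
  }
}

# Vectorized paired t statistics: D is subjects x variables (differences).
pairedTMatrix <- function(D) {
  n <- nrow(D)
  m <- colMeans(D)
  v <- (colSums(D^2) - n * m^2) / (n - 1)
  v[v < 0] <- 0
  m / sqrt(v / n)
}

# Connected same-sign supra-threshold clusters (>= minSize channels).
# t: channel statistic vector; nb: neighbour list; returns list of index
# vectors.
findClusters <- function(t, crit, nb, minSize = 2) {
  supra <- which(abs(t) > crit & is.finite(t))
  if (length(supra) < minSize) return(list())
  inSet <- logical(length(t)); inSet[supra] <- TRUE
  seen <- logical(length(t))
  out <- list()
  for (s in supra) {
    if (seen[s]) next
    comp <- integer(); stack <- s
    seen[s] <- TRUE
    while (length(stack)) {
      v <- stack[[1]]; stack <- stack[-1]
      comp <- c(comp, v)
      for (w in nb[[v]]) {
        if (inSet[w] && !seen[w] && sign(t[w]) == sign(t[v])) {
          seen[w] <- TRUE
          stack <- c(stack, w)
        }
      }
    }
    if (length(comp) >= minSize) out[[length(out) + 1]] <- sort(comp)
  }
  out
}

#' Cluster-based sensor permutation test
#'
#' Paired comparison of two conditions over channels with family-wise error
#' control by cluster-mass permutation: channels whose paired t exceeds the
#' two-tailed p < 0.05 threshold are grouped into neighbourhood-connected,
#' same-sign clusters of at least two channels; the cluster statistic is
#' the sum of t within the cluster, and its p-value compares the observed
#' mass against the maximum null mass over within-subject sign-flip
#' permutations, with the add-one estimator
#' \eqn{p = (1 + \#\{null \ge obs\}) / (1 + n_{perm})}.
#'
#' @param a,b subjects x channels matrices (window-aggregated amplitudes
#'   per condition).
#' @param channels montage data.frame (used to build neighbours when
#'   \code{neighbours} is NULL).
#' @param neighbours optional precomputed \code{channelNeighbours()} list.
#' @param nPerm number of sign-flip permutations.
#' @param alpha cluster-forming threshold (two-tailed, per channel).
#' @param seed permutation seed.
#' @return object of class \code{"ClusterResult"}: \code{clusters}
#'   data.frame (channels, size, mass, p), \code{tObs}, \code{nullMax},
#'   settings.
#' @export
clusterPermutation <- function(a, b, channels = NULL, neighbours = NULL,
                               nPerm = 3000, alpha = 0.05, seed = 1) {
  if (!all(dim(a) == dim(b))) stop("a and b must have identical shape")
  n <- nrow(a)
  if (n < 2) stop("need at least two subjects")
  if (is.null(neighbours)) {
    if (is.null(channels)) stop("no channel neighbourhood defined")
    neighbours <- channelNeighbours(channels)
  }
  D <- a - b
  crit <- stats::qt(1 - alpha / 2, n - 1)
  tObs <- pairedTMatrix(D)
  obsClusters <- findClusters(tObs, crit, neighbours)
  obsMass <- vapply(obsClusters, function(ix) sum(tObs[ix]), numeric(1))
  set.seed(seed)
  S <- matrix(sample(c(-1, 1), nPerm * n, replace = TRUE), nPerm, n)
  M <- (S %*% D) / n
  ss <- colSums(D^2)
  V <- sweep(-n * M^2, 2, ss, "+") / (n - 1)
  V[V < 0] <- 0
  Tn <- M / sqrt(V / n)
  nullMax <- numeric(nPerm)
  for (j in seq_len(nPerm)) {
    cl <- findClusters(Tn[j, ], crit, neighbours)
    nullMax[j] <- if (length(cl))
      max(abs(vapply(cl, function(ix) sum(Tn[j, ix]), numeric(1)))) else 0
  }
  pvals <- vapply(obsMass, function(m)
    (1 + sum(nullMax >= abs(m))) / (1 + nPerm), numeric(1))
  chNames <- if (!is.null(channels)) channels$name else
    as.character(seq_along(tObs))
  clusters <- if (length(obsClusters)) data.frame(
    channels = vapply(obsClusters, function(ix)
      paste(chNames[ix], collapse = "+"), character(1)),
    size = lengths(obsClusters),
    mass = obsMass,
    p = pvals, stringsAsFactors = FALSE) else
      data.frame(channels = character(), size = integer(),
                 mass = numeric(), p = numeric())
  structure(list(clusters = clusters, clusterIdx = obsClusters, tObs = tObs,
                 nullMax = nullMax, nPerm = nPerm, alpha = alpha,
                 threshold = crit),
            class = "ClusterResult")
}

#' @export
print.ClusterResult <- function(x, ...) {
  cat("ClusterResult:", nrow(x$clusters), "cluster(s),",
      x$nPerm, "permutations\n")
  if (nrow(x$clusters)) print(x$clusters, row.names = FALSE)
  invisible(x)
}

#' Consecutive-timepoint permutation test on waveforms
#'
#' Point-by-point paired t-tests between two condition waveforms; spans of
#' at least \code{minRun} consecutive samples with p < alpha (two-tailed)
#' are reported as significant. Condition-label (sign-flip) permutations
#' provide the null distribution of the longest consecutive run for
#' diagnostics and a run-level p-value.
#'
#' @param a,b subjects x time matrices.
#' @param times optional time axis, ms (defaults to sample indices).
#' @param minRun minimum consecutive significant samples.
#' @param alpha pointwise two-tailed level.
#' @param nPerm number of permutations.
#' @param seed permutation seed.
#' @return object of class \code{"RunsResult"}: \code{spans} data.frame
#'   (start, end, nSamples, meanT, p), \code{tObs}, \code{pObs},
#'   \code{nullLongestRun}.
#' @export
runsPermutation <- function(a, b, times = NULL, minRun = 10, alpha = 0.05,
                            nPerm = 3000, seed = 1) {
  if (!all(dim(a) == dim(b))) stop("a and b must have identical shape")
  n <- nrow(a); nT <- ncol(a)
  if (is.null(times)) times <- seq_len(nT)
  D <- a - b
  tObs <- pairedTMatrix(D)
  pObs <- 2 * stats::pt(abs(tObs), n - 1, lower.tail = FALSE)
  runsOf <- function(sig) {
    r <- rle(sig)
    ends <- cumsum(r$lengths)
    starts <- ends - r$lengths + 1
    keep <- r$values & r$lengths >= minRun
    cbind(start = starts[keep], end = ends[keep])
  }
  obs <- runsOf(pObs < alpha & is.finite(pObs))
  set.seed(seed)
  S <- matrix(sample(c(-1, 1), nPerm * n, replace = TRUE), nPerm, n)
  M <- (S %*% D) / n
  ss <- colSums(D^2)
  V <- sweep(-n * M^2, 2, ss, "+") / (n - 1)
  V[V < 0] <- 0
  Tn <- M / sqrt(V / n)
  Pn <- 2 * stats::pt(abs(Tn), n - 1, lower.tail = FALSE)
  nullLongest <- apply(Pn < alpha, 1, function(sig) {
    r <- rle(sig)
    m <- r$lengths[r$values]
    if (length(m)) max(m) else 0L
  })
  spans <- if (nrow(obs)) data.frame(
    start = times[obs[, "start"]], end = times[obs[, "end"]],
    nSamples = obs[, "end"] - obs[, "start"] + 1L,
    meanT = apply(obs, 1, function(rr) mean(tObs[rr[1]:rr[2]])),
    p = vapply(obs[, "end"] - obs[, "start"] + 1L, function(len)
      (1 + sum(nullLongest >= len)) / (1 + nPerm), numeric(1)),
    stringsAsFactors = FALSE) else
      data.frame(start = numeric(), end = numeric(), nSamples = integer(),
                 meanT = numeric(), p = numeric())
  structure(list(spans = spans, tObs = tObs, pObs = pObs,
                 nullLongestRun = nullLongest, minRun = minRun,
                 alpha = alpha, nPerm = nPerm),
            class = "RunsResult")
}

#' @export
print.RunsResult <- function(x, ...) {
  cat("RunsResult:", nrow(x$spans), "significant span(s), minRun =",
      x$minRun, "\n")
  if (nrow(x$spans)) print(x$spans, row.names = FALSE)
  invisible(x)
}

# Orthonormal contrast matrix for a p-level factor (columns orthogonal to
# the constant and mutually orthonormal).
orthoContrasts <- function(p) {
  cm <- stats::contr.helmert(p)
  sweep(cm, 2, sqrt(colSums(cm^2)), "/")
}

#' Repeated-measures ANOVA with sphericity handling
#'
#' Full-factorial within-subject ANOVA on a long-format table. Each effect
#' is tested with the univariate F from its orthonormal-contrast-projected
#' data; sphericity is assessed per effect with Mauchly's test, the
#' Greenhouse-Geisser epsilon is reported and, when Mauchly rejects at
#' alpha = 0.05, the corrected p is the gated result. Partial eta-squared
#' accompanies every effect.
#'
#' @param data long data.frame.
#' @param dv name of the dependent-variable column.
#' @param within character vector of within-subject factor column names.
#' @param subject name of the subject identifier column.
#' @return data.frame with one row per effect: \code{effect}, \code{df1},
#'   \code{df2}, \code{F}, \code{p}, \code{epsGG}, \code{pGG},
#'   \code{mauchlyP}, \code{pUsed}, \code{petaSq}.
#' @export
rmAnova <- function(data, dv, within, subject = "subject") {
  for (f in c(within, subject)) data[[f]] <- factor(data[[f]])
  lvls <- lapply(within, function(f) levels(data[[f]]))
  names(lvls) <- within
  subjects <- levels(data[[subject]])
  n <- length(subjects)
  if (n < 2) stop("need at least two subjects")
  # wide matrix: columns ordered so the *last* factor varies fastest,
  # matching kronecker() ordering of the contrast matrices
  grid <- rev(expand.grid(rev(lvls), stringsAsFactors = FALSE))
  key <- apply(grid, 1, paste, collapse = "\r")
  dataKey <- apply(data[, within, drop = FALSE], 1, paste, collapse = "\r")
  Y <- matrix(NA_real_, n, nrow(grid))
  for (i in seq_len(n)) {
    rows <- data[[subject]] == subjects[i]
    m <- match(key, dataKey[rows])
    if (anyNA(m)) stop("design is not complete for subject ", subjects[i])
    Y[i, ] <- data[[dv]][rows][m]
  }
  effects <- unlist(lapply(seq_along(within), function(k)
    utils::combn(within, k, simplify = FALSE)), recursive = FALSE)
  out <- lapply(effects, function(eff) {
    M <- Reduce(kronecker, lapply(within, function(f) {
      p <- length(lvls[[f]])
      if (f %in% eff) orthoContrasts(p) else matrix(1 / sqrt(p), p, 1)
    }))
    Tm <- Y %*% M
    df1 <- ncol(Tm)
    mu <- colMeans(Tm)
    ssE <- n * sum(mu^2)
    R <- sweep(Tm, 2, mu)
    ssErr <- sum(R^2)
    df2 <- (n - 1) * df1
    if (ssE < 1e-24 && ssErr < 1e-24) {
      Fv <- 0; pv <- 1; eps <- 1; pGG <- 1; mau <- NA_real_; peta <- 0
    } else {
      Fv <- (ssE / df1) / (ssErr / df2)
      if (!is.finite(Fv)) Fv <- 0
      pv <- stats::pf(Fv, df1, df2, lower.tail = FALSE)
      S <- crossprod(R) / (n - 1)
      trS <- sum(diag(S))
      eps <- if (df1 > 1 && sum(S^2) > 0)
        trS^2 / (df1 * sum(S^2)) else 1
      eps <- min(1, max(1 / df1, eps))
      pGG <- stats::pf(Fv, df1 * eps, df2 * eps, lower.tail = FALSE)
      mau <- NA_real_
      if (df1 > 1 && n - 1 > df1) {
        ev <- eigen(S, symmetric = TRUE, only.values = TRUE)$values
        if (all(ev > 1e-12 * max(ev))) {
          W <- prod(ev) / ((sum(ev) / df1)^df1)
          fct <- (2 * df1^2 + df1 + 2) / (6 * df1)
          chi2 <- -(n - 1 - fct) * log(W)
          mau <- stats::pchisq(chi2, df1 * (df1 + 1) / 2 - 1,
                               lower.tail = FALSE)
        }
      }
      peta <- ssE / (ssE + ssErr)
    }
    pUsed <- if (!is.na(mau) && mau < 0.05) pGG else pv
    data.frame(effect = paste(eff, collapse = ":"), df1 = df1, df2 = df2,
               F = Fv, p = pv, epsGG = eps, pGG = pGG, mauchlyP = mau,
               pUsed = pUsed, petaSq = peta, stringsAsFactors = FALSE)
  })
  do.call(rbind, out)
}

#' Sidak multiplicity adjustment
#'
#' \eqn{p_{adj} = 1 - (1 - p)^m} for m comparisons.
#'
#' @param p vector of raw p-values.
#' @param m number of comparisons (default: \code{length(p)}).
#' @return adjusted p-values in [0, 1].
#' @export
sidakPosthoc <- function(p, m = length(p)) {
  if (any(p < 0 | p > 1, na.rm = TRUE)) stop("p-values must lie in [0, 1]")
  pmin(1, pmax(0, 1 - (1 - p)^m))
}

#' Normality-gated correlation
#'
#' Shapiro-Wilk on both variables selects Pearson (both tenably normal) or
#' Spearman correlation.
#'
#' @param x,y numeric vectors.
#' @param alpha normality gate level.
#' @return list: \code{r}, \code{p}, \code{method}.
#' @export
correlateGated <- function(x, y, alpha = 0.05) {
  if (length(x) != length(y)) stop("x and y must have equal length")
  if (length(x) < 3 || !is.finite(stats::sd(x)) || !is.finite(stats::sd(y)) ||
      stats::sd(x) == 0 || stats::sd(y) == 0)
    return(list(r = NA_real_, p = 1, method = "degenerate (constant input)"))
  swx <- tryCatch(stats::shapiro.test(x)$p.value, error = function(e) 0)
  swy <- tryCatch(stats::shapiro.test(y)$p.value, error = function(e) 0)
  method <- if (swx >= alpha && swy >= alpha) "pearson" else "spearman"
  ct <- suppressWarnings(stats::cor.test(x, y, method = method,
                                         exact = FALSE))
  list(r = unname(ct$estimate), p = ct$p.value, method = method)
}

#' Stepwise forward regression
#'
#' Forward selection from a candidate predictor pool: at each step the
#' candidate with the smallest partial-F p-value enters if that p-value is
#' below \code{enterP}; selection stops when no candidate qualifies or the
#' residual degrees of freedom are exhausted. No removal step.
#'
#' @param y response vector.
#' @param X data.frame or matrix of candidate predictors.
#' @param enterP entry criterion on the candidate's partial F.
#' @return list: \code{selected} (names in entry order),
#'   \code{coefficients} (data.frame term/beta/t/p), \code{F}
#'   (overall F statistic), \code{Fp} (its p-value), \code{model} (the
#'   final \code{lm}).
#' @export
stepwiseRegression <- function(y, X, enterP = 0.05) {
  X <- as.data.frame(X)
  if (is.null(names(X)) || any(names(X) == ""))
    names(X) <- paste0("x", seq_along(X))
  df <- data.frame(.y = y, X, check.names = FALSE)
  selected <- character()
  repeat {
    remaining <- setdiff(names(X), selected)
    if (!length(remaining)) break
    rhs <- if (length(selected))
      paste(sprintf("`%s`", selected), collapse = " + ") else "1"
    fit <- stats::lm(stats::as.formula(paste(".y ~", rhs)), data = df)
    if (stats::df.residual(fit) <= 2) break
    scope <- stats::as.formula(paste(
      "~ . +", paste(sprintf("`%s`", remaining), collapse = " + ")))
    a1 <- stats::add1(fit, scope = scope, test = "F")
    cand <- a1[-1, , drop = FALSE]
    pv <- cand[["Pr(>F)"]]
    k <- which.min(pv)
    if (!length(k) || !is.finite(pv[k]) || pv[k] >= enterP) break
    selected <- c(selected, gsub("`", "", rownames(cand)[k]))
  }
  rhs <- if (length(selected))
    paste(sprintf("`%s`", selected), collapse = " + ") else "1"
  fit <- stats::lm(stats::as.formula(paste(".y ~", rhs)), data = df)
  sm <- summary(fit)
  co <- stats::coef(sm)
  coefficients <- data.frame(term = gsub("`", "", rownames(co)),
                             beta = co[, 1], t = co[, 3], p = co[, 4],
                             row.names = NULL, stringsAsFactors = FALSE)
  Fstat <- if (!is.null(sm$fstatistic)) unname(sm$fstatistic[1]) else NA_real_
  Fp <- if (!is.null(sm$fstatistic))
    stats::pf(sm$fstatistic[1], sm$fstatistic[2], sm$fstatistic[3],
              lower.tail = FALSE) else NA_real_
  list(selected = selected, coefficients = coefficients,
       F = Fstat, Fp = unname(Fp), model = fit)
}
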
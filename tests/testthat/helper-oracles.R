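# Independent oracle implementations used to validate the package's
# statistics: deliberately naive, loop-based transcriptions of the
# definitional formulas, plus base-R reference functions.

oracleWinsorize <- function(x, g) {
  xs <- sort(x)
  lo <- xs[g + 1]
  hi <- xs[length(x) - g]
  out <- x
  for (i in seq_along(x)) {
    if (out[i] < lo) out[i] <- lo
    if (out[i] > hi) out[i] <- hi
  }
  out
}

oracleTrimmedMean <- function(x, tr) mean(x, trim = tr)

oracleWinvar <- function(x, tr) {
  g <- floor(tr * length(x))
  var(oracleWinsorize(x, g))
}

# Yuen's dependent-samples trimmed-mean test, textbook transcription.
oracleYuenPaired <- function(x, y, tr = 0.2) {
  n <- length(x)
  g <- floor(tr * n)
  h <- n - 2 * g
  xw <- oracleWinsorize(x, g)
  yw <- oracleWinsorize(y, g)
  dx <- 0; dy <- 0; dxy <- 0
  for (i in seq_len(n)) {
    dx <- dx + (xw[i] - mean(xw))^2
    dy <- dy + (yw[i] - mean(yw))^2
    dxy <- dxy + (xw[i] - mean(xw)) * (yw[i] - mean(yw))
  }
  se <- sqrt((dx + dy - 2 * dxy) / (h * (h - 1)))
  diff <- mean(x, trim = tr) - mean(y, trim = tr)
  tstat <- diff / se
  list(statistic = tstat, df = h - 1, diff = diff,
       p = 2 * pt(-abs(tstat), h - 1),
       ciLow = diff - qt(0.975, h - 1) * se,
       ciHigh = diff + qt(0.975, h - 1) * se)
}

# Yuen's independent-samples (Welch-type) trimmed-mean test.
oracleYuenIndependent <- function(x, y, tr = 0.2) {
  n1 <- length(x); n2 <- length(y)
  g1 <- floor(tr * n1); g2 <- floor(tr * n2)
  h1 <- n1 - 2 * g1; h2 <- n2 - 2 * g2
  d1 <- (n1 - 1) * var(oracleWinsorize(x, g1)) / (h1 * (h1 - 1))
  d2 <- (n2 - 1) * var(oracleWinsorize(y, g2)) / (h2 * (h2 - 1))
  diff <- mean(x, trim = tr) - mean(y, trim = tr)
  tstat <- diff / sqrt(d1 + d2)
  df <- (d1 + d2)^2 / (d1^2 / (h1 - 1) + d2^2 / (h2 - 1))
  list(statistic = tstat, df = df, diff = diff,
       p = 2 * pt(-abs(tstat), df))
}

oracleXi <- function(x, y, tr = 0.2) {
  tm1 <- mean(x, trim = tr); tm2 <- mean(y, trim = tr)
  top <- var(c(tm1, tm2))
  bot <- oracleWinvar(c(x, y), tr) / ifelse(tr == 0, 1, 0.4121)
  sign(tm1 - tm2) * sqrt(min(1, top / bot))
}

oracleTrimmedSummary <- function(x, tr = 0.2, conf = 0.95) {
  n <- length(x)
  g <- floor(tr * n); h <- n - 2 * g
  se <- sqrt(oracleWinvar(x, tr)) / ((1 - 2 * tr) * sqrt(n))
  tm <- mean(x, trim = tr)
  crit <- qt((1 + conf) / 2, h - 1)
  list(tm = tm, se = se, ciLow = tm - crit * se, ciHigh = tm + crit * se)
}

# Brute-force BH step-up selection at level q.
oracleBhSelect <- function(p, q) {
  m <- length(p)
  o <- order(p)
  ps <- p[o]
  kmax <- 0
  for (i in seq_len(m)) if (ps[i] <= q * i / m) kmax <- i
  sel <- rep(FALSE, m)
  if (kmax > 0) sel[o[seq_len(kmax)]] <- TRUE
  sel
}

# Full enumeration of the Mann-Whitney U null distribution: every m-subset
# of the N ranks is equally likely under exchangeability (no ties).
oracleUEnumeration <- function(m, n) {
  N <- m + n
  subsets <- combn(N, m)
  u <- colSums(subsets) - m * (m + 1) / 2
  tabulate(u + 1L, nbins = m * n + 1L)  # counts for U = 0..m*n
}

# Naive per-vertex PE counting: explicit loops, no vectorization.
oraclePECounts <- function(valuesLeft, valuesRight, assignLeft, assignRight,
                           nParcels, basis = "full_map") {
  all <- c(valuesLeft, valuesRight)
  thr <- if (basis == "full_map") mean(all) else {
    nn <- all[all >= 0]
    if (length(nn) == 0) Inf else mean(nn)
  }
  countsL <- rep(0L, nParcels)
  countsR <- rep(0L, nParcels)
  for (i in seq_along(valuesLeft)) {
    v <- valuesLeft[i]
    if (v > 0 && v >= thr) countsL[assignLeft[i]] <- countsL[assignLeft[i]] + 1L
  }
  for (i in seq_along(valuesRight)) {
    v <- valuesRight[i]
    if (v > 0 && v >= thr) countsR[assignRight[i]] <- countsR[assignRight[i]] + 1L
  }
  list(left = countsL, right = countsR)
}

# Small cohort spec used across tests.
smallSpec <- function(nPerGroup = 5, ...) {
  syntheticCohortSpec(nPerGroup = nPerGroup, nParcelsPerHemi = 3,
                      verticesPerParcel = 12, seed = 11, ...)
}

randomMap <- function(nV, subject = "S1", contrast = "STORY") {
  vertexScalarMap(subject, contrast, rnorm(nV), rnorm(nV))
}
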
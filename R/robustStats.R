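## Robust trimmed-mean statistics: trimmed/winsorized estimators, Yuen's
## paired and independent tests, the explanatory effect size xi, rank tests
## and BH adjustment. Everything here is pure computation, deterministic
## given its inputs, and implemented from the definitional formulas.

checkTrim <- function(trim) {
  if (length(trim) != 1L || is.na(trim) || trim < 0 || trim >= 0.5)
    stop("'trim' must be a single proportion in [0, 0.5)")
}

trimCount <- function(n, trim) as.integer(floor(trim * n))

# Winsorize on the sample's own order statistics: values below x_(g+1) are
# replaced by x_(g+1), values above x_(n-g) by x_(n-g).
winsorize <- function(x, g) {
  if (g == 0L) return(x)
  xs <- sort(x)
  pmin(pmax(x, xs[g + 1L]), xs[length(x) - g])
}

#' Trimmed mean
#'
#' Mean of the order statistics `x_(g+1) ... x_(n-g)` with
#' `g = floor(trim * n)`.
#'
#' @param x numeric vector, length >= 1.
#' @param trim trimming proportion gamma in `[0, 0.5)` (default 0.2, the
#'   20% trimmed mean).
#' @return The trimmed mean.
#' @examples
#' trimmedMean(1:10, 0.2)  # 5.5
#' @export
trimmedMean <- function(x, trim = 0.2) {
  checkTrim(trim)
  n <- length(x)
  if (n < 1L || anyNA(x)) stop("'x' must be non-empty and free of NA")
  g <- trimCount(n, trim)
  if (n - 2L * g < 1L) stop("no observations left after trimming")
  xs <- sort(x)
  mean(xs[(g + 1L):(n - g)])
}

#' Winsorized moments
#'
#' Winsorizes each variable on its own order statistics and returns the
#' winsorized mean, variance (divisor `n - 1`) and, for paired input, the
#' cross-covariance of the aligned winsorized pairs.
#'
#' @param x numeric vector.
#' @param y optional numeric vector paired with `x` (same length, row
#'   alignment preserved).
#' @inheritParams trimmedMean
#' @return A list with elements `wmean`, `wvar`, `g`, `h` and, when `y` is
#'   supplied, `wmeanY`, `wvarY`, `wcov`.
#' @examples
#' winsorizedMoments(c(1, 2, 3, 4, 100), trim = 0.2)  # wmean 3, wvar 1
#' @export
winsorizedMoments <- function(x, y = NULL, trim = 0.2) {
  checkTrim(trim)
  n <- length(x)
  if (n < 2L || anyNA(x)) stop("'x' must have length >= 2 without NA")
  g <- trimCount(n, trim)
  h <- n - 2L * g
  xw <- winsorize(x, g)
  out <- list(wmean = mean(xw), wvar = var(xw), g = g, h = h)
  if (!is.null(y)) {
    if (length(y) != n)
      stop("paired samples must have equal lengths")
    if (anyNA(y)) stop("'y' must be free of NA")
    yw <- winsorize(y, g)
    out$wmeanY <- mean(yw)
    out$wvarY <- var(yw)
    out$wcov <- sum((xw - mean(xw)) * (yw - mean(yw))) / (n - 1)
  }
  out
}

#' Explanatory measure of effect size (xi) for trimmed-mean comparisons
#'
#' `|xi| = sqrt(min(1, s2_between / s2_total))` where `s2_between` is the
#' variance of the two group trimmed means (divisor 1) and `s2_total` is the
#' winsorized variance of the plainly concatenated samples rescaled to
#' estimate the underlying variance under normality (division by 0.4121 at
#' `trim = 0.2`; no rescaling at `trim = 0`). The returned value carries the
#' sign of the trimmed-mean difference `trimmedMean(x) - trimmedMean(y)` in
#' the caller's orientation. Absolute values of 0.10, 0.30 and 0.50
#' correspond to small, medium and large effects.
#'
#' For a paired design the same formula is applied to the two margins; the
#' dependence structure enters the test statistic but not this descriptive
#' measure.
#'
#' @param x,y the two samples (orientation: positive xi means `x` exceeds
#'   `y` on the trimmed mean).
#' @param trim 0 or 0.2 (the rescaling constant is tabulated only for
#'   these).
#' @param paired logical; kept for interface symmetry with the tests (the
#'   marginal formula is used either way).
#' @return Signed effect size in `[-1, 1]`.
#' @export
explanatoryEffectSize <- function(x, y, trim = 0.2, paired = FALSE) {
  if (!isTRUE(all.equal(trim, 0.2)) && trim != 0)
    stop("'trim' must be 0 or 0.2 for the explanatory effect size")
  tmx <- trimmedMean(x, trim)
  tmy <- trimmedMean(y, trim)
  s2between <- (tmx - tmy)^2 / 2           # var of the two means, divisor 1
  pooled <- c(x, y)
  wv <- winsorizedMoments(pooled, trim = trim)$wvar
  s2total <- if (trim == 0) wv else wv / 0.4121
  if (s2total <= 0) {
    if (s2between == 0) return(0)
    stop("explanatory effect size undefined: zero pooled winsorized variance")
  }
  sign(tmx - tmy) * sqrt(min(1, s2between / s2total))
}

# Shared assembly of a RobustTestResult.
newRobustResult <- function(label, statistic, df, diff, ciLow, ciHigh,
                            p, xi, direction, n) {
  new("RobustTestResult", parcelLabel = label,
      statistic = statistic, df = df, meanDifference = diff,
      ciLow = ciLow, ciHigh = ciHigh, pRaw = p, pCorrected = NA_real_,
      xi = xi, direction = direction, n = as.integer(n))
}

# Core of Yuen's dependent-samples trimmed-mean test; returns a plain list.
.yuenPairedCore <- function(x, y, trim, conf = 0.95) {
  checkTrim(trim)
  n <- length(x)
  if (length(y) != n) stop("paired samples must have equal lengths")
  g <- trimCount(n, trim)
  h <- n - 2L * g
  if (h < 2L) stop("effective sample size after trimming must be >= 2")
  tmx <- trimmedMean(x, trim)
  tmy <- trimmedMean(y, trim)
  diff <- tmx - tmy
  xw <- winsorize(x, g); yw <- winsorize(y, g)
  dx <- sum((xw - mean(xw))^2)
  dy <- sum((yw - mean(yw))^2)
  dxy <- sum((xw - mean(xw)) * (yw - mean(yw)))
  se2 <- (dx + dy - 2 * dxy) / (h * (h - 1))
  df <- h - 1
  if (se2 <= 0) {
    if (diff != 0)
      stop("degenerate data: zero standard error with nonzero trimmed-mean difference")
    return(list(statistic = 0, df = df, diff = 0, se = 0,
                ciLow = 0, ciHigh = 0, p = 1, xi = 0, n = n, h = h,
                degenerate = TRUE))
  }
  se <- sqrt(se2)
  tstat <- diff / se
  p <- 2 * pt(-abs(tstat), df)
  crit <- qt((1 + conf) / 2, df)
  list(statistic = tstat, df = df, diff = diff, se = se,
       ciLow = diff - crit * se, ciHigh = diff + crit * se, p = p,
       xi = explanatoryEffectSize(x, y, trim), n = n, h = h,
       degenerate = FALSE)
}

#' Yuen's paired trimmed-mean t test
#'
#' Dependent-samples comparison of gamma-trimmed means: with effective size
#' `h = n - 2g`, the statistic is `(tm_x - tm_y) / SE` with
#' `SE^2 = (d_x + d_y - 2 d_xy) / (h (h - 1))`, where `d_x`, `d_y`, `d_xy`
#' are the winsorized sums of squares and aligned cross-products;
#' `df = h - 1`; two-sided p from the t distribution. The signed explanatory
#' effect size is attached with the sign of the trimmed-mean difference
#' (orientation `x - y`).
#'
#' @inheritParams winsorizedMoments
#' @param conf confidence level of the interval for the trimmed-mean
#'   difference.
#' @param label optional region label carried into the result.
#' @return A [RobustTestResult-class].
#' @examples
#' set.seed(1)
#' yuenPaired(rnorm(20, 1), rnorm(20))
#' @export
yuenPaired <- function(x, y, trim = 0.2, conf = 0.95, label = "") {
  r <- .yuenPairedCore(x, y, trim, conf)
  newRobustResult(label, r$statistic, r$df, r$diff, r$ciLow, r$ciHigh,
                  r$p, r$xi, "x_minus_y", r$n)
}

# Core of Yuen's independent-samples (Welch-type) trimmed-mean test.
.yuenIndependentCore <- function(x, y, trim, conf = 0.95) {
  checkTrim(trim)
  n1 <- length(x); n2 <- length(y)
  g1 <- trimCount(n1, trim); g2 <- trimCount(n2, trim)
  h1 <- n1 - 2L * g1; h2 <- n2 - 2L * g2
  if (h1 < 2L || h2 < 2L)
    stop("effective sample size after trimming must be >= 2 in both groups")
  tm1 <- trimmedMean(x, trim); tm2 <- trimmedMean(y, trim)
  diff <- tm1 - tm2
  d1 <- (n1 - 1) * var(winsorize(x, g1)) / (h1 * (h1 - 1))
  d2 <- (n2 - 1) * var(winsorize(y, g2)) / (h2 * (h2 - 1))
  if (d1 + d2 <= 0) {
    if (diff != 0)
      stop("degenerate data: zero standard error with nonzero trimmed-mean difference")
    return(list(statistic = 0, df = max(h1, h2) - 1, diff = 0, se = 0,
                ciLow = 0, ciHigh = 0, p = 1, xi = 0, n = c(n1, n2),
                degenerate = TRUE))
  }
  se <- sqrt(d1 + d2)
  df <- (d1 + d2)^2 / (d1^2 / (h1 - 1) + d2^2 / (h2 - 1))
  tstat <- diff / se
  p <- 2 * pt(-abs(tstat), df)
  crit <- qt((1 + conf) / 2, df)
  list(statistic = tstat, df = df, diff = diff, se = se,
       ciLow = diff - crit * se, ciHigh = diff + crit * se, p = p,
       xi = explanatoryEffectSize(x, y, trim), n = c(n1, n2),
       degenerate = FALSE)
}

#' Yuen's independent-samples trimmed-mean t test (Welch-type)
#'
#' Two-group comparison of gamma-trimmed means with
#' `d_j = (n_j - 1) wvar_j / (h_j (h_j - 1))`, statistic
#' `(tm_1 - tm_2) / sqrt(d_1 + d_2)` and Welch-Satterthwaite degrees of
#' freedom `(d_1 + d_2)^2 / (d_1^2/(h_1 - 1) + d_2^2/(h_2 - 1))`. At
#' `trim = 0` this reduces exactly to Welch's unequal-variance t test.
#'
#' @inheritParams yuenPaired
#' @return A [RobustTestResult-class] (orientation `x - y`).
#' @export
yuenIndependent <- function(x, y, trim = 0.2, conf = 0.95, label = "") {
  r <- .yuenIndependentCore(x, y, trim, conf)
  newRobustResult(label, r$statistic, r$df, r$diff, r$ciLow, r$ciHigh,
                  r$p, r$xi, "x_minus_y", r$n)
}

#' Trimmed mean with standard error and confidence interval
#'
#' `SE = s_w / ((1 - 2 gamma) sqrt(n))` with `s_w` the winsorized standard
#' deviation (divisor `n - 1`); the interval is
#' `trimmed mean +/- t_{(1+conf)/2, h-1} * SE`.
#'
#' @inheritParams trimmedMean
#' @param conf confidence level.
#' @return A [TrimmedSummary-class].
#' @export
trimmedMeanSummary <- function(x, trim = 0.2, conf = 0.95) {
  checkTrim(trim)
  n <- length(x)
  g <- trimCount(n, trim)
  h <- n - 2L * g
  if (h < 2L) stop("effective sample size after trimming must be >= 2")
  tm <- trimmedMean(x, trim)
  sw <- sqrt(winsorizedMoments(x, trim = trim)$wvar)
  se <- sw / ((1 - 2 * trim) * sqrt(n))
  crit <- qt((1 + conf) / 2, h - 1)
  new("TrimmedSummary", trimmedMean = tm, se = se,
      ciLow = tm - crit * se, ciHigh = tm + crit * se,
      n = as.integer(n), h = as.integer(h), trim = trim, conf = conf)
}

## ---- Mann-Whitney U with Hodges-Lehmann shift ----

# Exact null counts of the rank sum of the first sample: number of
# m-subsets of ranks 1..(m+n) attaining each sum, by subset-sum dynamic
# programming. Returns counts for U = 0..m*n after shifting by m(m+1)/2.
uNullCounts <- function(m, n) {
  N <- m + n
  maxS <- sum((n + 1):N)           # largest rank sum of an m-subset
  dp <- matrix(0, nrow = m + 1L, ncol = maxS + 1L)  # dp[k+1, s+1]
  dp[1L, 1L] <- 1
  for (j in seq_len(N)) {
    for (k in rev(seq_len(min(m, j)))) {
      idx <- (j + 1L):(maxS + 1L)
      dp[k + 1L, idx] <- dp[k + 1L, idx] + dp[k, idx - j]
    }
  }
  s <- m * (m + 1L) / 2L
  dp[m + 1L, (s + 1L):(s + m * n + 1L)]
}

# Cumulative null probability P(U <= u), exact.
uCdf <- function(counts) cumsum(counts) / sum(counts)

#' Mann-Whitney U test with Hodges-Lehmann shift estimate
#'
#' U is computed from rank sums with midranks for ties. When
#' `nx * ny <= 400` and there are no ties the two-sided p comes from the
#' exact null distribution of U (subset-sum enumeration); otherwise from the
#' normal approximation with tie-corrected variance and continuity
#' correction. The accompanying location estimate is the Hodges-Lehmann
#' shift, the median of all pairwise differences `x_i - y_j`, with a
#' confidence interval obtained by inverting the test (order statistics of
#' the pairwise differences at the U critical values).
#'
#' @param x,y numeric samples.
#' @param conf confidence level for the shift interval.
#' @return A [MannWhitneyResult-class].
#' @examples
#' mannWhitney(c(1, 2), c(0, 1))
#' @export
mannWhitney <- function(x, y, conf = 0.95) {
  if (!length(x) || !length(y)) stop("both samples must be nonempty")
  if (anyNA(x) || anyNA(y)) stop("samples must be free of NA")
  m <- length(x); n <- length(y)
  r <- rank(c(x, y))
  U <- sum(r[seq_len(m)]) - m * (m + 1) / 2
  hasTies <- anyDuplicated(c(x, y)) > 0L
  exact <- (m * n <= 400) && !hasTies
  alpha <- 1 - conf
  if (exact) {
    cdf <- uCdf(uNullCounts(m, n))
    pLe <- cdf[U + 1L]                       # P(U <= u)
    pGe <- 1 - if (U >= 1) cdf[U] else 0     # P(U >= u)
    p <- min(1, 2 * if (U > m * n / 2) pGe else pLe)
    # largest k with P(U <= k) <= alpha/2 (k = -1 if none)
    k <- max(which(c(0, cdf) <= alpha / 2)) - 2L
  } else {
    N <- m + n
    ties <- table(r)
    sigma <- sqrt((m * n / 12) *
                  ((N + 1) - sum(ties^3 - ties) / (N * (N - 1))))
    zc <- U - m * n / 2
    z <- (zc - sign(zc) * 0.5) / sigma
    p <- min(1, 2 * pnorm(-abs(z)))
    k <- floor(m * n / 2 - qnorm(1 - alpha / 2) * sigma - 0.5)
  }
  d <- sort(as.vector(outer(x, y, "-")))
  hl <- median(d)
  lo <- if (k >= 0 && k + 1 <= m * n) d[k + 1L] else -Inf
  hi <- if (k >= 0 && k + 1 <= m * n) d[m * n - k] else Inf
  new("MannWhitneyResult", statistic = U, pValue = p, hlShift = hl,
      ciLow = lo, ciHigh = hi, conf = conf, exact = exact,
      nx = as.integer(m), ny = as.integer(n))
}

#' Benjamini-Hochberg step-up adjustment
#'
#' `p_(i) -> min_{j >= i} min(1, p_(j) * m / j)` on the sorted p-values,
#' mapped back to input order. Selecting `adjusted <= q` reproduces the BH
#' step-up rejection set at FDR level `q`.
#'
#' @param p numeric vector of raw p-values in `[0, 1]`.
#' @return Adjusted p-values in input order.
#' @examples
#' bhAdjust(c(0.01, 0.02, 0.03, 0.04))  # all 0.04
#' @export
bhAdjust <- function(p) {
  if (!length(p)) return(numeric(0))
  if (anyNA(p) || any(p < 0 | p > 1))
    stop("p-values must lie in [0, 1]")
  m <- length(p)
  o <- order(p)
  adj <- rev(cummin(rev(pmin(1, p[o] * m / seq_len(m)))))
  out <- numeric(m)
  out[o] <- adj
  out
}

## ---- show methods and coercion ----

setMethod("show", "RobustTestResult", function(object) {
  lab <- if (nzchar(object@parcelLabel)) paste0(" [", object@parcelLabel, "]") else ""
  cat("Robust trimmed-mean test", lab, "\n", sep = "")
  cat(sprintf("  t = %.4f, df = %.2f, p = %.4g", object@statistic,
              object@df, object@pRaw))
  if (!is.na(object@pCorrected))
    cat(sprintf(", p(BH) = %.4g", object@pCorrected))
  cat("\n")
  cat(sprintf("  trimmed-mean difference (%s) = %.4f  [%.4f, %.4f]\n",
              object@direction, object@meanDifference, object@ciLow,
              object@ciHigh))
  cat(sprintf("  explanatory effect size xi = %.3f\n", object@xi))
})

setMethod("show", "TrimmedSummary", function(object) {
  cat(sprintf("%.0f%% trimmed mean = %.4f (SE %.4f), %d%% CI [%.4f, %.4f], n = %d\n",
              100 * object@trim, object@trimmedMean, object@se,
              round(100 * object@conf), object@ciLow, object@ciHigh,
              object@n))
})

setMethod("show", "MannWhitneyResult", function(object) {
  cat(sprintf("Mann-Whitney U = %g (%s), p = %.4g\n", object@statistic,
              if (object@exact) "exact" else "normal approx.",
              object@pValue))
  cat(sprintf("  Hodges-Lehmann shift = %.4f  [%.4f, %.4f]\n",
              object@hlShift, object@ciLow, object@ciHigh))
})

#' Convert robust test results to a data.frame
#'
#' One row per result, with the column set of the published result tables:
#' `region`, `statistic`, `df`, `mean_difference`, `ci_low`, `ci_high`, `p`,
#' `p_corrected`, `xi`.
#'
#' @param results a [RobustTestResult-class] or a list of them.
#' @return A data.frame.
#' @export
resultsFrame <- function(results) {
  if (is(results, "RobustTestResult")) results <- list(results)
  do.call(rbind, lapply(results, function(r) {
    data.frame(region = r@parcelLabel, statistic = r@statistic, df = r@df,
               mean_difference = r@meanDifference,
               ci_low = r@ciLow, ci_high = r@ciHigh,
               p = r@pRaw, p_corrected = r@pCorrected, xi = r@xi)
  }))
}
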
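# Robust trimmed-mean machinery against independent oracles.

test_that("trimmed mean matches the sort-truncate-average definition", {
  expect_equal(trimmedMean(1:10, 0.2), 5.5)
  expect_equal(trimmedMean(c(7), 0), 7)
  expect_equal(trimmedMean(rep(3.2, 9), 0.2), 3.2)
  set.seed(101)
  for (i in 1:50) {
    n <- sample(3:40, 1)
    x <- rnorm(n, sd = 10)
    tr <- sample(c(0, 0.1, 0.2, 0.25), 1)
    expect_equal(trimmedMean(x, tr), oracleTrimmedMean(x, tr),
                 tolerance = 1e-12)
  }
  expect_error(trimmedMean(numeric(0)), "non-empty")
  expect_error(trimmedMean(1:5, 0.5), "trim")
})

test_that("trimmed mean is location-scale equivariant", {
  set.seed(7)
  x <- rnorm(23)
  expect_equal(trimmedMean(3 * x - 2, 0.2), 3 * trimmedMean(x, 0.2) - 2,
               tolerance = 1e-12)
})

test_that("winsorized moments follow the hand-winsorization definition", {
  wm <- winsorizedMoments(c(1, 2, 3, 4, 100), trim = 0.2)
  expect_equal(wm$wmean, 3)       # winsorized sample 2,2,3,4,4
  expect_equal(wm$wvar, 1)
  expect_equal(wm$g, 1L)
  expect_equal(wm$h, 3L)

  # gamma = 0 reduces to ordinary moments
  set.seed(21)
  x <- rnorm(12); y <- rnorm(12)
  wm0 <- winsorizedMoments(x, y, trim = 0)
  expect_equal(wm0$wvar, var(x), tolerance = 1e-12)
  expect_equal(wm0$wcov, cov(x, y), tolerance = 1e-12)

  expect_equal(winsorizedMoments(rep(2, 6), trim = 0.2)$wvar, 0)
  expect_error(winsorizedMoments(1:5, 1:4, trim = 0.2), "equal lengths")

  set.seed(22)
  for (i in 1:50) {
    n <- sample(4:30, 1)
    x <- rt(n, df = 3)
    expect_equal(winsorizedMoments(x, trim = 0.2)$wvar,
                 oracleWinvar(x, 0.2), tolerance = 1e-12)
  }
})

test_that("Yuen's paired test matches an independent transcription", {
  set.seed(31)
  for (i in 1:20) {
    n <- 12
    x <- rnorm(n); y <- 0.6 * x + rnorm(n)
    got <- yuenPaired(x, y)
    ref <- oracleYuenPaired(x, y)
    expect_equal(got@statistic, ref$statistic, tolerance = 1e-8)
    expect_equal(got@df, ref$df, tolerance = 1e-8)
    expect_equal(got@pRaw, ref$p, tolerance = 1e-8)
    expect_equal(got@ciLow, ref$ciLow, tolerance = 1e-8)
    expect_equal(got@ciHigh, ref$ciHigh, tolerance = 1e-8)
  }
})

test_that("Yuen's paired test handles identical and degenerate input", {
  set.seed(32)
  x <- rnorm(10)
  r <- yuenPaired(x, x)
  expect_equal(r@statistic, 0)
  expect_equal(r@meanDifference, 0)
  expect_equal(r@pRaw, 1)
  expect_equal(r@xi, 0)
  # zero SE with nonzero difference is an error, not a silent result
  expect_error(yuenPaired(rep(1, 8), rep(2, 8)), "degenerate")
})

test_that("at trim 0 the Yuen tests reduce to paired t and Welch t", {
  set.seed(33)
  for (i in 1:100) {
    n1 <- sample(5:25, 1); n2 <- sample(5:25, 1)
    x <- rnorm(n1, sd = runif(1, 0.5, 2)); y <- rnorm(n2, 1)
    ind <- yuenIndependent(x, y, trim = 0)
    tw <- t.test(x, y)
    expect_equal(ind@statistic, unname(tw$statistic), tolerance = 1e-10)
    expect_equal(ind@df, unname(tw$parameter), tolerance = 1e-10)
    expect_equal(ind@pRaw, tw$p.value, tolerance = 1e-10)

    xp <- rnorm(n1); yp <- xp * 0.5 + rnorm(n1)
    par <- yuenPaired(xp, yp, trim = 0)
    tp <- t.test(xp, yp, paired = TRUE)
    expect_equal(par@statistic, unname(tp$statistic), tolerance = 1e-10)
    expect_equal(par@df, unname(tp$parameter), tolerance = 1e-10)
    expect_equal(par@pRaw, tp$p.value, tolerance = 1e-10)
    expect_equal(c(par@ciLow, par@ciHigh), as.numeric(tp$conf.int),
                 tolerance = 1e-10)
  }
})

test_that("Yuen's independent test matches the transcription on unequal n", {
  set.seed(34)
  for (i in 1:20) {
    n1 <- sample(8:20, 1); n2 <- sample(8:20, 1)
    x <- rt(n1, 4); y <- rt(n2, 4) + 0.5
    got <- yuenIndependent(x, y)
    ref <- oracleYuenIndependent(x, y)
    expect_equal(got@statistic, ref$statistic, tolerance = 1e-8)
    expect_equal(got@df, ref$df, tolerance = 1e-8)
    expect_equal(got@pRaw, ref$p, tolerance = 1e-8)
  }
})

test_that("Yuen statistics are invariant under common affine transforms", {
  set.seed(35)
  x <- rnorm(15); y <- rnorm(15, 0.3)
  a <- 2.7; b <- -1.3
  r1 <- yuenIndependent(x, y)
  r2 <- yuenIndependent(a * x + b, a * y + b)
  expect_equal(r1@statistic, r2@statistic, tolerance = 1e-10)
  expect_equal(r1@pRaw, r2@pRaw, tolerance = 1e-10)
  expect_equal(r1@xi, r2@xi, tolerance = 1e-10)
  p1 <- yuenPaired(x, y); p2 <- yuenPaired(a * x + b, a * y + b)
  expect_equal(p1@statistic, p2@statistic, tolerance = 1e-10)
})

test_that("explanatory effect size follows its defining ratio and bands", {
  set.seed(41)
  x <- rnorm(30); y <- rnorm(30, 1)
  expect_equal(explanatoryEffectSize(x, y), oracleXi(x, y),
               tolerance = 1e-12)
  expect_equal(explanatoryEffectSize(x, y, trim = 0), oracleXi(x, y, 0),
               tolerance = 1e-12)
  expect_equal(explanatoryEffectSize(x, x), 0)
  # sign follows the trimmed-mean difference in the caller's orientation
  expect_lt(explanatoryEffectSize(y = x + 5, x = x), 0)
  expect_error(explanatoryEffectSize(x, y, trim = 0.3), "0 or 0.2")
  # winsorization flattens the pooled sample while the trimmed means differ
  expect_error(explanatoryEffectSize(rep(0, 10), c(0, 1, 1)), "undefined")
})

test_that("large separations drive |xi| toward its capped maximum", {
  set.seed(42)
  x <- rnorm(2000); y <- rnorm(2000, 10)
  xi <- explanatoryEffectSize(x, y)
  expect_gt(abs(xi), 0.85)
  expect_lte(abs(xi), 1)
  # unbalanced well-separated groups push the raw ratio past 1: the cap holds
  x2 <- rnorm(25, 10, 0.01); y2 <- rnorm(75, 0, 0.01)
  expect_equal(abs(explanatoryEffectSize(x2, y2)), 1)
})

test_that("trimmed-mean summaries match the definitional formulas", {
  set.seed(51)
  x <- rexp(24)
  s <- trimmedMeanSummary(x)
  ref <- oracleTrimmedSummary(x)
  expect_equal(s@trimmedMean, ref$tm, tolerance = 1e-12)
  expect_equal(s@se, ref$se, tolerance = 1e-12)
  expect_equal(s@ciLow, ref$ciLow, tolerance = 1e-12)
  expect_equal(s@ciHigh, ref$ciHigh, tolerance = 1e-12)

  # gamma = 0 reduction to the classical t interval
  s0 <- trimmedMeanSummary(x, trim = 0)
  tt <- t.test(x)
  expect_equal(s0@trimmedMean, mean(x), tolerance = 1e-12)
  expect_equal(c(s0@ciLow, s0@ciHigh), as.numeric(tt$conf.int),
               tolerance = 1e-12)

  # symmetry about the trimmed mean
  expect_equal(s@trimmedMean - s@ciLow, s@ciHigh - s@trimmedMean,
               tolerance = 1e-12)
})

test_that("Mann-Whitney matches hand examples and wilcox.test", {
  # pairwise differences {1, 0, 2, 1} -> HL shift 1
  r <- mannWhitney(c(1, 2), c(0, 1))
  expect_equal(r@hlShift, 1)

  # all x above all y: U = nx * ny, exact p = 2 / choose(nx + ny, nx)
  x <- 11:16; y <- 1:5
  r <- mannWhitney(x, y)
  expect_equal(r@statistic, length(x) * length(y))
  expect_equal(r@pValue, 2 / choose(11, 6), tolerance = 1e-12)

  # shift construction: y = x + 3 gives HL shift -3
  set.seed(61)
  x <- rnorm(9)
  expect_equal(mannWhitney(x, x + 3)@hlShift, -3, tolerance = 1e-12)

  # agreement with wilcox.test in both branches
  for (i in 1:30) {
    x <- rnorm(sample(4:12, 1)); y <- rnorm(sample(4:12, 1), 0.5)
    got <- mannWhitney(x, y)
    ref <- wilcox.test(x, y, exact = TRUE)
    expect_true(got@exact)
    expect_equal(got@statistic, unname(ref$statistic))
    expect_equal(got@pValue, ref$p.value, tolerance = 1e-12)
  }
  for (i in 1:20) {
    x <- sample(1:6, 25, replace = TRUE)  # ties force the normal branch
    y <- sample(1:6, 30, replace = TRUE)
    got <- mannWhitney(x, y)
    ref <- wilcox.test(x, y, exact = FALSE, correct = TRUE)
    expect_false(got@exact)
    expect_equal(got@statistic, unname(ref$statistic))
    expect_equal(got@pValue, ref$p.value, tolerance = 1e-10)
  }
})

test_that("the exact U distribution equals full permutation enumeration", {
  for (m in 2:7) for (n in 2:7) {
    expect_equal(peLaterality:::uNullCounts(m, n),
                 oracleUEnumeration(m, n),
                 info = sprintf("m=%d n=%d", m, n))
  }
})

test_that("BH adjustment reproduces the step-up rule", {
  expect_equal(bhAdjust(c(0.01, 0.02, 0.03, 0.04)), rep(0.04, 4))
  expect_equal(bhAdjust(0.2), 0.2)
  set.seed(71)
  for (i in 1:100) {
    m <- sample(1:50, 1)
    p <- runif(m)^sample(1:3, 1)
    adj <- bhAdjust(p)
    expect_equal(adj, p.adjust(p, "BH"), tolerance = 1e-12)
    expect_true(all(adj <= 1) && all(adj >= p - 1e-15))
    # monotone in the raw p-values
    o <- order(p)
    expect_true(all(diff(adj[o]) >= -1e-15))
    # threshold rule selects exactly the BH step-up set
    q <- runif(1, 0.01, 0.2)
    expect_equal(adj <= q, oracleBhSelect(p, q))
  }
  expect_error(bhAdjust(c(0.5, 1.2)), "\\[0, 1\\]")
})
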
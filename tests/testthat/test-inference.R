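test_that("one-tailed t-tests match the closed-form statistics", {
  # identical samples: t = 0 and the one-tailed p sits at 1/2
  r <- oneTailedTTest(c(0.4, 0.5, 0.6), c(0.4, 0.5, 0.6), "greater", "student")
  expect_equal(r$statistic, 0)
  expect_equal(r$p_one_tailed, 0.5)
  # non-degenerate paired example against the closed form
  a <- c(0.4, 0.5, 0.7); b <- c(0.1, 0.25, 0.3)
  r <- oneTailedTTest(a, b, "greater", "paired")
  o <- oracleTTest(a, b, "greater", "paired")
  expect_equal(r$statistic, o$t, tolerance = 1e-12)
  expect_equal(r$df, 2)
  expect_equal(r$p_one_tailed, o$p, tolerance = 1e-12)
  # mirrored direction flips the tail: p_less = 1 - p_greater
  r2 <- oneTailedTTest(a, b, "less", "paired")
  expect_equal(r2$p_one_tailed, 1 - r$p_one_tailed, tolerance = 1e-12)
  # small property sweep over all three variants
  set.seed(31)
  for (i in 1:20) {
    n <- sample(4:40, 1)
    a <- runif(n); b <- runif(n) + rnorm(1, 0, 0.1)
    for (v in c("student", "welch", "paired"))
      for (d in c("greater", "less")) {
        r <- oneTailedTTest(a, b, d, v)
        o <- oracleTTest(a, b, d, v)
        expect_equal(r$statistic, o$t, tolerance = 1e-10)
        expect_equal(r$df, o$df, tolerance = 1e-10)
        expect_equal(r$p_one_tailed, o$p, tolerance = 1e-10)
      }
  }
})

test_that("degenerate t-test inputs are refused, not mis-reported", {
  # constant paired differences have no variance to test against
  expect_error(oneTailedTTest(c(0.4, 0.5, 0.6), c(0.1, 0.2, 0.3),
                              "greater", "paired"), "degenerate")
  expect_error(oneTailedTTest(c(1, 1, 1), c(1, 1, 1), "greater", "student"),
               "degenerate")
  expect_error(oneTailedTTest(0.4, c(0.1, 0.2), "greater", "student"),
               "at least 2")
  expect_error(oneTailedTTest(c(0.4, 0.5, 0.6), c(0.1, 0.2), "greater",
                              "paired"), "equal-length")
})

test_that("the Deming fit solves the errors-in-variables problem", {
  # exactly collinear points give the exact line
  fit <- demingFit(c(0, 1, 2), c(0, 1, 2))
  expect_equal(fit@slope, 1)
  expect_equal(fit@intercept, 0)
  # the fitted line passes through the centroid by construction
  set.seed(41)
  x <- runif(10); y <- 1.4 * x + rnorm(10, 0, 0.1)
  fit <- demingFit(x, y)
  expect_equal(fit@intercept, mean(y) - fit@slope * mean(x), tolerance = 1e-12)
  # orthogonal case agrees with the brute-force perpendicular search,
  # including the four-point scatter with an irregular spread
  xs <- c(0, 0.3, 0.5, 0.8); ys <- c(0.1, 0.25, 0.6, 0.75)
  expect_equal(demingFit(xs, ys)@slope, oracleDemingSlope(xs, ys),
               tolerance = 1e-6)
  # axis-swap reciprocity at lambda = 1
  expect_equal(demingFit(x, y)@slope * demingFit(y, x)@slope, 1,
               tolerance = 1e-10)
  # sandwich property: between OLS(y|x) and 1/OLS(x|y) for correlated data
  b <- demingFit(x, y)@slope
  expect_gte(b, oracleOlsSlope(x, y) - 1e-12)
  expect_lte(b, 1 / oracleOlsSlope(y, x) + 1e-12)
  # lambda -> 0 treats x as error-free: OLS limit
  expect_equal(demingFit(x, y, lambda = 1e-8)@slope, oracleOlsSlope(x, y),
               tolerance = 1e-4)
  # equivariance under common rescaling of both axes
  fit2 <- demingFit(10 * x, 10 * y)
  expect_equal(fit2@slope, fit@slope, tolerance = 1e-12)
  expect_equal(fit2@intercept, 10 * fit@intercept, tolerance = 1e-10)
  # uncorrelated data fall back to the positive-root convention
  xs <- c(-1, 0, 1, 0); ys <- c(0, 1, 0, -1)
  expect_equal(demingFit(xs, ys)@slope, sqrt(var(ys) / var(xs)))
  # guards
  expect_error(demingFit(1:2, 1:2), "at least 3")
  expect_error(demingFit(c(1, 1, 1), c(1, 2, 3)), "constant")
})

test_that("jackknife slope SE behaves like a standard error", {
  # collinear data: every leave-one-out slope identical, SE exactly 0
  expect_equal(demingSlopeSE(c(0, 1, 2, 3), c(0, 1, 2, 3)), 0)
  set.seed(51)
  x <- runif(12); y <- x + rnorm(12, 0, 0.05)
  se1 <- demingSlopeSE(x, y)
  expect_gt(se1, 0)
  # duplicating every point halves the information per point: smaller SE
  expect_lt(demingSlopeSE(rep(x, 2), rep(y, 2)), se1)
  # jackknife tracks the sampling SD of the slope under the generative
  # model (parametric bootstrap with noise on both axes)
  set.seed(61)
  n <- 10; sd0 <- 0.05
  xt <- seq(0.1, 0.9, length.out = n)
  x0 <- xt + rnorm(n, 0, sd0); y0 <- xt + rnorm(n, 0, sd0)
  se_jack <- demingSlopeSE(x0, y0)
  boot <- replicate(2000, {
    demingFit(xt + rnorm(n, 0, sd0), xt + rnorm(n, 0, sd0))@slope
  })
  expect_lt(abs(se_jack - sd(boot)) / sd(boot), 0.25)
})

test_that("slope tests compare against a reference line", {
  set.seed(71)
  x <- runif(20); y <- 1.3 * x + rnorm(20, 0, 0.05)
  fit <- demingRegression(x, y)
  expect_equal(fit@intercept, mean(y) - fit@slope * mean(x), tolerance = 1e-12)
  # manual t computation
  tstat <- (fit@slope - 1) / fit@slopeSE
  expect_equal(fit@pSlopeVsOne, 2 * pt(-abs(tstat), df = fit@n - 2),
               tolerance = 1e-12)
  expect_lt(fit@pSlopeVsZero, fit@pSlopeVsOne)
  # slope equal to the reference is maximally compatible
  expect_equal(testSlope(fit, fit@slope), 1)
  # zero-SE degeneracies
  col <- demingFit(c(0, 1, 2, 3), c(0, 1, 2, 3))
  col@slopeSE <- 0
  expect_equal(testSlope(col, 1), 1)
  expect_warning(p <- testSlope(col, 2), "degenerates")
  expect_equal(p, 0)
  # a fit without an SE cannot be tested
  expect_error(testSlope(demingFit(x, y), 1), "no slope standard error")
})

test_that("population comparison extracts the requested frequency scale", {
  cat <- singleDbCatalog(or_value = c(1.5, 3, 2), afr = c(0.4, 0.6, 0.5),
                         eur = c(0.35, 0.5, 0.45))
  agg <- aggregateCatalog(cat)
  cmp <- comparePopulations(agg, "afr", "eur", useWeighted = FALSE,
                            direction = "greater", variant = "paired")
  expect_equal(cmp$mean_a, 0.5)
  expect_equal(cmp$mean_b, mean(c(0.35, 0.5, 0.45)))
  expect_equal(cmp$n_units, 3)
  cmpw <- comparePopulations(agg, "afr", "eur", useWeighted = TRUE,
                             direction = "greater", variant = "paired")
  expect_equal(cmpw$mean_a, mean(c(0.4, 0.6, 0.5) * c(1.5, 3, 2) / 3))
  # two identical populations: equal means, p = 1/2 (unpaired; the paired
  # variant is degenerate on identical vectors)
  same <- singleDbCatalog(or_value = c(1.5, 3, 2), afr = c(0.4, 0.6, 0.5),
                          eur = c(0.4, 0.6, 0.5))
  cmp0 <- comparePopulations(aggregateCatalog(same), "afr", "eur",
                             variant = "student")
  expect_equal(cmp0$mean_a, cmp0$mean_b)
  expect_equal(cmp0$ttest$p_one_tailed, 0.5)
  expect_error(comparePopulations(agg, "afr", "asn"), "not in the aggregated")
})
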
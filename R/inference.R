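#' One-tailed t-test between two frequency vectors
#'
#' Directional comparison of per-unit risk-allele frequencies between two
#' populations. The hypotheses here are directional by design — a
#' population with a higher disease incidence is tested for a *higher*
#' burden of risk alleles — so the one-tailed p-value is reported. Three
#' variants are available: the classical two-sample Student's t-test with
#' pooled variance (`"student"`, the default), the Welch unequal-variance
#' test (`"welch"`), and the paired test on per-unit differences
#' (`"paired"`), which is natural when the same variant units are measured
#' in both populations. Computation is delegated to [stats::t.test()].
#'
#' @param a,b numeric vectors (per-unit frequencies); equal length required
#'   for the paired variant, length >= 2 for all.
#' @param direction `"greater"` tests mean(a) > mean(b); `"less"` the
#'   mirror image.
#' @param variant `"student"`, `"welch"`, or `"paired"`.
#' @return object of class `"TTestResult"`: a list with `statistic`, `df`,
#'   `p_one_tailed`, `direction`, `variant`, `mean_a`, `mean_b`, `n`.
#' @examples
#' oneTailedTTest(c(0.4, 0.5, 0.7), c(0.1, 0.25, 0.3),
#'                direction = "greater", variant = "paired")
#' @export
oneTailedTTest <- function(a, b, direction = c("greater", "less"),
                           variant = c("student", "welch", "paired")) {
  direction <- match.arg(direction)
  variant <- match.arg(variant)
  if (length(a) < 2L || length(b) < 2L)
    stop("both samples need at least 2 observations", call. = FALSE)
  if (variant == "paired" && length(a) != length(b))
    stop("paired variant requires equal-length samples", call. = FALSE)
  tt <- tryCatch(
    stats::t.test(a, b, alternative = direction,
                  paired = variant == "paired",
                  var.equal = variant == "student"),
    error = function(e)
      stop("degenerate data for the ", variant, " t-test: ",
           conditionMessage(e), call. = FALSE))
  structure(list(statistic = unname(tt$statistic),
                 df = unname(tt$parameter),
                 p_one_tailed = tt$p.value,
                 direction = direction,
                 variant = variant,
                 mean_a = mean(a),
                 mean_b = mean(b),
                 n = if (variant == "paired") length(a) else c(length(a), length(b))),
            class = "TTestResult")
}

#' @export
print.TTestResult <- function(x, ...) {
  cat(sprintf("One-tailed %s t-test (direction: a %s b)\n", x$variant,
              if (x$direction == "greater") ">" else "<"))
  cat(sprintf("  mean(a) = %.4f, mean(b) = %.4f, n = %s\n", x$mean_a, x$mean_b,
              paste(x$n, collapse = "/")))
  cat(sprintf("  t = %.4f, df = %.4g, p = %.4g\n", x$statistic, x$df,
              x$p_one_tailed))
  invisible(x)
}

# (co)variance building blocks about the means, with the n-1 denominator
# (any common denominator cancels in the slope formula)
.demingMoments <- function(x, y) {
  list(xbar = mean(x), ybar = mean(y),
       sxx = stats::var(x), syy = stats::var(y), sxy = stats::cov(x, y))
}

.demingSlopeFromMoments <- function(mom, lambda) {
  # lambda = x-error variance / y-error variance; delta = 1/lambda is the
  # classical y/x error-variance ratio of the errors-in-variables MLE
  delta <- 1 / lambda
  with(mom, {
    if (abs(sxy) < .Machine$double.eps * max(syy, delta * sxx, 1)) {
      # degenerate uncorrelated case: convention, positive root
      sqrt(delta * syy / sxx)
    } else {
      (syy - delta * sxx + sqrt((syy - delta * sxx)^2 + 4 * delta * sxy^2)) /
        (2 * sxy)
    }
  })
}

#' Deming (errors-in-variables) regression
#'
#' Fits a straight line when both axes are measured with error, minimising
#' the sum of squared residuals measured in the metric set by `lambda`, the
#' assumed ratio of x-error variance to y-error variance. `lambda = 1`
#' (the default, appropriate when both axes are allele-frequency estimates
#' of comparable precision) gives orthogonal regression; as `lambda` tends
#' to 0 the x axis is treated as error-free and the fit approaches ordinary
#' least squares of y on x. The closed-form slope is
#' `(syy - delta*sxx + sqrt((syy - delta*sxx)^2 + 4*delta*sxy^2)) / (2*sxy)`
#' with `delta = 1/lambda`, and the line always passes through the centroid
#' `(xbar, ybar)`. When `sxy = 0` exactly, the positive root
#' `sqrt(delta*syy/sxx)` is returned by convention.
#'
#' @param x,y numeric vectors of equal length n >= 3; x must not be
#'   constant.
#' @param lambda positive error-variance ratio (x over y); default 1.
#' @return a [DemingFit-class] with slope and intercept filled in (use
#'   [demingRegression()] for slope inference).
#' @examples
#' demingFit(c(0, 1, 2), c(0, 1, 2))  # exact identity line
#' @export
demingFit <- function(x, y, lambda = 1) {
  .assertScalarNumber(lambda, "lambda", positive = TRUE)
  n <- length(x)
  if (length(y) != n) stop("x and y must have equal length", call. = FALSE)
  if (n < 3L) stop("Deming regression needs at least 3 points", call. = FALSE)
  if (anyNA(x) || anyNA(y)) stop("x and y must not contain NA", call. = FALSE)
  mom <- .demingMoments(x, y)
  if (mom$sxx < .Machine$double.eps)
    stop("degenerate data: x is constant", call. = FALSE)
  slope <- .demingSlopeFromMoments(mom, lambda)
  new("DemingFit", slope = slope, intercept = mom$ybar - slope * mom$xbar,
      n = as.integer(n), lambda = lambda)
}

#' Jackknife standard error of the Deming slope
#'
#' Delete-one jackknife: refits the slope with each point removed and
#' returns `sqrt(((n-1)/n) * sum((b_i - mean(b))^2))`. This is the standard
#' resampling route to slope uncertainty for errors-in-variables fits,
#' where no exact finite-sample SE exists.
#'
#' @param x,y numeric vectors of equal length n >= 4.
#' @param lambda error-variance ratio, as in [demingFit()].
#' @return the jackknife standard error (0 for exactly collinear data).
#' @export
demingSlopeSE <- function(x, y, lambda = 1) {
  n <- length(x)
  if (length(y) != n) stop("x and y must have equal length", call. = FALSE)
  if (n < 4L)
    stop("jackknife slope SE needs at least 4 points", call. = FALSE)
  b <- vapply(seq_len(n), function(i) {
    fit <- tryCatch(demingFit(x[-i], y[-i], lambda = lambda),
                    error = function(e)
                      stop("degenerate leave-one-out fit (point ", i, "): ",
                           conditionMessage(e), call. = FALSE))
    fit@slope
  }, 0)
  sqrt((n - 1) / n * sum((b - mean(b))^2))
}

#' Deming regression with slope inference
#'
#' Convenience wrapper around [demingFit()] and [demingSlopeSE()] that also
#' tests the slope against 1 (the identity line of equal allele frequencies
#' in both populations) and against 0, two-sided, using a t reference
#' distribution with n - 2 degrees of freedom.
#'
#' @inheritParams demingFit
#' @return a fully populated [DemingFit-class].
#' @export
demingRegression <- function(x, y, lambda = 1) {
  fit <- demingFit(x, y, lambda = lambda)
  fit@slopeSE <- demingSlopeSE(x, y, lambda = lambda)
  fit@pSlopeVsOne <- testSlope(fit, 1)
  fit@pSlopeVsZero <- testSlope(fit, 0)
  fit
}

#' @rdname testSlope
#' @export
setMethod("testSlope", "DemingFit", function(fit, reference = 1) {
  if (is.na(fit@slopeSE))
    stop("fit has no slope standard error; use demingRegression() or ",
         "demingSlopeSE()", call. = FALSE)
  if (fit@slopeSE == 0) {
    if (fit@slope == reference) return(1)
    warning("zero slope SE with slope != reference: p degenerates to 0",
            call. = FALSE)
    return(0)
  }
  tstat <- (fit@slope - reference) / fit@slopeSE
  2 * stats::pt(-abs(tstat), df = fit@n - 2L)
})

#' Compare risk-allele frequency burden between two populations
#'
#' Extracts the per-unit pooled (F) or OR-weighted (Fw) frequencies of two
#' populations from an aggregated catalog and runs the one-tailed t-test.
#'
#' @param aggregated an [AggregatedCatalog-class].
#' @param popA,popB population labels (both must be in the catalog).
#' @param useWeighted compare Fw (TRUE, default) or F.
#' @param direction,variant passed to [oneTailedTTest()]; `direction =
#'   "greater"` tests popA > popB.
#' @return object of class `"ComparisonResult"`: a list with `pop_a`,
#'   `pop_b`, `used` ("F" or "Fw"), `mean_a`, `mean_b`, `n_units`, and
#'   `ttest` (a `"TTestResult"`).
#' @export
comparePopulations <- function(aggregated, popA, popB, useWeighted = TRUE,
                               direction = c("greater", "less"),
                               variant = c("student", "welch", "paired")) {
  stopifnot(is(aggregated, "AggregatedCatalog"))
  direction <- match.arg(direction)
  variant <- match.arg(variant)
  suffix <- if (useWeighted) "_Fw" else "_F"
  for (pop in c(popA, popB))
    if (!pop %in% populations(aggregated))
      stop("population '", pop, "' not in the aggregated catalog", call. = FALSE)
  u <- aggregatedUnits(aggregated)
  a <- u[[paste0(popA, suffix)]]
  b <- u[[paste0(popB, suffix)]]
  tt <- oneTailedTTest(a, b, direction = direction, variant = variant)
  structure(list(pop_a = popA, pop_b = popB,
                 used = if (useWeighted) "Fw" else "F",
                 mean_a = mean(a), mean_b = mean(b), n_units = nrow(u),
                 ttest = tt),
            class = "ComparisonResult")
}

#' @export
print.ComparisonResult <- function(x, ...) {
  cat(sprintf("Population comparison on %s (%d units): %s vs %s\n", x$used,
              x$n_units, x$pop_a, x$pop_b))
  cat(sprintf("  mean %s = %.4f, mean %s = %.4f\n", x$pop_a, x$mean_a,
              x$pop_b, x$mean_b))
  cat(sprintf("  %s t-test, %s: p = %.4g\n", x$ttest$variant,
              x$ttest$direction, x$ttest$p_one_tailed))
  invisible(x)
}
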
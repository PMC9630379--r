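# Independent oracles, written from the textbook definitions and kept free
# of any package internals.

# Closed-form one-tailed t-tests.
oracleTTest <- function(a, b, direction, variant) {
  if (variant == "paired") {
    d <- a - b
    n <- length(d)
    t <- mean(d) / (stats::sd(d) / sqrt(n))
    df <- n - 1
  } else if (variant == "student") {
    na <- length(a); nb <- length(b)
    sp2 <- ((na - 1) * stats::var(a) + (nb - 1) * stats::var(b)) / (na + nb - 2)
    t <- (mean(a) - mean(b)) / sqrt(sp2 * (1 / na + 1 / nb))
    df <- na + nb - 2
  } else { # welch
    na <- length(a); nb <- length(b)
    va <- stats::var(a) / na; vb <- stats::var(b) / nb
    t <- (mean(a) - mean(b)) / sqrt(va + vb)
    df <- (va + vb)^2 / (va^2 / (na - 1) + vb^2 / (nb - 1))
  }
  p <- if (direction == "greater") stats::pt(t, df, lower.tail = FALSE)
       else stats::pt(t, df)
  list(t = t, df = df, p = p)
}

# Brute-force errors-in-variables slope: profile the intercept out
# (a = ybar - b*xbar) and minimise sum((y - a - b*x)^2) / (1 + lambda*b^2)
# over the slope by coarse grid + local golden-section refinement.
# lambda is the x-error / y-error variance ratio; lambda = 1 minimises
# plain perpendicular distance.
oracleDemingSlope <- function(x, y, lambda = 1) {
  xc <- x - mean(x); yc <- y - mean(y)
  f <- function(b) sum((yc - b * xc)^2) / (1 + lambda * b^2)
  grid <- seq(-50, 50, length.out = 20001)
  b0 <- grid[which.min(vapply(grid, f, 0))]
  stats::optimize(f, c(b0 - 0.01, b0 + 0.01), tol = 1e-12)$minimum
}

oracleOlsSlope <- function(x, y) stats::cov(x, y) / stats::var(x)

# Random small scatter roughly mimicking frequency data on a line.
randomScatter <- function(n = NULL) {
  if (is.null(n)) n <- sample(5:30, 1L)
  x <- stats::runif(n)
  slope <- stats::runif(1, 0.3, 2.5)
  y <- slope * x + stats::rnorm(n, 0, 0.1)
  list(x = x, y = y)
}
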
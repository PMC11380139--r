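# Independent oracles used across the suite. Each is deliberately written in
# a different way from the implementation it checks.

# textbook weighted least squares via explicit normal equations
wlsOracle <- function(X, y, w) {
  XtWX <- t(X) %*% (w * X)
  coef <- drop(solve(XtWX, t(X) %*% (w * y)))
  list(coef = coef, covUnscaled = solve(XtWX))
}

# weighted 50th percentile by cumulative-weight scan + stats::approx
# interpolation
wmedianOracle <- function(theta, w) {
  o <- order(theta)
  th <- theta[o]
  ww <- w[o] / sum(w)
  p <- cumsum(ww) - 0.5 * ww
  if (p[1] >= 0.5) return(th[1])
  if (p[length(p)] <= 0.5) return(th[length(th)])
  stats::approx(x = p, y = th, xout = 0.5, ties = "ordered")$y
}

# chi-square survival function by numerical quadrature of the density
chisqSurvOracle <- function(q, df) {
  dens <- function(x) x^(df / 2 - 1) * exp(-x / 2) / (2^(df / 2) * gamma(df / 2))
  stats::integrate(dens, q, Inf, rel.tol = 1e-13, abs.tol = 1e-16)$value
}

# delta-method ratio SE via numerical gradients (central differences)
ratioSEOracle <- function(bx, by, sx, sy) {
  f <- function(x, y) y / x
  hX <- 1e-6 * max(abs(bx), 1)
  hY <- 1e-6 * max(abs(by), 1)
  gx <- (f(bx + hX, by) - f(bx - hX, by)) / (2 * hX)
  gy <- (f(bx, by + hY) - f(bx, by - hY)) / (2 * hY)
  sqrt(gx^2 * sx^2 + gy^2 * sy^2)
}

sampleSkewness <- function(x) {
  m <- mean(x)
  mean((x - m)^3) / (mean((x - m)^2))^1.5
}
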
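# internal MRResult builder; pval = NULL derives a normal two-sided p from
# beta/se.
.mrResult <- function(method, nSnp, beta, se, pval = NULL, level = 0.95,
                      extras = list()) {
  beta <- unname(beta); se <- unname(se)
  pval <- unname(pval %||% twoSidedNormalP(beta / se))
  pval <- min(max(pval, .Machine$double.xmin), 1)
  z <- qnorm(1 - (1 - level) / 2)
  new("MRResult", method = method, nSnp = as.integer(nSnp),
      beta = beta, se = se, pval = pval,
      or = exp(beta), ciLow = exp(beta - z * se), ciHigh = exp(beta + z * se),
      level = level, extras = extras)
}

#' Odds ratio and confidence interval from a log-scale estimate
#'
#' @param beta log odds-ratio estimate.
#' @param se its standard error (> 0).
#' @param level confidence level (default 0.95).
#' @return list with `or = exp(beta)`, `ci_low`/`ci_high` (`exp(beta -/+
#'   z * se)`) and the two-sided normal `pval`.
#' @export
orCI <- function(beta, se, level = 0.95) {
  stopifnot(se > 0, level > 0, level < 1)
  z <- qnorm(1 - (1 - level) / 2)
  list(or = exp(beta), ci_low = exp(beta - z * se),
       ci_high = exp(beta + z * se), pval = twoSidedNormalP(beta / se))
}

#' Single-SNP Wald ratio estimate
#'
#' The per-variant causal estimate `by / bx` with the first-order standard
#' error `sy / |bx|` (the exposure-side uncertainty `sx` is ignored at first
#' order, standard two-sample practice when instruments are strong);
#' `secondOrder = TRUE` adds the exposure term by the delta method.
#'
#' @param bx,by exposure and outcome per-allele effects.
#' @param sx,sy their standard errors (`sx` used only at second order).
#' @param secondOrder use the second-order delta-method variance.
#' @param level confidence level.
#' @return An [MRResult-class] object.
#' @export
waldRatio <- function(bx, by, sx = NA_real_, sy, secondOrder = FALSE,
                      level = 0.95) {
  if (bx == 0) stop("null instrument: exposure effect is zero")
  beta <- by / bx
  se <- if (secondOrder) {
    if (!is.finite(sx)) stop("second-order variance needs sx")
    sqrt(sy^2 / bx^2 + by^2 * sx^2 / bx^4)
  } else sy / abs(bx)
  .mrResult("wald_ratio", 1L, beta, se, level = level,
            extras = list(second_order = secondOrder))
}

# ratio estimates and first/second-order inverse-variance weights
.ratioParts <- function(d, weights = c("first_order", "second_order")) {
  weights <- match.arg(weights)
  if (any(d$beta_exposure == 0)) stop("null instrument: beta_exposure == 0")
  theta <- d$beta_outcome / d$beta_exposure
  varRatio <- switch(weights,
    first_order = d$se_outcome^2 / d$beta_exposure^2,
    second_order = d$se_outcome^2 / d$beta_exposure^2 +
      d$beta_outcome^2 * d$se_exposure^2 / d$beta_exposure^4)
  list(theta = theta, w = 1 / varRatio)
}

#' Inverse-variance weighted estimator
#'
#' The weighted average of per-SNP Wald ratios with weights inverse to their
#' first-order variances (equivalently, no-intercept weighted least squares of
#' `by` on `bx` with weights `1/sy^2`). `mode = "fixed"` uses
#' `se = (sum w)^(-1/2)`; `"random"` multiplies by
#' `sqrt(max(1, Q / (J - 1)))` (multiplicative overdispersion floored at 1);
#' `"auto"` picks random effects iff the Cochran-Q p-value is below 0.05 and
#' records the choice in `extras$mode_used`.
#'
#' @param h a [HarmonizedSet-class] with at least 2 SNPs.
#' @param mode `"auto"`, `"fixed"` or `"random"`.
#' @param weights `"first_order"` (default) or `"second_order"` ratio
#'   variances.
#' @param level confidence level.
#' @return An [MRResult-class]; `extras` carries `Q`, `Q_df`, `Q_pval`,
#'   `overdispersion` and `mode_used`.
#' @export
mrIVW <- function(h, mode = c("auto", "fixed", "random"),
                  weights = c("first_order", "second_order"), level = 0.95) {
  mode <- match.arg(mode); weights <- match.arg(weights)
  d <- harmonizedData(h)
  J <- nrow(d)
  if (J < 2) stop("IVW needs >= 2 instruments; use waldRatio() for one SNP")
  rp <- .ratioParts(d, weights)
  beta <- sum(rp$w * rp$theta) / sum(rp$w)
  seFixed <- sqrt(1 / sum(rp$w))
  Q <- sum(rp$w * (rp$theta - beta)^2)
  qdf <- J - 1L
  qp <- pchisq(Q, qdf, lower.tail = FALSE)
  phi <- max(1, Q / qdf)
  used <- switch(mode, fixed = "fixed", random = "random",
                 auto = if (qp < 0.05) "random" else "fixed")
  se <- if (used == "random") seFixed * sqrt(phi) else seFixed
  .mrResult(paste0("ivw_", mode), J, beta, se, level = level,
            extras = list(mode_used = used, Q = Q, Q_df = qdf, Q_pval = qp,
                          overdispersion = phi, weights = weights))
}

#' MR-Egger regression
#'
#' Weighted linear regression of the outcome effects on the exposure effects
#' **with** an intercept (weights `1/sy^2`), after orienting every row so the
#' exposure effect is non-negative (both betas flipped where needed). The
#' slope is the causal estimate; a non-zero intercept indicates directional
#' pleiotropy. Both variance estimates carry the multiplicative residual
#' overdispersion factor `max(1, RSS_w / (J - 2))`; slope and intercept
#' p-values use Student-t with `J - 2` df.
#'
#' @param h a [HarmonizedSet-class] with at least 3 SNPs.
#' @param level confidence level.
#' @return An [MRResult-class]; `extras` carries `intercept`,
#'   `intercept_se`, `intercept_pval`, `Q` (weighted RSS), `Q_df` and
#'   `overdispersion`.
#' @export
mrEgger <- function(h, level = 0.95) {
  d <- harmonizedData(h)
  J <- nrow(d)
  if (J < 3) stop("MR-Egger needs >= 3 instruments (slope + intercept + 1 df)")
  flip <- d$beta_exposure < 0
  bx <- abs(d$beta_exposure)
  by <- ifelse(flip, -d$beta_outcome, d$beta_outcome)
  if (diff(range(bx)) < .Machine$double.eps * max(abs(bx)))
    stop("exposure effects have no spread; the Egger slope is unidentifiable")
  w <- 1 / d$se_outcome^2
  fit <- lm(by ~ bx, weights = w)
  co <- stats::coef(fit)
  res <- by - co[1] - co[2] * bx
  rssw <- sum(w * res^2)
  df <- J - 2L
  sigma2 <- rssw / df
  phi <- max(1, sigma2)
  X <- cbind(1, bx)
  covUnscaled <- solve(crossprod(X, w * X))
  se <- sqrt(diag(covUnscaled) * phi)
  slope <- unname(co[2]); slopeSE <- se[2]
  intercept <- unname(co[1]); interceptSE <- se[1]
  .mrResult("egger", J, slope, slopeSE,
            pval = twoSidedTP(slope / slopeSE, df), level = level,
            extras = list(intercept = intercept, intercept_se = interceptSE,
                          intercept_pval = twoSidedTP(intercept / interceptSE, df),
                          Q = rssw, Q_df = df, overdispersion = phi))
}

# weighted 50th percentile with linear interpolation between bracketing
# order statistics; exact sample median for equal weights and odd J
.weightedMedian <- function(theta, w) {
  o <- order(theta)
  th <- theta[o]
  ww <- w[o] / sum(w)
  p <- cumsum(ww) - 0.5 * ww
  n <- length(th)
  if (p[1] >= 0.5) return(th[1])
  if (p[n] <= 0.5) return(th[n])
  i <- max(which(p <= 0.5))
  if (abs(p[i] - 0.5) < 1e-12) return(th[i])
  th[i] + (th[i + 1] - th[i]) * (0.5 - p[i]) / (p[i + 1] - p[i])
}

# parametric bootstrap SE shared by median/mode: resample (bx, by) from
# normals at their SEs, recompute the point estimate, return the SD
.bootstrapSE <- function(d, pointFun, nBoot, seed) {
  J <- nrow(d)
  withSeed(seed, {
    bxs <- matrix(rnorm(J * nBoot, mean = d$beta_exposure,
                        sd = d$se_exposure), nrow = J)
    bys <- matrix(rnorm(J * nBoot, mean = d$beta_outcome,
                        sd = d$se_outcome), nrow = J)
    est <- vapply(seq_len(nBoot), function(i) {
      bx <- bxs[, i]
      bx[bx == 0] <- .Machine$double.eps
      pointFun(bys[, i] / bx, bx^2 / d$se_outcome^2)
    }, numeric(1))
    sd(est)
  })
}

#' Weighted-median estimator
#'
#' The weighted 50th percentile of the per-SNP ratio estimates, weights
#' inverse to the first-order ratio variances, with linear interpolation
#' between bracketing order statistics. Consistent when at least half the
#' weight comes from valid instruments. The standard error comes from a
#' parametric bootstrap (resampling `bx`, `by` from normals at their reported
#' SEs); `seed` makes it reproducible.
#'
#' @param h a [HarmonizedSet-class] with at least 3 SNPs.
#' @param nBoot bootstrap replicates (default 1000).
#' @param seed integer seed for the bootstrap (`NULL` uses the ambient RNG
#'   stream).
#' @param level confidence level.
#' @return An [MRResult-class]; `extras` records `n_boot` and `seed`.
#' @export
mrWeightedMedian <- function(h, nBoot = 1000, seed = NULL, level = 0.95) {
  if (nBoot < 1) stop("nBoot must be a positive integer")
  d <- harmonizedData(h)
  if (nrow(d) < 3) stop("weighted median needs >= 3 instruments")
  rp <- .ratioParts(d)
  beta <- .weightedMedian(rp$theta, rp$w)
  se <- .bootstrapSE(d, .weightedMedian, nBoot, seed)
  .mrResult("weighted_median", nrow(d), beta, se, level = level,
            extras = list(n_boot = nBoot, seed = seed))
}

# weighted Gaussian kernel density argmax; bandwidth = phi x Silverman's rule
.modeEstimate <- function(theta, w, phi = 1) {
  wn <- w / sum(w)
  s <- sd(theta)
  iqr <- stats::IQR(theta) / 1.349
  spread <- min(s, if (iqr > 0) iqr else s)
  bw <- phi * 0.9 * spread / length(theta)^0.2
  if (!is.finite(bw) || bw <= 0) return(theta[which.max(wn)])
  dens <- function(x)
    vapply(x, function(xx) sum(wn * dnorm(xx, mean = theta, sd = bw)),
           numeric(1))
  grid <- seq(min(theta) - 3 * bw, max(theta) + 3 * bw, length.out = 512)
  i <- which.max(dens(grid))
  lo <- grid[max(1L, i - 1L)]
  hi <- grid[min(length(grid), i + 1L)]
  if (lo == hi) return(grid[i])
  optimize(dens, c(lo, hi), maximum = TRUE)$maximum
}

#' Weighted-mode estimator
#'
#' The maximizer of a weighted Gaussian kernel density over the per-SNP ratio
#' estimates: the causal effect of the largest cluster of agreeing
#' instruments. Bandwidth is `phi` times Silverman's rule
#' (`0.9 min(sd, IQR/1.349) J^{-1/5}`). Bootstrap SE as in
#' [mrWeightedMedian()].
#'
#' @param h a [HarmonizedSet-class] with at least 3 SNPs.
#' @param phi bandwidth multiplier (> 0, default 1).
#' @param nBoot bootstrap replicates (default 1000).
#' @param seed integer seed for the bootstrap.
#' @param level confidence level.
#' @return An [MRResult-class]; `extras` records `phi`, `n_boot`, `seed`.
#' @export
mrWeightedMode <- function(h, phi = 1, nBoot = 1000, seed = NULL,
                           level = 0.95) {
  if (phi <= 0) stop("phi must be > 0")
  if (nBoot < 1) stop("nBoot must be a positive integer")
  d <- harmonizedData(h)
  if (nrow(d) < 3) stop("weighted mode needs >= 3 instruments")
  rp <- .ratioParts(d)
  beta <- .modeEstimate(rp$theta, rp$w, phi)
  se <- .bootstrapSE(d, function(th, w) .modeEstimate(th, w, phi), nBoot, seed)
  .mrResult("weighted_mode", nrow(d), beta, se, level = level,
            extras = list(phi = phi, n_boot = nBoot, seed = seed))
}

#' Run the standard estimator battery on a harmonized set
#'
#' IVW (auto fixed/random) plus, when enough instruments are available,
#' MR-Egger, the weighted median and the weighted mode; a single SNP falls
#' back to the Wald ratio. Also records whether all computed estimates share
#' one beta sign (`attr(, "direction_consistent")`), the direction-consistency
#' convention used when supplementary methods are non-significant.
#'
#' @param h a [HarmonizedSet-class].
#' @param nBoot,seed bootstrap controls for median/mode.
#' @param level confidence level.
#' @return Named list of [MRResult-class] objects with attribute
#'   `direction_consistent`.
#' @export
mrAllMethods <- function(h, nBoot = 1000, seed = NULL, level = 0.95) {
  d <- harmonizedData(h)
  J <- nrow(d)
  out <- list()
  if (J == 1L) {
    out$wald_ratio <- waldRatio(d$beta_exposure, d$beta_outcome,
                                d$se_exposure, d$se_outcome, level = level)
  } else {
    out$ivw_auto <- mrIVW(h, mode = "auto", level = level)
    if (J >= 3L) {
      out$egger <- mrEgger(h, level = level)
      out$weighted_median <- mrWeightedMedian(h, nBoot = nBoot,
                                              seed = deriveSeed(seed, 1),
                                              level = level)
      out$weighted_mode <- mrWeightedMode(h, nBoot = nBoot,
                                          seed = deriveSeed(seed, 2),
                                          level = level)
    }
  }
  signs <- vapply(out, function(r) sign(mrBeta(r)), numeric(1))
  attr(out, "direction_consistent") <-
    length(unique(signs[signs != 0])) <= 1L
  out
}
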
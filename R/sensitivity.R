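#' Cochran's Q heterogeneity test
#'
#' `Q = sum_j w_j (theta_j - theta)^2` over the per-SNP ratio estimates, with
#' an upper chi-square tail p-value. Defaults reproduce the IVW fit: `theta`
#' is the fixed-effects IVW estimate, the weights are the first-order
#' inverse-variance weights, and `df = J - 1`; pass `df = J - 2` (with the
#' Egger slope as `theta`) for the Egger variant.
#'
#' @param h a [HarmonizedSet-class] with at least 2 SNPs.
#' @param theta pooled estimate to test against (default: IVW fixed).
#' @param weights per-SNP weights (default: first-order inverse variances).
#' @param df degrees of freedom (default `J - 1`).
#' @return A [HeterogeneityResult-class] object.
#' @export
cochranQ <- function(h, theta = NULL, weights = NULL, df = NULL) {
  d <- harmonizedData(h)
  J <- nrow(d)
  if (J < 2) stop("Cochran's Q needs >= 2 instruments")
  rp <- .ratioParts(d)
  w <- weights %||% rp$w
  theta <- theta %||% (sum(rp$w * rp$theta) / sum(rp$w))
  Q <- sum(w * (rp$theta - theta)^2)
  df <- as.integer(df %||% (J - 1L))
  new("HeterogeneityResult", Q = Q, df = df,
      pval = max(pchisq(Q, df, lower.tail = FALSE), .Machine$double.xmin))
}

#' MR-Egger intercept test for directional pleiotropy
#'
#' The intercept of the Egger regression with its standard error and a
#' two-sided Student-t p-value on `J - 2` df; a small p indicates directional
#' pleiotropy.
#'
#' @param h a [HarmonizedSet-class] with at least 3 SNPs.
#' @return list with `intercept`, `se` and `pval`.
#' @export
eggerInterceptTest <- function(h) {
  e <- mrExtras(mrEgger(h))
  list(intercept = e$intercept, se = e$intercept_se, pval = e$intercept_pval)
}

#' Simulation-based pleiotropy residual-sum-of-squares outlier test
#'
#' Monte-Carlo test in three parts. *Global*: the observed statistic is
#' `RSS = sum_j (by_j - theta_(-j) bx_j)^2 / sy_j^2`, where `theta_(-j)` is
#' the leave-one-out IVW estimate; `nSim` datasets are simulated with
#' `by*_j ~ N(theta_(-j) bx_j, sy_j)`, the statistic recomputed on each, and
#' the p-value is the add-one Monte-Carlo tail `(1 + #{RSS* >= RSS}) /
#' (nSim + 1)` (resolution `1/(nSim + 1)`; never exactly zero). *Outlier*:
#' each SNP's observed residual term is referred to its own simulated
#' distribution; per-SNP p-values are Bonferroni-adjusted across the J SNPs
#' and flagged below `outlierAlpha`. *Distortion*: the change in the IVW
#' estimate after removing the flagged SNPs is referred to the distribution
#' of changes obtained by removing random same-size SNP subsets.
#'
#' Flagged SNPs should be removed and the estimators re-run once; the
#' orchestration layer does exactly that.
#'
#' @param h a [HarmonizedSet-class] with at least 4 SNPs.
#' @param nSim simulated datasets (default 3000).
#' @param outlierAlpha significance level for the Bonferroni-adjusted
#'   per-SNP test (default 0.05).
#' @param seed integer seed; the Monte-Carlo p is bit-reproducible given
#'   `(nSim, seed)`.
#' @param level confidence level for the embedded IVW estimates.
#' @return A [PressoReport-class] object.
#' @export
mrPresso <- function(h, nSim = 3000, outlierAlpha = 0.05, seed = NULL,
                     level = 0.95) {
  d <- harmonizedData(h)
  J <- nrow(d)
  if (J < 4) stop("outlier test undefined below 4 instruments (J = ", J, ")")
  bx <- d$beta_exposure; by <- d$beta_outcome; sy <- d$se_outcome
  wiv <- bx^2 / sy^2
  th <- by / bx
  Sw <- sum(wiv)
  Sxy <- sum(wiv * th)
  looTheta <- (Sxy - wiv * th) / (Sw - wiv)
  resObs <- (by - looTheta * bx)^2 / sy^2
  rssObs <- sum(resObs)

  # parametric replicates resample BOTH sides: bx* ~ N(bx, sx) and
  # by* ~ N(theta_(-j) bx, sy). Resampling only the outcome would leave the
  # replicate residual variance at sy^2 while the observed residuals carry
  # sy^2 + theta^2 sx^2, and the global test would reject under the null.
  sx <- d$se_exposure
  sims <- withSeed(seed, list(
    bx = matrix(rnorm(J * nSim, mean = bx, sd = sx), nrow = J),
    by = matrix(rnorm(J * nSim, mean = looTheta * bx, sd = sy), nrow = J)))
  wSim <- sims$bx^2 / sy^2
  num <- sims$bx * sims$by / sy^2   # J x S matrix of bx* by* / sy^2
  looSim <- (rep(colSums(num), each = J) - num) /
    (rep(colSums(wSim), each = J) - wSim)
  resSim <- (sims$by - looSim * sims$bx)^2 / sy^2
  rssSim <- colSums(resSim)
  globalP <- (1 + sum(rssSim >= rssObs)) / (nSim + 1)
  pSnp <- (1 + rowSums(resSim >= resObs)) / (nSim + 1)
  names(pSnp) <- d$snp
  pAdj <- pmin(1, pSnp * J)
  outliers <- d$snp[pAdj < outlierAlpha]

  raw <- mrIVW(h, mode = "auto", level = level)
  corrected <- NULL
  distortion <- NA_real_
  if (length(outliers) && (J - length(outliers)) >= 2L) {
    corrected <- mrIVW(subsetHarmonized(h, !(d$snp %in% outliers)),
                       mode = "auto", level = level)
    dObs <- mrBeta(corrected) - mrBeta(raw)
    k <- length(outliers)
    nd <- min(nSim, 1000L)
    dSim <- withSeed(deriveSeed(seed, 1), vapply(seq_len(nd), function(i) {
      drop <- sample.int(J, k)
      sum(wiv[-drop] * th[-drop]) / sum(wiv[-drop]) - mrBeta(raw)
    }, numeric(1)))
    distortion <- (1 + sum(abs(dSim) >= abs(dObs))) / (nd + 1)
  } else if (length(outliers)) {
    # every SNP (or all but one) flagged: corrected estimate undefined
    outliers <- character()
  }
  new("PressoReport", observedRSS = rssObs, globalPval = globalP,
      nSim = as.integer(nSim), perSnpPvals = pSnp, outliers = outliers,
      rawEstimate = raw, correctedEstimate = corrected,
      distortionPval = distortion)
}

#' Leave-one-out sensitivity analysis
#'
#' Re-estimates the IVW (auto) effect J times, each time omitting one SNP,
#' and flags omissions that change the estimate's sign or its significance at
#' 0.05 relative to the full-set fit — the signature of a single variant
#' driving the result.
#'
#' @param h a [HarmonizedSet-class] with at least 3 SNPs.
#' @param level confidence level.
#' @return data.frame with one row per omitted SNP: `snp_excluded, n_snp,
#'   beta, se, pval, or, ci_low, ci_high, sign_change, significance_change,
#'   flagged`.
#' @export
leaveOneOut <- function(h, level = 0.95) {
  d <- harmonizedData(h)
  J <- nrow(d)
  if (J < 3) stop("leave-one-out needs >= 3 instruments")
  full <- mrIVW(h, mode = "auto", level = level)
  rows <- lapply(seq_len(J), function(j) {
    r <- mrIVW(subsetHarmonized(h, seq_len(J) != j), mode = "auto",
               level = level)
    data.frame(snp_excluded = d$snp[j], n_snp = nSnp(r), beta = mrBeta(r),
               se = mrSE(r), pval = mrPval(r), or = oddsRatio(r),
               ci_low = confInt(r)[["ciLow"]], ci_high = confInt(r)[["ciHigh"]],
               sign_change = sign(mrBeta(r)) != sign(mrBeta(full)),
               significance_change =
                 (mrPval(r) < 0.05) != (mrPval(full) < 0.05),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out$flagged <- out$sign_change | out$significance_change
  attr(out, "full_estimate") <- full
  out
}

#' Funnel-plot data
#'
#' Per-SNP ratio estimates against their precisions (1/se of the ratio),
#' with the IVW and Egger reference-line parameters; asymmetry suggests
#' directional pleiotropy.
#'
#' @param h a [HarmonizedSet-class] (>= 1 SNP).
#' @return list with `data` (data.frame `snp, ratio, precision`), `ivw_beta`,
#'   and, when J >= 3, `egger_beta` and `egger_intercept` (else `NA`).
#' @export
funnelData <- function(h) {
  d <- harmonizedData(h)
  if (!nrow(d)) stop("empty harmonized set")
  seRatio <- d$se_outcome / abs(d$beta_exposure)
  dat <- data.frame(snp = d$snp, ratio = d$beta_outcome / d$beta_exposure,
                    precision = 1 / seRatio, stringsAsFactors = FALSE)
  ivwBeta <- if (nrow(d) >= 2) mrBeta(mrIVW(h, mode = "fixed")) else
    dat$ratio[1]
  eggerBeta <- eggerInt <- NA_real_
  if (nrow(d) >= 3) {
    e <- mrEgger(h)
    eggerBeta <- mrBeta(e)
    eggerInt <- mrExtras(e)$intercept
  }
  list(data = dat, ivw_beta = ivwBeta, egger_beta = eggerBeta,
       egger_intercept = eggerInt)
}
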
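#' Simulation configuration for synthetic GWAS summary statistics
#'
#' Builds and validates the configuration consumed by [simulatePair()] and
#' [simulateMediationChain()]. Defaults emulate a cytokine-exposure /
#' disease-endpoint two-sample design: an exposure GWAS of 8,293 individuals,
#' a binary outcome with 287 cases against 360,143 controls (effects on the
#' log odds-ratio scale), allele frequencies uniform on (0.1, 0.9), and
#' per-SNP exposure effects with magnitude scale 0.15 coded on the
#' exposure-increasing allele — yielding per-SNP F statistics spanning the
#' weak-to-strong range seen in practice (roughly 10 to several hundred).
#'
#' @param nSnp number of instruments (default 30).
#' @param theta true causal effect of exposure on outcome (default 0).
#' @param nExposure exposure GWAS sample size (default 8293).
#' @param nCase,nControl outcome case/control counts (defaults 287 and
#'   360143); their sum is the outcome sample size.
#' @param nOutcome outcome sample size; overrides `nCase + nControl` when
#'   given (used for quantitative outcomes).
#' @param eafRange range of effect-allele frequencies (default `c(0.1, 0.9)`).
#' @param exposureEffectScale scale of the half-normal true exposure effect
#'   magnitudes (default 0.15).
#' @param pleiotropy list `(mu, sd, fraction)`: the affected fraction of SNPs
#'   receives a direct (horizontal) outcome effect drawn from
#'   `N(mu, sd^2)`; `mu != 0` is directional pleiotropy, `mu = 0` balanced.
#'   Default: none. Pleiotropic effects are drawn independently of
#'   instrument strength, so the InSIDE condition holds by construction;
#'   `insideViolation > 0` adds that multiple of the centred true exposure
#'   effect to each pleiotropic effect to stress-test Egger.
#' @param outliers list `(n, offset, relative)`: `n` SNPs get `offset` added
#'   to their observed outcome effect; with `relative = TRUE` (default) the
#'   offset is `offset` times the median absolute observed outcome effect.
#' @param palindromicFraction fraction of SNPs given A/T or C/G allele pairs
#'   (default 0.17, the approximate genome-wide share).
#' @param binaryOutcome interpret outcome effects as log odds ratios
#'   (default TRUE); the sampling-error scale is the same closed form either
#'   way (standardized-trait model).
#' @param insideViolation correlation knob described under `pleiotropy`.
#' @param seed integer seed driving all draws (default 1).
#' @return A validated list of class `SimulationConfig`.
#' @export
simConfig <- function(nSnp = 30, theta = 0, nExposure = 8293,
                      nCase = 287, nControl = 360143, nOutcome = NULL,
                      eafRange = c(0.1, 0.9), exposureEffectScale = 0.15,
                      pleiotropy = list(mu = 0, sd = 0, fraction = 0),
                      outliers = list(n = 0, offset = 0, relative = TRUE),
                      palindromicFraction = 0.17, binaryOutcome = TRUE,
                      insideViolation = 0, seed = 1) {
  pleiotropy <- utils::modifyList(list(mu = 0, sd = 0, fraction = 0),
                                  pleiotropy)
  outliers <- utils::modifyList(list(n = 0, offset = 0, relative = TRUE),
                                outliers)
  if (!is.null(nOutcome) && isTRUE(binaryOutcome))
    nControl <- nOutcome - nCase   # keep n = nCase + nControl consistent
  nOutcome <- nOutcome %||% (nCase + nControl)
  cfg <- list(nSnp = as.integer(nSnp), theta = theta,
              nExposure = nExposure, nCase = nCase, nControl = nControl,
              nOutcome = nOutcome, eafRange = eafRange,
              exposureEffectScale = exposureEffectScale,
              pleiotropy = pleiotropy, outliers = outliers,
              palindromicFraction = palindromicFraction,
              binaryOutcome = isTRUE(binaryOutcome),
              insideViolation = insideViolation,
              seed = as.integer(seed))
  ok <- cfg$nSnp >= 1 && cfg$nExposure > 1 && cfg$nOutcome > 1 &&
    length(eafRange) == 2 && eafRange[1] > 0 && eafRange[2] < 1 &&
    eafRange[1] <= eafRange[2] &&
    exposureEffectScale > 0 &&
    pleiotropy$sd >= 0 && pleiotropy$fraction >= 0 &&
    pleiotropy$fraction <= 1 &&
    outliers$n >= 0 && outliers$n <= cfg$nSnp &&
    palindromicFraction >= 0 && palindromicFraction <= 1
  if (!ok) stop("invalid simulation configuration")
  class(cfg) <- "SimulationConfig"
  cfg
}

.NONPAL_PAIRS <- matrix(c("A", "G", "A", "C", "T", "G", "T", "C",
                          "G", "A", "C", "A", "G", "T", "C", "T"),
                        ncol = 2, byrow = TRUE)

# allele pairs, positions spaced beyond any clumping window, Wald p-values
.assembleTable <- function(snp, chr, pos, ea, oa, eaf, beta, se, n,
                           traitId, traitType, nCase, nControl) {
  SummaryStats(data.frame(
    snp = snp, chr = chr, pos = pos, effect_allele = ea, other_allele = oa,
    eaf = eaf, beta = beta, se = se,
    pval = pmax(twoSidedNormalP(beta / se), .Machine$double.xmin),
    n = n,
    n_case = if (traitType == "binary") nCase else NA_real_,
    n_control = if (traitType == "binary") nControl else NA_real_,
    stringsAsFactors = FALSE
  ), traitId = traitId, traitType = traitType,
  nCase = if (traitType == "binary") nCase else NA_real_,
  nControl = if (traitType == "binary") nControl else NA_real_)
}

#' Simulate a two-sample exposure/outcome GWAS pair with known truth
#'
#' Per SNP j: `eaf_j ~ U(eafRange)`; the true exposure effect is
#' `b_j = |N(0, scale^2)|`, coded on the exposure-increasing allele; the
#' exposure sampling SE is the standardized-trait closed form
#' `1 / sqrt(2 n_x eaf (1 - eaf))` and the observed effect
#' `bx_j ~ N(b_j, se_x^2)`. A pleiotropic fraction receives a direct outcome
#' effect `alpha_j ~ N(mu, sd^2)` (independent of `b_j` unless
#' `insideViolation` is set); the true outcome effect is
#' `theta b_j + alpha_j`, observed with SE `1 / sqrt(2 n_y eaf (1 - eaf))`.
#' Planted outliers add a fixed offset to the observed outcome effect.
#' A configured fraction of SNPs gets palindromic (A/T or C/G) allele pairs;
#' both studies report the same strand and frequency, so harmonization under
#' the default policy retains unambiguous ones. All draws are governed by
#' `config$seed`; output is byte-identical across runs.
#'
#' @param config a [simConfig()] list.
#' @return list with `exposure` and `outcome` ([SummaryStats-class]) and
#'   `truth` (list: `theta`, per-SNP `b`, `alpha`, `eaf`, `seX`, `seY`,
#'   `outlierIds`, `palindromicIds`).
#' @export
simulatePair <- function(config = simConfig()) {
  stopifnot(inherits(config, "SimulationConfig"))
  J <- config$nSnp
  withSeed(config$seed, {
    eaf <- runif(J, config$eafRange[1], config$eafRange[2])
    b <- abs(rnorm(J, 0, config$exposureEffectScale))
    seX <- 1 / sqrt(2 * config$nExposure * eaf * (1 - eaf))
    bx <- rnorm(J, b, seX)
    affected <- runif(J) < config$pleiotropy$fraction
    alpha <- ifelse(affected,
                    rnorm(J, config$pleiotropy$mu, config$pleiotropy$sd), 0)
    if (config$insideViolation != 0)
      alpha <- alpha + affected * config$insideViolation * (b - mean(b))
    byTrue <- config$theta * b + alpha
    seY <- 1 / sqrt(2 * config$nOutcome * eaf * (1 - eaf))
    by <- rnorm(J, byTrue, seY)
    outIdx <- integer()
    if (config$outliers$n > 0) {
      outIdx <- sample.int(J, config$outliers$n)
      off <- config$outliers$offset
      if (isTRUE(config$outliers$relative)) off <- off * median(abs(by))
      by[outIdx] <- by[outIdx] + off
    }
    nPal <- round(config$palindromicFraction * J)
    palIdx <- if (nPal > 0) sample.int(J, nPal) else integer()
    ea <- oa <- character(J)
    pick <- sample.int(nrow(.NONPAL_PAIRS), J, replace = TRUE)
    ea <- .NONPAL_PAIRS[pick, 1]; oa <- .NONPAL_PAIRS[pick, 2]
    if (length(palIdx)) {
      palPick <- sample(c("AT", "TA", "CG", "GC"), length(palIdx),
                        replace = TRUE)
      ea[palIdx] <- substr(palPick, 1, 1)
      oa[palIdx] <- substr(palPick, 2, 2)
    }
    snp <- sprintf("rs%07d", seq_len(J))
    chr <- as.character(rep_len(1:22, J))
    pos <- 1e6 + (seq_len(J) - 1) * 2e7   # beyond the 10,000 kb window
    exposure <- .assembleTable(snp, chr, pos, ea, oa, eaf, bx, seX,
                               config$nExposure, "sim_exposure",
                               "quantitative", NA_real_, NA_real_)
    outType <- if (config$binaryOutcome) "binary" else "quantitative"
    outcome <- .assembleTable(snp, chr, pos, ea, oa, eaf, by, seY,
                              config$nOutcome, "sim_outcome", outType,
                              config$nCase, config$nControl)
    truth <- list(theta = config$theta, b = b, alpha = alpha, eaf = eaf,
                  seX = seX, seY = seY,
                  outlierIds = snp[outIdx], palindromicIds = snp[palIdx])
    list(exposure = exposure, outcome = outcome, truth = truth)
  })
}

#' Simulate an exposure-mediator-outcome chain with known truth
#'
#' Generates three summary tables over the union of two disjoint instrument
#' sets (one per heritable trait). The exposure's instruments carry
#' half-normal effects `b`; the mediator receives the flow-through
#' `beta1 * b` at those SNPs plus its own instruments' direct effects `m`;
#' the outcome receives `direct * b + beta2 * (mediator effect)` at every
#' SNP, i.e. a total exposure effect of `direct + beta1 * beta2` at exposure
#' instruments and `beta2 * m` at mediator instruments. Sampling noise as in
#' [simulatePair()].
#'
#' @param config a [simConfig()] list; `nSnp` is the instrument count *per
#'   trait*.
#' @param chain list `(beta1, beta2, direct)`: exposure-to-mediator,
#'   mediator-to-outcome and direct exposure-to-outcome effects.
#' @param nMediator mediator GWAS sample size (defaults to `nExposure`).
#' @return list with `exposure`, `mediator`, `outcome`
#'   ([SummaryStats-class]) and `truth` (chain coefficients, per-SNP truths,
#'   instrument id sets, and the implied `total = direct + beta1 * beta2`).
#' @export
simulateMediationChain <- function(config = simConfig(), chain,
                                   nMediator = NULL) {
  stopifnot(inherits(config, "SimulationConfig"))
  if (missing(chain) || !all(c("beta1", "beta2", "direct") %in% names(chain)))
    stop("chain must supply beta1, beta2 and direct")
  J <- config$nSnp
  nMed <- nMediator %||% config$nExposure
  withSeed(config$seed, {
    n2 <- 2L * J
    eaf <- runif(n2, config$eafRange[1], config$eafRange[2])
    isX <- seq_len(n2) <= J          # exposure instruments first, mediator second
    b <- ifelse(isX, abs(rnorm(n2, 0, config$exposureEffectScale)), 0)
    m <- ifelse(!isX, abs(rnorm(n2, 0, config$exposureEffectScale)), 0)
    medTrue <- chain$beta1 * b + m
    outTrue <- chain$direct * b + chain$beta2 * medTrue
    seX <- 1 / sqrt(2 * config$nExposure * eaf * (1 - eaf))
    seM <- 1 / sqrt(2 * nMed * eaf * (1 - eaf))
    seY <- 1 / sqrt(2 * config$nOutcome * eaf * (1 - eaf))
    bx <- rnorm(n2, b, seX)
    bm <- rnorm(n2, medTrue, seM)
    by <- rnorm(n2, outTrue, seY)
    pick <- sample.int(nrow(.NONPAL_PAIRS), n2, replace = TRUE)
    ea <- .NONPAL_PAIRS[pick, 1]; oa <- .NONPAL_PAIRS[pick, 2]
    snp <- sprintf("rs%07d", seq_len(n2))
    chr <- as.character(rep_len(1:22, n2))
    pos <- 1e6 + (seq_len(n2) - 1) * 2e7
    outType <- if (config$binaryOutcome) "binary" else "quantitative"
    list(
      exposure = .assembleTable(snp, chr, pos, ea, oa, eaf, bx, seX,
                                config$nExposure, "sim_exposure",
                                "quantitative", NA_real_, NA_real_),
      mediator = .assembleTable(snp, chr, pos, ea, oa, eaf, bm, seM,
                                nMed, "sim_mediator", "quantitative",
                                NA_real_, NA_real_),
      outcome = .assembleTable(snp, chr, pos, ea, oa, eaf, by, seY,
                               config$nOutcome, "sim_outcome", outType,
                               config$nCase, config$nControl),
      truth = list(beta1 = chain$beta1, beta2 = chain$beta2,
                   direct = chain$direct,
                   total = chain$direct + chain$beta1 * chain$beta2,
                   b = b, m = m, exposureSnps = snp[isX],
                   mediatorSnps = snp[!isX])
    )
  })
}
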
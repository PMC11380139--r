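#' Product-of-coefficients mediation decomposition
#'
#' Combines three causal-leg estimates — exposure-to-mediator (`beta1`),
#' mediator-to-outcome (`beta2`) and total exposure-to-outcome (`beta3`) —
#' into the mediated effect `beta1 * beta2`, the direct effect
#' `beta3 - beta1 * beta2` and the proportion mediated
#' `beta1 * beta2 / beta3`. Additivity is exact on the log scale, so on the
#' odds-ratio scale `exp(direct) * exp(mediated) = exp(total)` to machine
#' precision. The mediated-effect variance uses the delta method,
#' `beta2^2 se1^2 + beta1^2 se2^2`; the proportion's delta-method SE is
#' reported but the proportion is flagged undefined when `|beta3|` is below
#' `tol` or the mediated and total effects have opposite signs.
#'
#' @param beta1,se1 exposure-to-mediator estimate and SE.
#' @param beta2,se2 mediator-to-outcome estimate and SE.
#' @param beta3,se3 total exposure-to-outcome estimate and SE.
#' @param exposureId,mediatorId,outcomeId trait identifiers.
#' @param level confidence level.
#' @param tol threshold on `|beta3|` below which the proportion is flagged
#'   undefined (default 1e-8).
#' @return A [MediationResult-class] object.
#' @export
decomposeMediation <- function(beta1, se1, beta2, se2, beta3, se3,
                               exposureId = "exposure",
                               mediatorId = "mediator",
                               outcomeId = "outcome",
                               level = 0.95, tol = 1e-8) {
  stopifnot(se1 > 0, se2 > 0, se3 > 0)
  mediated <- beta1 * beta2
  direct <- beta3 - mediated
  seMed <- sqrt(beta2^2 * se1^2 + beta1^2 * se2^2)
  defined <- abs(beta3) >= tol && (mediated == 0 || sign(mediated) == sign(beta3))
  prop <- if (abs(beta3) >= tol) mediated / beta3 else NA_real_
  seProp <- if (abs(beta3) >= tol) {
    sqrt((beta2 / beta3)^2 * se1^2 + (beta1 / beta3)^2 * se2^2 +
           (mediated / beta3^2)^2 * se3^2)
  } else NA_real_
  pMed <- if (seMed > 0) twoSidedNormalP(mediated / seMed) else 1
  new("MediationResult",
      exposureId = exposureId, mediatorId = mediatorId, outcomeId = outcomeId,
      beta1 = beta1, se1 = se1, beta2 = beta2, se2 = se2,
      beta3 = beta3, se3 = se3,
      mediatedBeta = mediated, mediatedSE = seMed, directBeta = direct,
      proportion = prop, proportionSE = seProp, proportionDefined = defined,
      pvalMediated = pMed, level = level)
}

#' Two-step mediation analysis on summary statistics
#'
#' Estimates the three causal legs by the pipeline's primary method (IVW with
#' the automatic fixed/random switch; Wald ratio for a single instrument):
#' `beta1` from MR of exposure on mediator using the exposure's instruments,
#' `beta2` from MR of mediator on outcome using the mediator's instruments,
#' `beta3` from MR of exposure on outcome using the exposure's instruments —
#' then applies [decomposeMediation()] to the leg estimates. The
#' decomposition is computed exactly once, from these legs.
#'
#' Instruments selected for the exposure are excluded from the
#' mediator-to-outcome leg: a variant instrumenting both traits reaches the
#' outcome through the exposure's direct path as well, violating that leg's
#' exclusion restriction and biasing `beta2` (the same spirit as excluding
#' confounder-associated instruments during selection).
#'
#' @param exposure,mediator,outcome [SummaryStats-class] tables.
#' @param config a [pipelineConfig()] list controlling instrument selection
#'   and harmonization.
#' @return A [MediationResult-class] object; the three leg
#'   [MRResult-class]s are attached as attribute `"legs"`.
#' @export
twoStepMediation <- function(exposure, mediator, outcome,
                             config = pipelineConfig()) {
  leg <- function(from, to, label, dropSnps = character()) {
    if (length(dropSnps)) {
      cfgLeg <- config
      cfgLeg$exclude <- union(config$exclude, dropSnps)
    } else cfgLeg <- config
    sel <- tryCatch(.selectWithFallback(from, cfgLeg), error = function(e)
      stop(label, " leg: ", conditionMessage(e), call. = FALSE))
    inst <- subsetSnps(from, instrumentRecords(sel$instruments)$snp)
    h <- tryCatch(harmonize(inst, to,
                            palindromePolicy = config$palindrome_policy),
                  error = function(e)
                    stop(label, " leg: ", conditionMessage(e), call. = FALSE))
    if (!nSnp(h)) stop(label, " leg: no harmonized instruments", call. = FALSE)
    if (nSnp(h) == 1L) {
      d <- harmonizedData(h)
      waldRatio(d$beta_exposure, d$beta_outcome, d$se_exposure, d$se_outcome)
    } else mrIVW(h, mode = "auto")
  }
  sel1 <- tryCatch(.selectWithFallback(exposure, config), error = function(e)
    stop("exposure->mediator leg: ", conditionMessage(e), call. = FALSE))
  exposureSnps <- instrumentRecords(sel1$instruments)$snp
  l1 <- leg(exposure, mediator, "exposure->mediator")
  l2 <- leg(mediator, outcome, "mediator->outcome", dropSnps = exposureSnps)
  l3 <- leg(exposure, outcome, "exposure->outcome")
  out <- decomposeMediation(mrBeta(l1), mrSE(l1), mrBeta(l2), mrSE(l2),
                            mrBeta(l3), mrSE(l3),
                            exposureId = traitId(exposure),
                            mediatorId = traitId(mediator),
                            outcomeId = traitId(outcome))
  attr(out, "legs") <- list(exposure_mediator = l1, mediator_outcome = l2,
                            exposure_outcome = l3)
  out
}

#' Mediation summary table
#'
#' One row mirroring the usual reporting layout: total, direct and mediated
#' effects as odds ratios with confidence intervals, plus the mediated-effect
#' p-value and the proportion mediated.
#'
#' @param x a [MediationResult-class] object.
#' @return A one-row data.frame.
#' @export
mediationTable <- function(x) {
  stopifnot(is(x, "MediationResult"))
  z <- qnorm(1 - (1 - x@level) / 2)
  seDirect <- sqrt(x@se3^2 + x@mediatedSE^2)  # conservative delta combination
  fmt <- function(b, s)
    c(or = exp(b), ci_low = exp(b - z * s), ci_high = exp(b + z * s))
  tot <- fmt(x@beta3, x@se3)
  dir <- fmt(x@directBeta, seDirect)
  med <- fmt(x@mediatedBeta, x@mediatedSE)
  data.frame(outcome = x@outcomeId, mediator = x@mediatorId,
             exposure = x@exposureId,
             total_or = tot["or"], total_ci_low = tot["ci_low"],
             total_ci_high = tot["ci_high"],
             direct_or = dir["or"], direct_ci_low = dir["ci_low"],
             direct_ci_high = dir["ci_high"],
             mediation_or = med["or"], mediation_ci_low = med["ci_low"],
             mediation_ci_high = med["ci_high"],
             pval = x@pvalMediated,
             proportion = if (x@proportionDefined) x@proportion else NA_real_,
             row.names = NULL, stringsAsFactors = FALSE)
}
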
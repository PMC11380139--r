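#' SummaryStats: a validated GWAS summary-statistic table
#'
#' Container for one trait's per-variant summary associations. Each record
#' carries the variant identifier, alleles, effect-allele frequency, the
#' per-allele effect (a log odds ratio for binary traits), its standard error,
#' p-value and sample size. Rows failing the record invariants at construction
#' are moved to the `rejected` slot with a per-row reason rather than
#' invalidating the object.
#'
#' Record invariants: `se > 0`; `pval` in (0, 1]; `eaf`, when present, strictly
#' inside (0, 1); `effect_allele != other_allele` (case-insensitive); non-empty
#' unique `snp`. For binary traits with `nCase`/`nControl` set, any record `n`
#' present must equal `nCase + nControl`.
#'
#' @slot traitId character(1), trait identifier.
#' @slot traitType `"quantitative"` or `"binary"`.
#' @slot nCase,nControl case/control counts for binary traits (`NA` otherwise).
#' @slot variants data.frame of validated records in canonical columns
#'   (`snp, chr, pos, effect_allele, other_allele, eaf, beta, se, pval, n,
#'   n_case, n_control`).
#' @slot rejected data.frame of rejected rows with a `reason` column.
#' @exportClass SummaryStats
setClass("SummaryStats",
  representation(
    traitId   = "character",
    traitType = "character",
    nCase     = "numeric",
    nControl  = "numeric",
    variants  = "data.frame",
    rejected  = "data.frame"
  ),
  prototype(
    traitId = "trait", traitType = "quantitative",
    nCase = NA_real_, nControl = NA_real_,
    variants = data.frame(), rejected = data.frame()
  )
)

setValidity("SummaryStats", function(object) {
  v <- object@variants
  msgs <- character()
  if (length(object@traitId) != 1L || !nzchar(object@traitId))
    msgs <- c(msgs, "traitId must be a single non-empty string")
  if (!object@traitType %in% c("quantitative", "binary"))
    msgs <- c(msgs, "traitType must be 'quantitative' or 'binary'")
  miss <- setdiff(.CANONICAL_COLS, names(v))
  if (length(miss))
    msgs <- c(msgs, paste0("variants lacks canonical columns: ",
                           paste(miss, collapse = ", ")))
  if (nrow(v) && !length(miss)) {
    if (anyDuplicated(v$snp)) msgs <- c(msgs, "duplicate snp ids")
    if (any(!nzchar(v$snp) | is.na(v$snp))) msgs <- c(msgs, "empty snp id")
    if (any(!is.finite(v$se) | v$se <= 0)) msgs <- c(msgs, "se must be > 0")
    if (any(!is.finite(v$pval) | v$pval <= 0 | v$pval > 1))
      msgs <- c(msgs, "pval must lie in (0, 1]")
    ea <- !is.na(v$eaf)
    if (any(v$eaf[ea] <= 0 | v$eaf[ea] >= 1))
      msgs <- c(msgs, "eaf must lie strictly in (0, 1)")
    if (any(toupper(v$effect_allele) == toupper(v$other_allele)))
      msgs <- c(msgs, "effect_allele must differ from other_allele")
    if (object@traitType == "binary" &&
        is.finite(object@nCase) && is.finite(object@nControl)) {
      nn <- !is.na(v$n)
      if (any(v$n[nn] != object@nCase + object@nControl))
        msgs <- c(msgs, "record n must equal nCase + nControl for binary traits")
    }
  }
  if (length(msgs)) msgs else TRUE
})

#' HarmonizedSet: exposure/outcome effects on a shared effect allele
#'
#' The unit all univariable estimators consume: per-SNP exposure and outcome
#' effects aligned so both refer to the same effect allele, with per-row
#' harmonization flags (`flipped`, `palindromic`) and an audit of rows dropped
#' during harmonization (`dropped`, with a `reason` per row).
#'
#' @slot exposureId,outcomeId trait identifiers.
#' @slot data data.frame with columns `snp, effect_allele, other_allele,
#'   beta_exposure, se_exposure, beta_outcome, se_outcome, eaf, flipped,
#'   palindromic`.
#' @slot dropped data.frame with columns `snp, reason`.
#' @exportClass HarmonizedSet
setClass("HarmonizedSet",
  representation(
    exposureId = "character",
    outcomeId  = "character",
    data       = "data.frame",
    dropped    = "data.frame"
  ),
  prototype(exposureId = "exposure", outcomeId = "outcome",
            data = data.frame(), dropped = data.frame(snp = character(),
                                                      reason = character()))
)

setValidity("HarmonizedSet", function(object) {
  d <- object@data
  msgs <- character()
  need <- c("snp", "effect_allele", "other_allele", "beta_exposure",
            "se_exposure", "beta_outcome", "se_outcome", "eaf",
            "flipped", "palindromic")
  miss <- setdiff(need, names(d))
  if (length(miss))
    return(paste0("data lacks columns: ", paste(miss, collapse = ", ")))
  if (nrow(d)) {
    if (anyDuplicated(d$snp)) msgs <- c(msgs, "duplicate snp ids")
    num <- c("beta_exposure", "se_exposure", "beta_outcome", "se_outcome")
    if (any(vapply(d[num], function(x) any(!is.finite(x)), logical(1))))
      msgs <- c(msgs, "betas and ses must be finite and non-missing")
    else if (any(d$se_exposure <= 0) || any(d$se_outcome <= 0))
      msgs <- c(msgs, "standard errors must be > 0")
  }
  if (length(msgs)) msgs else TRUE
})

#' MRResult: one causal estimate
#'
#' Result of a single Mendelian randomization estimator: the causal effect on
#' the log odds-ratio (or per-unit) scale with its standard error, p-value and
#' odds-ratio-scale confidence interval, plus method-specific extras (for
#' MR-Egger: the intercept triple; for IVW: Cochran's Q and the fixed/random
#' decision; for bootstrap methods: replication count and seed).
#'
#' @slot method estimator name (`wald_ratio`, `ivw_fixed`, `ivw_random`,
#'   `ivw_auto`, `egger`, `weighted_median`, `weighted_mode`, `mvmr_ivw`).
#' @slot nSnp number of instruments used.
#' @slot beta,se,pval estimate, standard error, two-sided p-value.
#' @slot or,ciLow,ciHigh `exp(beta)` and the level-`level` CI bounds.
#' @slot level confidence level.
#' @slot extras named list of method-specific quantities.
#' @exportClass MRResult
setClass("MRResult",
  representation(
    method = "character", nSnp = "integer",
    beta = "numeric", se = "numeric", pval = "numeric",
    or = "numeric", ciLow = "numeric", ciHigh = "numeric",
    level = "numeric", extras = "list"
  )
)

setValidity("MRResult", function(object) {
  msgs <- character()
  if (object@nSnp < 1L) msgs <- c(msgs, "nSnp must be >= 1")
  if (!is.finite(object@se) || object@se <= 0)
    msgs <- c(msgs, "se must be > 0")
  if (object@pval <= 0 || object@pval > 1)
    msgs <- c(msgs, "pval must lie in (0, 1]")
  if (abs(object@or - exp(object@beta)) > 1e-12 * max(1, object@or))
    msgs <- c(msgs, "or must equal exp(beta)")
  if (!(object@ciLow < object@or && object@or < object@ciHigh))
    msgs <- c(msgs, "ciLow < or < ciHigh violated")
  if (length(msgs)) msgs else TRUE
})

#' HeterogeneityResult: Cochran's Q statistic
#'
#' @slot Q non-negative heterogeneity statistic.
#' @slot df degrees of freedom (J - 1 for IVW, J - 2 for Egger, J - K for
#'   multivariable fits).
#' @slot pval upper chi-square tail probability.
#' @exportClass HeterogeneityResult
setClass("HeterogeneityResult",
  representation(Q = "numeric", df = "integer", pval = "numeric")
)

setValidity("HeterogeneityResult", function(object) {
  msgs <- character()
  if (!is.finite(object@Q) || object@Q < 0) msgs <- c(msgs, "Q must be >= 0")
  if (object@pval <= 0 || object@pval > 1)
    msgs <- c(msgs, "pval must lie in (0, 1]")
  if (length(msgs)) msgs else TRUE
})

setClassUnion("MRResultOrNULL", c("MRResult", "NULL"))

#' PressoReport: simulation-based pleiotropy residual-sum-of-squares test
#'
#' Holds the global observed residual sum of squares and its Monte-Carlo
#' p-value, per-SNP outlier p-values (Bonferroni-adjusted for flagging), the
#' flagged outlier ids, the raw and outlier-corrected IVW estimates, and the
#' distortion p-value for the raw-versus-corrected difference. The Monte-Carlo
#' p-values use the add-one estimator, so their resolution is 1/(nSim + 1) and
#' they are never exactly zero.
#'
#' @slot observedRSS weighted observed residual sum of squares.
#' @slot globalPval Monte-Carlo global test p-value.
#' @slot nSim number of simulated datasets.
#' @slot perSnpPvals named numeric, unadjusted per-SNP Monte-Carlo p-values.
#' @slot outliers character, SNPs flagged at the Bonferroni-adjusted threshold.
#' @slot rawEstimate,correctedEstimate IVW estimates before/after outlier
#'   removal; `correctedEstimate` is `NULL` when no outlier is flagged.
#' @slot distortionPval p-value of the distortion test (`NA` when no outlier).
#' @exportClass PressoReport
setClass("PressoReport",
  representation(
    observedRSS = "numeric", globalPval = "numeric", nSim = "integer",
    perSnpPvals = "numeric", outliers = "character",
    rawEstimate = "MRResult", correctedEstimate = "MRResultOrNULL",
    distortionPval = "numeric"
  )
)

setValidity("PressoReport", function(object) {
  msgs <- character()
  if (object@globalPval < 1 / (object@nSim + 1) - 1e-12)
    msgs <- c(msgs, "globalPval below Monte-Carlo resolution 1/(nSim + 1)")
  if (!all(object@outliers %in% names(object@perSnpPvals)))
    msgs <- c(msgs, "outliers must be a subset of tested SNPs")
  hasOut <- length(object@outliers) > 0L
  if (hasOut && is.null(object@correctedEstimate))
    msgs <- c(msgs, "correctedEstimate required when outliers are flagged")
  if (!hasOut && !is.null(object@correctedEstimate))
    msgs <- c(msgs, "correctedEstimate must be NULL when no outlier is flagged")
  if (length(msgs)) msgs else TRUE
})

#' MVHarmonizedSet: jointly harmonized multi-exposure effects
#'
#' Per-SNP effects of K >= 1 exposures and one outcome, all aligned to a
#' common effect allele, complete-case (no missing betas in retained rows).
#'
#' @slot outcomeId outcome trait identifier.
#' @slot exposureIds ordered exposure identifiers (columns of the matrices).
#' @slot snp variant identifiers (rows).
#' @slot betaExposure,seExposure J x K matrices of exposure effects/SEs.
#' @slot betaOutcome,seOutcome length-J outcome effect and SE vectors.
#' @exportClass MVHarmonizedSet
setClass("MVHarmonizedSet",
  representation(
    outcomeId = "character", exposureIds = "character", snp = "character",
    betaExposure = "matrix", seExposure = "matrix",
    betaOutcome = "numeric", seOutcome = "numeric"
  )
)

setValidity("MVHarmonizedSet", function(object) {
  J <- length(object@snp); K <- length(object@exposureIds)
  msgs <- character()
  if (!all(dim(object@betaExposure) == c(J, K)) ||
      !all(dim(object@seExposure) == c(J, K)))
    msgs <- c(msgs, "exposure matrices must be J x K")
  if (length(object@betaOutcome) != J || length(object@seOutcome) != J)
    msgs <- c(msgs, "outcome vectors must have length J")
  if (anyDuplicated(object@snp)) msgs <- c(msgs, "duplicate snp ids")
  if (any(!is.finite(object@betaExposure)) || any(!is.finite(object@betaOutcome)))
    msgs <- c(msgs, "missing exposure or outcome betas in retained rows")
  if (J <= K + 1L)
    msgs <- c(msgs, sprintf("need more SNPs than exposures + 1 (J = %d, K = %d)", J, K))
  if (length(msgs)) msgs else TRUE
})

#' MediationResult: two-step mediation decomposition
#'
#' Product-of-coefficients decomposition of a total causal effect: with beta1
#' the exposure-to-mediator effect, beta2 the mediator-to-outcome effect and
#' beta3 the total exposure-to-outcome effect, the mediated effect is
#' beta1 x beta2, the direct effect beta3 - beta1 x beta2, and the proportion
#' mediated beta1 x beta2 / beta3. Additivity (direct + mediated = total) is
#' exact on the log scale by construction.
#'
#' @slot exposureId,mediatorId,outcomeId trait identifiers.
#' @slot beta1,se1,beta2,se2,beta3,se3 leg estimates and standard errors.
#' @slot mediatedBeta,mediatedSE product estimate and its delta-method SE.
#' @slot directBeta beta3 - beta1 * beta2.
#' @slot proportion,proportionSE proportion mediated and its delta-method SE.
#' @slot proportionDefined FALSE when |beta3| is below tolerance or the
#'   mediated and total effects have opposite signs (proportion then
#'   uninterpretable).
#' @slot pvalMediated normal two-sided p for the mediated effect.
#' @slot level confidence level for the interval accessors.
#' @exportClass MediationResult
setClass("MediationResult",
  representation(
    exposureId = "character", mediatorId = "character", outcomeId = "character",
    beta1 = "numeric", se1 = "numeric",
    beta2 = "numeric", se2 = "numeric",
    beta3 = "numeric", se3 = "numeric",
    mediatedBeta = "numeric", mediatedSE = "numeric",
    directBeta = "numeric",
    proportion = "numeric", proportionSE = "numeric",
    proportionDefined = "logical",
    pvalMediated = "numeric", level = "numeric"
  )
)

setValidity("MediationResult", function(object) {
  msgs <- character()
  if (abs(object@mediatedBeta + object@directBeta - object@beta3) > 1e-12 *
      max(1, abs(object@beta3)))
    msgs <- c(msgs, "mediated + direct must equal total exactly")
  if (any(c(object@se1, object@se2, object@se3) <= 0))
    msgs <- c(msgs, "leg standard errors must be > 0")
  if (length(msgs)) msgs else TRUE
})

#' InstrumentSet: selected instruments with strength diagnostics
#'
#' The product of the instrument-selection pipeline: retained variant records
#' with their per-SNP F statistics, the group F statistic (when effect-allele
#' frequencies and a sample size are available), and an ordered audit log of
#' every filter applied with before/after counts.
#'
#' @slot traitId exposure trait identifier.
#' @slot records data.frame of retained variants (canonical columns plus `F`).
#' @slot groupF group F statistic (`NA` when not computable).
#' @slot selectionLog data.frame with columns `step, n_before, n_after, note`.
#' @exportClass InstrumentSet
setClass("InstrumentSet",
  representation(
    traitId = "character", records = "data.frame",
    groupF = "numeric", selectionLog = "data.frame"
  )
)

setValidity("InstrumentSet", function(object) {
  msgs <- character()
  if (nrow(object@records)) {
    if (anyDuplicated(object@records$snp)) msgs <- c(msgs, "duplicate snp ids")
    if (!"F" %in% names(object@records)) msgs <- c(msgs, "records lacks F column")
  }
  if (length(msgs)) msgs else TRUE
})

#' StudyReport: orchestrated study results
#'
#' Aggregated output of a forward or reverse pipeline run: the per-pair,
#' per-method estimate table with Bonferroni significance labels; the
#' sensitivity table (Egger intercept triple, global outlier-test p,
#' Cochran's Q and its p); leave-one-out rows; and the detailed per-pair
#' objects. Optional multivariable and mediation tables are attached by their
#' respective drivers.
#'
#' @slot results per-pair per-method estimates with significance labels.
#' @slot sensitivity per-pair sensitivity diagnostics.
#' @slot loo leave-one-out rows for every pair.
#' @slot mvmr multivariable-adjusted estimates (may be empty).
#' @slot mediation mediation decompositions (may be empty).
#' @slot pairs named list of detailed per-pair result lists.
#' @slot config the PipelineConfig used.
#' @slot direction `"forward"` or `"reverse"`.
#' @exportClass StudyReport
setClass("StudyReport",
  representation(
    results = "data.frame", sensitivity = "data.frame", loo = "data.frame",
    mvmr = "data.frame", mediation = "data.frame",
    pairs = "list", config = "list", direction = "character"
  ),
  prototype(mvmr = data.frame(), mediation = data.frame(),
            direction = "forward")
)
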
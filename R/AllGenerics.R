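#' Accessors for mrpipe S4 objects
#'
#' Small accessor family: `traitId()`, `traitType()`, `variants()`,
#' `rejectedVariants()` for [SummaryStats-class]; `harmonizedData()`,
#' `droppedVariants()`, `exposureId()`, `outcomeId()` for
#' [HarmonizedSet-class]; `nSnp()` for anything carrying instruments;
#' `mrMethod()`, `mrBeta()`, `mrSE()`, `mrPval()`, `oddsRatio()`, `confInt()`,
#' `mrExtras()` for [MRResult-class]; `instrumentRecords()`, `groupFStat()`,
#' `selectionLog()` for [InstrumentSet-class]; `globalPval()`, `outlierSnps()`,
#' `rawEstimate()`, `correctedEstimate()`, `distortionPval()`, `perSnpPvals()`
#' for [PressoReport-class].
#'
#' @param x an mrpipe S4 object.
#' @return The corresponding slot value; `confInt()` returns a named numeric
#'   of length 2 on the odds-ratio scale.
#' @name accessors
#' @aliases traitId traitType variants rejectedVariants harmonizedData
#'   droppedVariants exposureId outcomeId nSnp mrMethod mrBeta mrSE mrPval
#'   oddsRatio confInt mrExtras instrumentRecords groupFStat selectionLog
#'   globalPval outlierSnps rawEstimate correctedEstimate distortionPval
#'   perSnpPvals
NULL

#' @rdname accessors
#' @export
setGeneric("traitId", function(x) standardGeneric("traitId"))
#' @rdname accessors
#' @export
setGeneric("traitType", function(x) standardGeneric("traitType"))
#' @rdname accessors
#' @export
setGeneric("variants", function(x) standardGeneric("variants"))
#' @rdname accessors
#' @export
setGeneric("rejectedVariants", function(x) standardGeneric("rejectedVariants"))
#' @rdname accessors
#' @export
setGeneric("harmonizedData", function(x) standardGeneric("harmonizedData"))
#' @rdname accessors
#' @export
setGeneric("droppedVariants", function(x) standardGeneric("droppedVariants"))
#' @rdname accessors
#' @export
setGeneric("exposureId", function(x) standardGeneric("exposureId"))
#' @rdname accessors
#' @export
setGeneric("outcomeId", function(x) standardGeneric("outcomeId"))
#' @rdname accessors
#' @export
setGeneric("nSnp", function(x) standardGeneric("nSnp"))
#' @rdname accessors
#' @export
setGeneric("mrMethod", function(x) standardGeneric("mrMethod"))
#' @rdname accessors
#' @export
setGeneric("mrBeta", function(x) standardGeneric("mrBeta"))
#' @rdname accessors
#' @export
setGeneric("mrSE", function(x) standardGeneric("mrSE"))
#' @rdname accessors
#' @export
setGeneric("mrPval", function(x) standardGeneric("mrPval"))
#' @rdname accessors
#' @export
setGeneric("oddsRatio", function(x) standardGeneric("oddsRatio"))
#' @rdname accessors
#' @export
setGeneric("confInt", function(x) standardGeneric("confInt"))
#' @rdname accessors
#' @export
setGeneric("mrExtras", function(x) standardGeneric("mrExtras"))
#' @rdname accessors
#' @export
setGeneric("instrumentRecords", function(x) standardGeneric("instrumentRecords"))
#' @rdname accessors
#' @export
setGeneric("groupFStat", function(x) standardGeneric("groupFStat"))
#' @rdname accessors
#' @export
setGeneric("selectionLog", function(x) standardGeneric("selectionLog"))
#' @rdname accessors
#' @export
setGeneric("globalPval", function(x) standardGeneric("globalPval"))
#' @rdname accessors
#' @export
setGeneric("outlierSnps", function(x) standardGeneric("outlierSnps"))
#' @rdname accessors
#' @export
setGeneric("rawEstimate", function(x) standardGeneric("rawEstimate"))
#' @rdname accessors
#' @export
setGeneric("correctedEstimate", function(x) standardGeneric("correctedEstimate"))
#' @rdname accessors
#' @export
setGeneric("distortionPval", function(x) standardGeneric("distortionPval"))
#' @rdname accessors
#' @export
setGeneric("perSnpPvals", function(x) standardGeneric("perSnpPvals"))

setMethod("traitId", "SummaryStats", function(x) x@traitId)
setMethod("traitType", "SummaryStats", function(x) x@traitType)
setMethod("variants", "SummaryStats", function(x) x@variants)
setMethod("rejectedVariants", "SummaryStats", function(x) x@rejected)
setMethod("nSnp", "SummaryStats", function(x) nrow(x@variants))

setMethod("harmonizedData", "HarmonizedSet", function(x) x@data)
setMethod("droppedVariants", "HarmonizedSet", function(x) x@dropped)
setMethod("exposureId", "HarmonizedSet", function(x) x@exposureId)
setMethod("outcomeId", "HarmonizedSet", function(x) x@outcomeId)
setMethod("nSnp", "HarmonizedSet", function(x) nrow(x@data))

setMethod("mrMethod", "MRResult", function(x) x@method)
setMethod("mrBeta", "MRResult", function(x) x@beta)
setMethod("mrSE", "MRResult", function(x) x@se)
setMethod("mrPval", "MRResult", function(x) x@pval)
setMethod("oddsRatio", "MRResult", function(x) x@or)
setMethod("confInt", "MRResult",
          function(x) c(ciLow = x@ciLow, ciHigh = x@ciHigh))
setMethod("mrExtras", "MRResult", function(x) x@extras)
setMethod("nSnp", "MRResult", function(x) x@nSnp)

setMethod("instrumentRecords", "InstrumentSet", function(x) x@records)
setMethod("groupFStat", "InstrumentSet", function(x) x@groupF)
setMethod("selectionLog", "InstrumentSet", function(x) x@selectionLog)
setMethod("nSnp", "InstrumentSet", function(x) nrow(x@records))
setMethod("traitId", "InstrumentSet", function(x) x@traitId)

setMethod("globalPval", "PressoReport", function(x) x@globalPval)
setMethod("outlierSnps", "PressoReport", function(x) x@outliers)
setMethod("rawEstimate", "PressoReport", function(x) x@rawEstimate)
setMethod("correctedEstimate", "PressoReport", function(x) x@correctedEstimate)
setMethod("distortionPval", "PressoReport", function(x) x@distortionPval)
setMethod("perSnpPvals", "PressoReport", function(x) x@perSnpPvals)
setMethod("nSnp", "MVHarmonizedSet", function(x) length(x@snp))

setMethod("show", "SummaryStats", function(object) {
  cat("SummaryStats '", object@traitId, "' (", object@traitType, ")\n",
      sep = "")
  if (object@traitType == "binary" && is.finite(object@nCase))
    cat("  cases/controls: ", object@nCase, "/", object@nControl, "\n", sep = "")
  cat("  variants: ", nrow(object@variants),
      "  rejected: ", nrow(object@rejected), "\n", sep = "")
})

setMethod("show", "HarmonizedSet", function(object) {
  d <- object@data
  cat("HarmonizedSet ", object@exposureId, " -> ", object@outcomeId, "\n",
      "  SNPs retained: ", nrow(d),
      " (flipped: ", sum(d$flipped), ", palindromic: ", sum(d$palindromic),
      ")  dropped: ", nrow(object@dropped), "\n", sep = "")
})

setMethod("show", "MRResult", function(object) {
  ci <- sprintf("%.3f-%.3f", object@ciLow, object@ciHigh)
  cat(sprintf("MRResult [%s]  nSNP = %d\n  beta = %.4f (se %.4f)  OR = %.3f (%g%% CI %s)  p = %.4g\n",
              object@method, object@nSnp, object@beta, object@se, object@or,
              100 * object@level, ci, object@pval))
})

setMethod("show", "HeterogeneityResult", function(object) {
  cat(sprintf("Cochran's Q = %.4f on %d df, p = %.4g\n",
              object@Q, object@df, object@pval))
})

setMethod("show", "PressoReport", function(object) {
  cat(sprintf("Pleiotropy RSS outlier test: observed RSS = %.4f, global p = %.4g (%d simulations)\n",
              object@observedRSS, object@globalPval, object@nSim))
  if (length(object@outliers)) {
    cat("  outliers: ", paste(object@outliers, collapse = ", "),
        sprintf("  distortion p = %.4g\n", object@distortionPval), sep = "")
  } else cat("  no outliers flagged\n")
})

setMethod("show", "InstrumentSet", function(object) {
  cat("InstrumentSet '", object@traitId, "': ", nrow(object@records),
      " instruments", sep = "")
  if (is.finite(object@groupF)) cat(sprintf(", group F = %.2f", object@groupF))
  cat("\n")
  if (nrow(object@records))
    cat(sprintf("  per-SNP F range: %.2f-%.2f\n",
                min(object@records$F), max(object@records$F)))
})

setMethod("show", "MediationResult", function(object) {
  cat("MediationResult ", object@exposureId, " -> ", object@mediatorId,
      " -> ", object@outcomeId, "\n", sep = "")
  cat(sprintf("  total = %.4f  direct = %.4f  mediated = %.4f (se %.4f, p = %.4g)\n",
              object@beta3, object@directBeta, object@mediatedBeta,
              object@mediatedSE, object@pvalMediated))
  if (object@proportionDefined)
    cat(sprintf("  proportion mediated = %.3f\n", object@proportion))
  else cat("  proportion mediated: undefined (total near zero or opposite signs)\n")
})

setMethod("show", "StudyReport", function(object) {
  cat("StudyReport (", object@direction, "): ", length(object@pairs),
      " exposure-outcome pairs, ", nrow(object@results), " estimates\n",
      sep = "")
  if (nrow(object@results)) {
    lab <- table(object@results$label[object@results$method == "ivw_auto"])
    cat("  IVW labels: ",
        paste(names(lab), as.integer(lab), sep = "=", collapse = ", "), "\n",
        sep = "")
  }
})
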
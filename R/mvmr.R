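#' Jointly harmonize several exposures and one outcome
#'
#' Aligns every table to the first exposure's effect alleles using the same
#' allele logic as [harmonize()] (including the palindrome policy), restricts
#' to the requested instrument union, and keeps complete cases only — SNPs
#' missing from any table, or dropped during any pairwise alignment, are
#' excluded.
#'
#' @param exposures named list of [SummaryStats-class] objects (K >= 1); the
#'   first is the orientation reference.
#' @param outcome a [SummaryStats-class] object.
#' @param snps character vector of instrument ids to use (typically the union
#'   of the per-exposure selections); `NULL` uses all shared SNPs.
#' @param palindromePolicy,eafWindow passed to the pairwise alignments.
#' @return An [MVHarmonizedSet-class] object.
#' @export
mvmrHarmonize <- function(exposures, outcome, snps = NULL,
                          palindromePolicy = "infer_by_eaf",
                          eafWindow = 0.08) {
  stopifnot(is.list(exposures), length(exposures) >= 1L,
            is(outcome, "SummaryStats"))
  ids <- names(exposures) %||% vapply(exposures, traitId, character(1))
  if (is.null(names(exposures))) names(exposures) <- ids
  ref <- exposures[[1]]
  if (!is.null(snps)) ref <- subsetSnps(ref, snps)
  refV <- variants(ref)

  aligned <- list()
  aligned[[ids[1]]] <- data.frame(snp = refV$snp, beta = refV$beta,
                                  se = refV$se, stringsAsFactors = FALSE)
  others <- c(exposures[-1], list(.outcome. = outcome))
  for (nm in names(others)) {
    h <- harmonize(ref, others[[nm]], palindromePolicy = palindromePolicy,
                   eafWindow = eafWindow)
    hd <- harmonizedData(h)
    aligned[[nm]] <- data.frame(snp = hd$snp, beta = hd$beta_outcome,
                                se = hd$se_outcome, stringsAsFactors = FALSE)
  }
  common <- Reduce(intersect, lapply(aligned, `[[`, "snp"))
  if (!length(common)) stop("no shared instruments across all tables")
  getCol <- function(nm, col)
    aligned[[nm]][match(common, aligned[[nm]]$snp), col]
  K <- length(ids)
  betaX <- vapply(ids, getCol, numeric(length(common)), col = "beta")
  seX <- vapply(ids, getCol, numeric(length(common)), col = "se")
  betaX <- matrix(betaX, ncol = K, dimnames = list(NULL, ids))
  seX <- matrix(seX, ncol = K, dimnames = list(NULL, ids))
  new("MVHarmonizedSet", outcomeId = traitId(outcome), exposureIds = ids,
      snp = common, betaExposure = betaX, seExposure = seX,
      betaOutcome = getCol(".outcome.", "beta"),
      seOutcome = getCol(".outcome.", "se"))
}

# WLS machinery shared by the multivariable fits; X may carry an intercept
# column. Returns coefficients, their floored-overdispersion SEs, residual
# weighted RSS and df.
.mvmrWLS <- function(X, y, w, df) {
  qrX <- qr(sqrt(w) * X)
  if (qrX$rank < ncol(X)) {
    cc <- suppressWarnings(stats::cor(X))
    diag(cc) <- 0
    idx <- which(abs(cc) == max(abs(cc), na.rm = TRUE), arr.ind = TRUE)[1, ]
    stop("collinear exposures: '", colnames(X)[idx[1]], "' and '",
         colnames(X)[idx[2]], "'")
  }
  XtWX <- crossprod(X, w * X)
  betah <- drop(solve(XtWX, crossprod(X, w * y)))
  res <- drop(y - X %*% betah)
  rssw <- sum(w * res^2)
  phi <- if (df > 0) max(1, rssw / df) else 1
  se <- sqrt(diag(solve(XtWX)) * phi)
  list(beta = betah, se = se, rssw = rssw, df = df, phi = phi)
}

#' Multivariable IVW estimator
#'
#' Weighted multiple regression of the outcome effects on the K exposure
#' effect columns without intercept, weights `1/se_outcome^2`: each
#' coefficient is that exposure's direct effect conditional on the others.
#' Standard errors carry the multiplicative overdispersion factor
#' `max(1, RSS_w / (J - K))`; p-values are Student-t with `J - K` df. With
#' K = 1 this reduces exactly to univariable fixed/random IVW.
#'
#' @param m an [MVHarmonizedSet-class] object.
#' @param level confidence level.
#' @return Named list of [MRResult-class] objects, one per exposure; each
#'   `extras` carries `adjusted_for` (the other exposures), `Q`, `Q_df`.
#' @export
mvmrIVW <- function(m, level = 0.95) {
  stopifnot(is(m, "MVHarmonizedSet"))
  X <- m@betaExposure
  ids <- m@exposureIds
  zero <- colSums(X != 0) == 0L
  if (any(zero)) {
    # an exposure with no genetic effect carries no information and would
    # make the design singular; drop it and estimate the rest
    warning("dropping exposure(s) with all-zero effects: ",
            paste(ids[zero], collapse = ", "))
    X <- X[, !zero, drop = FALSE]
    ids <- ids[!zero]
  }
  J <- nrow(X); K <- ncol(X)
  fit <- .mvmrWLS(X, m@betaOutcome, 1 / m@seOutcome^2, J - K)
  out <- lapply(seq_len(K), function(k) {
    .mrResult("mvmr_ivw", J, fit$beta[k], fit$se[k],
              pval = twoSidedTP(fit$beta[k] / fit$se[k], fit$df),
              level = level,
              extras = list(exposure = ids[k],
                            adjusted_for = ids[-k],
                            Q = fit$rssw, Q_df = fit$df,
                            overdispersion = fit$phi))
  })
  names(out) <- ids
  out
}

#' Multivariable Egger intercept test
#'
#' Re-fits the multivariable regression with an intercept after orienting
#' every row so the primary exposure's effect is non-negative (the whole row
#' — all exposure columns and the outcome — is flipped together); the
#' intercept's Student-t test (`J - K - 1` df) probes directional pleiotropy.
#'
#' @param m an [MVHarmonizedSet-class] with `J > K + 2` rows.
#' @param primary index or name of the orienting exposure (default first).
#' @return list with `intercept`, `se` and `pval`.
#' @export
mvmrEggerIntercept <- function(m, primary = 1L) {
  stopifnot(is(m, "MVHarmonizedSet"))
  X <- m@betaExposure
  J <- nrow(X); K <- ncol(X)
  if (J <= K + 2) stop("multivariable Egger needs J > K + 2 rows (J = ",
                       J, ", K = ", K, ")")
  if (is.character(primary)) primary <- match(primary, m@exposureIds)
  flip <- X[, primary] < 0
  Xo <- X * ifelse(flip, -1, 1)
  yo <- m@betaOutcome * ifelse(flip, -1, 1)
  Xi <- cbind(`(Intercept)` = 1, Xo)
  fit <- .mvmrWLS(Xi, yo, 1 / m@seOutcome^2, J - K - 1L)
  list(intercept = unname(fit$beta[1]), se = unname(fit$se[1]),
       pval = unname(twoSidedTP(fit$beta[1] / fit$se[1], fit$df)))
}

#' Cochran's Q for the multivariable fit
#'
#' The weighted residual sum of squares of the no-intercept multivariable
#' regression, referred to chi-square with `J - K` df.
#'
#' @param m an [MVHarmonizedSet-class] object.
#' @return A [HeterogeneityResult-class] object.
#' @export
mvmrQ <- function(m) {
  stopifnot(is(m, "MVHarmonizedSet"))
  X <- m@betaExposure
  J <- nrow(X); K <- ncol(X)
  fit <- .mvmrWLS(X, m@betaOutcome, 1 / m@seOutcome^2, J - K)
  new("HeterogeneityResult", Q = fit$rssw, df = as.integer(J - K),
      pval = max(pchisq(fit$rssw, J - K, lower.tail = FALSE),
                 .Machine$double.xmin))
}

#' Pairwise confounder-adjusted MVMR analysis
#'
#' For each confounder exposure, selects instruments for the primary exposure
#' and the confounder (union of the two selections), harmonizes all three
#' tables jointly and reports the primary exposure's adjusted estimate — one
#' adjusted result per confounder, the presentation used when screening a
#' primary exposure against confounders one at a time. `adjust = "all"`
#' fits the single joint model with every confounder at once instead.
#'
#' @param primary exposure [SummaryStats-class].
#' @param confounders named list of confounder [SummaryStats-class] objects.
#' @param outcome outcome [SummaryStats-class].
#' @param config a [pipelineConfig()] list (thresholds, clumping, F filter).
#' @param adjust `"pairwise"` (default) or `"all"`.
#' @return data.frame with one row per adjustment: `exposure, adjusted_for,
#'   n_snp, beta, se, or, ci_low, ci_high, pval, q, q_pval, egger_intercept_pval`.
#' @export
mvmrAnalysis <- function(primary, confounders, outcome,
                         config = pipelineConfig(),
                         adjust = c("pairwise", "all")) {
  adjust <- match.arg(adjust)
  stopifnot(is(primary, "SummaryStats"), is.list(confounders))
  if (is.null(names(confounders)))
    names(confounders) <- vapply(confounders, traitId, character(1))
  selectIds <- function(tb) {
    iset <- .selectWithFallback(tb, config)
    instrumentRecords(iset$instruments)$snp
  }
  primarySnps <- selectIds(primary)
  sets <- if (adjust == "pairwise") {
    lapply(names(confounders), function(nm) {
      snps <- union(primarySnps, selectIds(confounders[[nm]]))
      mvmrHarmonize(c(setNames(list(primary), traitId(primary)),
                      setNames(list(confounders[[nm]]), nm)),
                    outcome, snps = snps,
                    palindromePolicy = config$palindrome_policy)
    })
  } else {
    snps <- Reduce(union, lapply(confounders, selectIds), primarySnps)
    list(mvmrHarmonize(c(setNames(list(primary), traitId(primary)),
                         confounders), outcome, snps = snps,
                       palindromePolicy = config$palindrome_policy))
  }
  rows <- lapply(sets, function(m) {
    res <- mvmrIVW(m)[[1]]
    q <- mvmrQ(m)
    eg <- tryCatch(mvmrEggerIntercept(m), error = function(e) NULL)
    data.frame(exposure = traitId(primary),
               adjusted_for = paste(m@exposureIds[-1], collapse = "+"),
               outcome = traitId(outcome),
               n_snp = nSnp(res), beta = mrBeta(res), se = mrSE(res),
               or = oddsRatio(res), ci_low = confInt(res)[["ciLow"]],
               ci_high = confInt(res)[["ciHigh"]], pval = mrPval(res),
               q = q@Q, q_pval = q@pval,
               egger_intercept_pval = if (is.null(eg)) NA_real_ else eg$pval,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}
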
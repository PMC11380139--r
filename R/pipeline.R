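#' Pipeline configuration
#'
#' Central knob set for the orchestrated study. Defaults follow the standard
#' two-sample design: genome-wide screen at p < 5e-8 with a locus-wide
#' fallback (applied when the primary screen yields fewer than
#' `min_instruments` SNPs, and logged), clumping at r-squared < 0.001 within
#' 10,000 kb, per-SNP F >= 10, four estimators, Bonferroni correction over
#' `n_methods_bonferroni = 4` methods (0.05 / 4 = 0.0125 with a suggestive
#' band up to 0.05), and 3,000 outlier-test simulation cycles.
#'
#' @param p_threshold_primary genome-wide screen (default 5e-8).
#' @param p_threshold_fallback locus-wide fallback (default 5e-6; microbiome
#'   traits conventionally use 1e-5).
#' @param min_instruments minimum SNPs to proceed without fallback
#'   (default 3, MR-Egger's requirement).
#' @param r2_max,window_kb clumping parameters.
#' @param f_min weak-instrument cutoff.
#' @param alpha,n_methods_bonferroni significance level and method count for
#'   the Bonferroni classification.
#' @param presso_n_sim outlier-test cycles (default 3000).
#' @param presso_outlier_alpha per-SNP outlier flag level (Bonferroni
#'   adjusted; default 0.05).
#' @param n_boot bootstrap replicates for median/mode SEs.
#' @param palindrome_policy harmonization policy (see [harmonize()]).
#' @param exclude character vector of snp ids to exclude (confounder list).
#' @param ld optional LD matrix passed to clumping.
#' @param seed master seed; every stochastic stage derives its own stream
#'   from it.
#' @return A validated list of class `PipelineConfig`.
#' @export
pipelineConfig <- function(p_threshold_primary = 5e-8,
                           p_threshold_fallback = 5e-6,
                           min_instruments = 3,
                           r2_max = 0.001, window_kb = 10000, f_min = 10,
                           alpha = 0.05, n_methods_bonferroni = 4,
                           presso_n_sim = 3000, presso_outlier_alpha = 0.05,
                           n_boot = 1000,
                           palindrome_policy = "infer_by_eaf",
                           exclude = character(), ld = NULL, seed = 1) {
  cfg <- list(p_threshold_primary = p_threshold_primary,
              p_threshold_fallback = p_threshold_fallback,
              min_instruments = as.integer(min_instruments),
              r2_max = r2_max, window_kb = window_kb, f_min = f_min,
              alpha = alpha,
              n_methods_bonferroni = as.integer(n_methods_bonferroni),
              presso_n_sim = as.integer(presso_n_sim),
              presso_outlier_alpha = presso_outlier_alpha,
              n_boot = as.integer(n_boot),
              palindrome_policy = palindrome_policy,
              exclude = exclude, ld = ld, seed = as.integer(seed))
  stopifnot(cfg$p_threshold_primary > 0, cfg$p_threshold_primary < 1,
            cfg$p_threshold_fallback > 0, cfg$p_threshold_fallback < 1,
            cfg$alpha > 0, cfg$alpha < 1, cfg$n_methods_bonferroni >= 1)
  class(cfg) <- "PipelineConfig"
  cfg
}

# instrument selection with the logged fallback threshold
.selectWithFallback <- function(table, config) {
  tryPrimary <- tryCatch(
    selectInstruments(table, pThreshold = config$p_threshold_primary,
                      ld = config$ld, r2Max = config$r2_max,
                      windowKb = config$window_kb, exclude = config$exclude,
                      fMin = config$f_min),
    error = function(e) NULL)
  if (!is.null(tryPrimary) && nSnp(tryPrimary) >= config$min_instruments)
    return(list(instruments = tryPrimary, fallback = FALSE,
                threshold = config$p_threshold_primary))
  fb <- selectInstruments(table, pThreshold = config$p_threshold_fallback,
                          ld = config$ld, r2Max = config$r2_max,
                          windowKb = config$window_kb,
                          exclude = config$exclude, fMin = config$f_min)
  list(instruments = fb, fallback = TRUE,
       threshold = config$p_threshold_fallback)
}

#' Bonferroni significance classification
#'
#' Labels p-values `"significant"` below `alpha / n` (0.05 / 4 = 0.0125 by
#' default), `"suggestive"` in `[alpha / n, alpha)`, and
#' `"not_significant"` otherwise.
#'
#' @param pvals numeric p-values.
#' @param alpha family-wise level (default 0.05).
#' @param n number of test methods corrected over (default 4).
#' @return character labels with the corrected threshold as attribute
#'   `"threshold"`.
#' @export
bonferroniClassify <- function(pvals, alpha = 0.05, n = 4) {
  stopifnot(n >= 1)
  thr <- alpha / n
  out <- ifelse(pvals < thr, "significant",
                ifelse(pvals < alpha, "suggestive", "not_significant"))
  attr(out, "threshold") <- thr
  out
}

#' Bonferroni-corrected threshold
#'
#' @inheritParams bonferroniClassify
#' @return `alpha / n`.
#' @export
bonferroniThreshold <- function(alpha = 0.05, n = 4) {
  stopifnot(n >= 1)
  alpha / n
}

#' Maximum exposure/outcome sample-overlap percentage
#'
#' `100 * nShared / nTotal`, the conservative overlap rate quoted when the
#' same cohort could contribute to both GWAS (largest possible shared sample
#' over the smaller study's total).
#'
#' @param nShared largest sample that could be shared.
#' @param nTotal smaller study's total sample size.
#' @return Percentage.
#' @export
sampleOverlapPercent <- function(nShared, nTotal) {
  stopifnot(nShared >= 0, nTotal > 0)
  100 * nShared / nTotal
}

# one exposure-outcome pair end to end; pairSeed drives all stochastic stages
.runPair <- function(exposure, outcome, config, pairSeed) {
  sel <- .selectWithFallback(exposure, config)
  inst <- subsetSnps(exposure, instrumentRecords(sel$instruments)$snp)
  h <- harmonize(inst, outcome, palindromePolicy = config$palindrome_policy)
  if (!nSnp(h)) stop("no harmonized instruments for ", traitId(exposure),
                     " -> ", traitId(outcome))

  runStage <- function(hs) {
    est <- mrAllMethods(hs, nBoot = config$n_boot, seed = pairSeed)
    J <- nSnp(hs)
    sens <- list(
      q = if (J >= 2) cochranQ(hs) else NULL,
      egger_intercept = if (J >= 3) eggerInterceptTest(hs) else NULL,
      loo = if (J >= 3) leaveOneOut(hs) else NULL,
      presso = if (J >= 4) mrPresso(hs, nSim = config$presso_n_sim,
                                    outlierAlpha = config$presso_outlier_alpha,
                                    seed = deriveSeed(pairSeed, 3)) else NULL)
    list(estimates = est, sensitivity = sens)
  }

  stage <- runStage(h)
  removed <- character()
  # single outlier-removal pass: flagged SNPs are dropped and everything
  # re-estimated once
  pr <- stage$sensitivity$presso
  if (!is.null(pr) && length(outlierSnps(pr))) {
    removed <- outlierSnps(pr)
    h <- subsetHarmonized(h, !(harmonizedData(h)$snp %in% removed))
    stage <- runStage(h)
  }
  primary <- stage$estimates$ivw_auto %||% stage$estimates$wald_ratio
  label <- bonferroniClassify(mrPval(primary), alpha = config$alpha,
                              n = config$n_methods_bonferroni)
  list(exposure = traitId(exposure), outcome = traitId(outcome),
       instruments = sel$instruments, fallback = sel$fallback,
       threshold = sel$threshold, harmonized = h,
       estimates = stage$estimates, sensitivity = stage$sensitivity,
       outliers_removed = removed,
       direction_consistent = attr(stage$estimates, "direction_consistent"),
       label = as.character(label))
}

.resultRows <- function(pair, config) {
  do.call(rbind, lapply(pair$estimates, function(r) {
    data.frame(exposure = pair$exposure, outcome = pair$outcome,
               method = mrMethod(r), n_snp = nSnp(r), beta = mrBeta(r),
               se = mrSE(r), or = oddsRatio(r),
               ci_low = confInt(r)[["ciLow"]],
               ci_high = confInt(r)[["ciHigh"]], pval = mrPval(r),
               label = as.character(bonferroniClassify(
                 mrPval(r), config$alpha, config$n_methods_bonferroni)),
               threshold_used = pair$threshold,
               fallback = pair$fallback,
               direction_consistent = pair$direction_consistent,
               outliers_removed = paste(pair$outliers_removed, collapse = ","),
               stringsAsFactors = FALSE)
  }))
}

.sensitivityRow <- function(pair) {
  s <- pair$sensitivity
  eg <- s$egger_intercept
  pr <- s$presso
  data.frame(exposure = pair$exposure, outcome = pair$outcome,
             egger_intercept = if (is.null(eg)) NA_real_ else eg$intercept,
             intercept_se = if (is.null(eg)) NA_real_ else eg$se,
             egger_pval = if (is.null(eg)) NA_real_ else eg$pval,
             presso_global_pval = if (is.null(pr)) NA_real_ else globalPval(pr),
             cochran_q = if (is.null(s$q)) NA_real_ else s$q@Q,
             cochran_q_pval = if (is.null(s$q)) NA_real_ else s$q@pval,
             stringsAsFactors = FALSE)
}

#' Run the forward two-sample study
#'
#' For every exposure-outcome pair: select instruments (genome-wide screen,
#' logged locus-wide fallback when too few SNPs survive), harmonize, run the
#' estimator battery, run the sensitivity suite, remove flagged outlier SNPs
#' and re-estimate once, and attach Bonferroni significance labels.
#'
#' @param exposures a [SummaryStats-class] or list of them.
#' @param outcomes a [SummaryStats-class] or list of them.
#' @param config a [pipelineConfig()] list.
#' @return A [StudyReport-class] object.
#' @export
runForward <- function(exposures, outcomes, config = pipelineConfig()) {
  if (is(exposures, "SummaryStats")) exposures <- list(exposures)
  if (is(outcomes, "SummaryStats")) outcomes <- list(outcomes)
  pairs <- list()
  k <- 0L
  for (ex in exposures) for (ou in outcomes) {
    k <- k + 1L
    pr <- .runPair(ex, ou, config, deriveSeed(config$seed, k))
    pairs[[paste(pr$exposure, pr$outcome, sep = "|")]] <- pr
  }
  results <- do.call(rbind, lapply(pairs, .resultRows, config = config))
  sens <- do.call(rbind, lapply(pairs, .sensitivityRow))
  loo <- do.call(rbind, lapply(pairs, function(p) {
    if (is.null(p$sensitivity$loo)) return(NULL)
    cbind(exposure = p$exposure, outcome = p$outcome, p$sensitivity$loo,
          stringsAsFactors = FALSE)
  }))
  rownames(results) <- rownames(sens) <- NULL
  if (!is.null(loo)) rownames(loo) <- NULL
  new("StudyReport", results = results, sensitivity = sens,
      loo = loo %||% data.frame(), pairs = pairs,
      config = unclass(config), direction = "forward")
}

#' Run the reverse-direction study
#'
#' Identical machinery with exposure and outcome roles swapped (the disease
#' endpoints instrument the analysis, the original exposures are the
#' outcomes), probing reverse causation. `runReverse(a, b, cfg)` equals
#' `runForward(b, a, cfg)` with the direction recorded as `"reverse"`.
#'
#' @param exposures,outcomes as in [runForward()] (forward-direction roles).
#' @param config a [pipelineConfig()] list.
#' @return A [StudyReport-class] object.
#' @export
runReverse <- function(exposures, outcomes, config = pipelineConfig()) {
  rep <- runForward(outcomes, exposures, config)
  rep@direction <- "reverse"
  rep
}

#' Write a StudyReport to disk
#'
#' Emits `results.tsv`, `sensitivity.tsv` (Egger intercept, intercept se,
#' Egger p, outlier-test global p, Cochran's Q, Q p), `loo.tsv`, `mvmr.tsv`,
#' `mediation.tsv`, a machine-readable `summary.json`, and `run_log.txt`
#' echoing the configuration and seed. Empty tables produce header-only
#' files; a fixed configuration and seed produce byte-identical output.
#'
#' @param report a [StudyReport-class] object.
#' @param outdir output directory (created if needed).
#' @return Invisibly, the vector of written paths.
#' @export
writeReport <- function(report, outdir) {
  stopifnot(is(report, "StudyReport"))
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  wtsv <- function(d, name, emptyCols) {
    p <- file.path(outdir, name)
    if (!nrow(d)) d <- setNames(data.frame(matrix(nrow = 0,
                                                  ncol = length(emptyCols))),
                                emptyCols)
    data.table::fwrite(d, p, sep = "\t", quote = FALSE, na = "NA")
    p
  }
  paths <- c(
    wtsv(report@results, "results.tsv",
         c("exposure", "outcome", "method", "n_snp", "beta", "se", "or",
           "ci_low", "ci_high", "pval", "label")),
    wtsv(report@sensitivity, "sensitivity.tsv",
         c("exposure", "outcome", "egger_intercept", "intercept_se",
           "egger_pval", "presso_global_pval", "cochran_q",
           "cochran_q_pval")),
    wtsv(report@loo, "loo.tsv",
         c("exposure", "outcome", "snp_excluded", "beta", "se", "pval")),
    wtsv(report@mvmr, "mvmr.tsv",
         c("exposure", "adjusted_for", "outcome", "n_snp", "beta", "se",
           "or", "ci_low", "ci_high", "pval")),
    wtsv(report@mediation, "mediation.tsv",
         c("outcome", "mediator", "exposure", "total_or", "direct_or",
           "mediation_or", "pval", "proportion")))
  cfg <- report@config
  cfg$ld <- NULL
  summaryPath <- file.path(outdir, "summary.json")
  jsonlite::write_json(
    list(direction = report@direction,
         n_pairs = length(report@pairs),
         results = report@results,
         sensitivity = report@sensitivity,
         mvmr = report@mvmr,
         mediation = report@mediation,
         config = cfg),
    summaryPath, auto_unbox = TRUE, digits = NA, pretty = TRUE, na = "null")
  logPath <- file.path(outdir, "run_log.txt")
  writeLines(c(
    sprintf("direction: %s", report@direction),
    sprintf("pairs: %s", paste(names(report@pairs), collapse = "; ")),
    "config:",
    vapply(names(cfg), function(nm)
      sprintf("  %s = %s", nm, paste(format(cfg[[nm]]), collapse = ",")),
      character(1))), logPath)
  invisible(c(paths, summaryPath, logPath))
}
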
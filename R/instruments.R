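#' Threshold a summary table on p-value
#'
#' Retains rows with `pval` strictly below `threshold` (the conventional
#' genome-wide screen uses 5e-8; locus-wide screens 5e-6 or 1e-5), preserving
#' input order. An empty result is allowed.
#'
#' @param table a [SummaryStats-class] object.
#' @param threshold p-value cutoff in (0, 1); strict `<` comparison.
#' @return A [SummaryStats-class] object with the retained rows.
#' @export
selectByPvalue <- function(table, threshold) {
  stopifnot(is(table, "SummaryStats"),
            is.numeric(threshold), threshold > 0, threshold < 1)
  v <- variants(table)
  keep <- v[v$pval < threshold, , drop = FALSE]
  rownames(keep) <- NULL
  methods::initialize(table, variants = keep)
}

#' Read a square LD r-squared matrix from tab-delimited text
#'
#' Expects the first column and the header to carry the SNP ids; cells are
#' r-squared values in `[0, 1]`. The matrix must be symmetric with a unit
#' diagonal.
#'
#' @param path file path.
#' @return A named square numeric matrix.
#' @export
readLDMatrix <- function(path) {
  dt <- data.table::fread(path, header = TRUE, data.table = FALSE)
  ids <- as.character(dt[[1]])
  m <- as.matrix(dt[, -1, drop = FALSE])
  rownames(m) <- ids
  validateLDMatrix(m)
  m
}

#' Validate an LD matrix
#'
#' Checks squareness, label agreement, symmetry, entries in `[0, 1]` and a
#' unit diagonal; errors otherwise.
#'
#' @param m named square numeric matrix of r-squared values.
#' @return Invisibly, `m`.
#' @export
validateLDMatrix <- function(m) {
  if (!is.matrix(m) || nrow(m) != ncol(m))
    stop("LD matrix must be square")
  if (is.null(rownames(m)) || is.null(colnames(m)) ||
      !identical(rownames(m), colnames(m)))
    stop("LD matrix must carry identical row and column snp labels")
  if (any(m < 0 | m > 1)) stop("LD r-squared entries must lie in [0, 1]")
  if (max(abs(m - t(m))) > 1e-8) stop("LD matrix must be symmetric")
  if (max(abs(diag(m) - 1)) > 1e-8) stop("LD matrix diagonal must be 1")
  invisible(m)
}

#' Greedy LD clumping
#'
#' Iterates variants by ascending p-value (ties broken by `snp` id for
#' determinism) and keeps a variant only if it conflicts with no
#' already-kept variant. Two variants conflict when they lie within
#' `windowKb` kilobases on the same chromosome **and** their LD r-squared is
#' at least `r2Max`; without an LD matrix the distance criterion alone
#' applies. Retained rows keep their input order.
#'
#' @param table a [SummaryStats-class] object.
#' @param ld optional named r-squared matrix covering the table's snp ids.
#' @param r2Max r-squared cutoff (default 0.001).
#' @param windowKb clumping window in kb (default 10000); interpreted as
#'   |position difference| <= windowKb * 1000 on the same chromosome.
#' @return A [SummaryStats-class] object with the clumped rows.
#' @export
clumpVariants <- function(table, ld = NULL, r2Max = 0.001, windowKb = 10000) {
  stopifnot(is(table, "SummaryStats"))
  v <- variants(table)
  if (nrow(v) <= 1L) return(table)
  havePos <- !anyNA(v$chr) && !anyNA(v$pos)
  if (is.null(ld)) {
    if (!havePos)
      stop("cannot clump: no LD matrix and chromosome/position are missing")
  } else {
    validateLDMatrix(ld)
    miss <- setdiff(v$snp, rownames(ld))
    if (length(miss))
      stop("LD matrix does not cover snp(s): ", paste(miss, collapse = ", "))
  }
  ord <- order(v$pval, v$snp)
  keptIdx <- integer()
  for (i in ord) {
    conflict <- FALSE
    for (j in keptIdx) {
      within <- if (havePos)
        v$chr[i] == v$chr[j] && abs(v$pos[i] - v$pos[j]) <= windowKb * 1000
      else TRUE
      r2 <- if (is.null(ld)) 1 else ld[v$snp[i], v$snp[j]]
      if (within && r2 >= r2Max) { conflict <- TRUE; break }
    }
    if (!conflict) keptIdx <- c(keptIdx, i)
  }
  keep <- v[sort(keptIdx), , drop = FALSE]
  rownames(keep) <- NULL
  methods::initialize(table, variants = keep)
}

#' Remove listed variants (confounder-associated exclusion)
#'
#' Models confounder screening as a user-supplied exclusion list: listed
#' variants are removed; ids absent from the table are a logged no-op.
#'
#' @param table a [SummaryStats-class] object.
#' @param exclusionList character vector of snp ids to remove.
#' @param reason reason recorded for the removals.
#' @return A [SummaryStats-class] object; the removal audit is attached as
#'   attribute `"exclusions"` (data.frame `snp, reason, present`).
#' @export
excludeSnps <- function(table, exclusionList, reason = "confounder-associated") {
  stopifnot(is(table, "SummaryStats"))
  v <- variants(table)
  exclusionList <- unique(as.character(exclusionList))
  present <- exclusionList %in% v$snp
  keep <- v[!v$snp %in% exclusionList, , drop = FALSE]
  rownames(keep) <- NULL
  out <- methods::initialize(table, variants = keep)
  attr(out, "exclusions") <- data.frame(snp = exclusionList,
                                        reason = rep_len(reason,
                                                         length(exclusionList)),
                                        present = present,
                                        stringsAsFactors = FALSE)
  out
}

#' Read a two-column exclusion list (snp id, reason)
#'
#' @param path tab-delimited file with columns `snp` and `reason` (header
#'   optional; a headerless file is read positionally).
#' @return data.frame with columns `snp` and `reason`.
#' @export
readExclusionList <- function(path) {
  dt <- data.table::fread(path, header = "auto", data.table = FALSE)
  if (!all(c("snp", "reason") %in% names(dt))) {
    if (ncol(dt) < 1) stop("empty exclusion list: ", path)
    names(dt)[1] <- "snp"
    if (ncol(dt) >= 2) names(dt)[2] <- "reason" else dt$reason <- "listed"
  }
  dt[, c("snp", "reason")]
}

#' Per-SNP F statistic
#'
#' The squared Wald statistic `(beta / se)^2`, the standard instrument
#' strength measure for a single variant; invariant under sign flips of beta
#' and monotone decreasing in `se`.
#'
#' @param beta per-allele effect estimate(s).
#' @param se standard error(s), strictly positive.
#' @return Numeric F statistic(s).
#' @export
perSnpF <- function(beta, se) {
  if (any(!is.finite(se)) || any(se <= 0)) stop("se must be > 0")
  (beta / se)^2
}

#' Group F statistic for a set of instruments
#'
#' Uses the standardized-trait variance-explained approximation
#' `R^2 = sum_j 2 * eaf_j * (1 - eaf_j) * beta_j^2` (capped below 1) and
#' returns `((n - k - 1) / k) * R^2 / (1 - R^2)` for `k` instruments and
#' exposure sample size `n`.
#'
#' @param table a [SummaryStats-class] object whose rows are the instrument
#'   set; `eaf` must be present for every row.
#' @param n exposure GWAS sample size; must exceed `k + 1`.
#' @param k number of instruments (defaults to the row count).
#' @return The group F statistic (scalar).
#' @export
groupF <- function(table, n, k = nSnp(table)) {
  stopifnot(is(table, "SummaryStats"))
  v <- variants(table)
  if (k < 1) stop("k must be >= 1")
  if (n <= k + 1) stop("n must exceed k + 1")
  if (anyNA(v$eaf))
    stop("eaf missing for some instruments; group F needs allele ",
         "frequencies - use perSnpF() only")
  r2 <- sum(2 * v$eaf * (1 - v$eaf) * v$beta^2)
  r2 <- min(r2, 1 - 1e-10)
  ((n - k - 1) / k) * r2 / (1 - r2)
}

#' Drop weak instruments from an InstrumentSet
#'
#' Removes instruments with per-SNP F below `fMin` (default 10, the
#' conventional weak-instrument cutoff) and appends the step to the
#' selection log. Removing every instrument is fatal: the estimators need at
#' least one.
#'
#' @param instruments an [InstrumentSet-class] object.
#' @param fMin minimum per-SNP F.
#' @return An [InstrumentSet-class] object.
#' @export
filterWeak <- function(instruments, fMin = 10) {
  stopifnot(is(instruments, "InstrumentSet"))
  rec <- instruments@records
  keep <- rec[rec$F >= fMin, , drop = FALSE]
  if (!nrow(keep))
    stop("no valid instruments: all per-SNP F below ", fMin)
  rownames(keep) <- NULL
  log <- rbind(instruments@selectionLog,
               data.frame(step = "filter_weak", n_before = nrow(rec),
                          n_after = nrow(keep),
                          note = sprintf("F >= %g", fMin),
                          stringsAsFactors = FALSE))
  methods::initialize(instruments, records = keep, selectionLog = log)
}

#' Full instrument-selection pipeline
#'
#' Applies, in order: p-value thresholding, greedy LD clumping, removal of
#' listed (confounder-associated) variants, per-SNP F computation and
#' weak-instrument filtering. Every step is recorded with before/after counts
#' in the selection log. The group F statistic is computed when `n` and
#' complete allele frequencies are available, else left `NA`.
#'
#' @param table exposure [SummaryStats-class].
#' @param pThreshold significance threshold (strict `<`).
#' @param ld optional LD r-squared matrix for clumping.
#' @param r2Max,windowKb clumping parameters (defaults 0.001 and 10000 kb).
#' @param exclude character vector of snp ids to exclude.
#' @param excludeReason reason logged for exclusions.
#' @param fMin minimum per-SNP F (default 10).
#' @param n exposure sample size for the group F statistic; defaults to the
#'   median of the table's `n` column when present.
#' @param clump set `FALSE` to skip clumping (e.g. pre-clumped input).
#' @return An [InstrumentSet-class] object.
#' @export
selectInstruments <- function(table, pThreshold = 5e-6, ld = NULL,
                              r2Max = 0.001, windowKb = 10000,
                              exclude = character(),
                              excludeReason = "confounder-associated",
                              fMin = 10, n = NULL, clump = TRUE) {
  stopifnot(is(table, "SummaryStats"))
  log <- data.frame(step = character(), n_before = integer(),
                    n_after = integer(), note = character(),
                    stringsAsFactors = FALSE)
  note <- function(step, before, after, txt) {
    log <<- rbind(log, data.frame(step = step, n_before = before,
                                  n_after = after, note = txt,
                                  stringsAsFactors = FALSE))
  }
  n0 <- nSnp(table)
  sel <- selectByPvalue(table, pThreshold)
  note("select_by_pvalue", n0, nSnp(sel), sprintf("p < %g", pThreshold))
  if (!nSnp(sel)) stop("no valid instruments: none pass p < ", pThreshold)
  if (clump) {
    before <- nSnp(sel)
    sel <- clumpVariants(sel, ld = ld, r2Max = r2Max, windowKb = windowKb)
    note("clump", before, nSnp(sel),
         sprintf("r2 < %g within %g kb", r2Max, windowKb))
  }
  if (length(exclude)) {
    before <- nSnp(sel)
    sel <- excludeSnps(sel, exclude, reason = excludeReason)
    note("exclude", before, nSnp(sel), excludeReason)
    if (!nSnp(sel)) stop("no valid instruments after exclusions")
  }
  rec <- variants(sel)
  rec$F <- perSnpF(rec$beta, rec$se)
  iset <- new("InstrumentSet", traitId = traitId(table), records = rec,
              groupF = NA_real_, selectionLog = log)
  iset <- filterWeak(iset, fMin = fMin)
  nEff <- n %||% (if (!anyNA(rec$n)) stats::median(rec$n) else NULL)
  k <- nrow(iset@records)
  if (!is.null(nEff) && !anyNA(iset@records$eaf) && nEff > k + 1) {
    tmp <- methods::initialize(sel, variants = iset@records[, .CANONICAL_COLS])
    iset@groupF <- groupF(tmp, n = nEff, k = k)
  }
  validObject(iset)
  iset
}
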
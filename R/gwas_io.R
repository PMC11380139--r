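#' Construct a SummaryStats object from a data.frame
#'
#' Normalizes a per-variant association table to the canonical column set,
#' validates every record, and moves rows violating the record invariants
#' (non-positive `se`, `pval` outside (0, 1], `eaf` outside (0, 1), identical
#' alleles, empty or duplicated `snp`, unparseable numerics) into the
#' `rejected` slot with a reason.
#'
#' @param variants data.frame with at least the mandatory columns
#'   `snp, effect_allele, other_allele, beta, se, pval` (canonical names;
#'   see [readSummaryStats()] for dialect mapping).
#' @param traitId trait identifier.
#' @param traitType `"quantitative"` or `"binary"`.
#' @param nCase,nControl case/control counts for binary traits.
#' @return A [SummaryStats-class] object.
#' @export
SummaryStats <- function(variants, traitId = "trait",
                         traitType = c("quantitative", "binary"),
                         nCase = NA_real_, nControl = NA_real_) {
  traitType <- match.arg(traitType)
  stopifnot(is.data.frame(variants))
  miss <- setdiff(.MANDATORY_COLS, names(variants))
  if (length(miss))
    stop("missing mandatory column(s): ", paste(miss, collapse = ", "))
  v <- as.data.frame(variants, stringsAsFactors = FALSE)
  for (col in setdiff(.CANONICAL_COLS, names(v)))
    v[[col]] <- rep(if (col %in% c("snp", "effect_allele", "other_allele"))
      NA_character_ else NA_real_, nrow(v))
  v <- v[, .CANONICAL_COLS]
  v$snp <- as.character(v$snp)
  v$effect_allele <- as.character(v$effect_allele)
  v$other_allele <- as.character(v$other_allele)
  for (col in c("pos", "eaf", "beta", "se", "pval", "n", "n_case", "n_control"))
    v[[col]] <- suppressWarnings(as.numeric(v[[col]]))
  v$chr <- as.character(v$chr)

  reason <- rep(NA_character_, nrow(v))
  flag <- function(cond, why) {
    cond[is.na(cond)] <- FALSE
    reason[cond & is.na(reason)] <<- why
  }
  flag(is.na(v$snp) | !nzchar(v$snp), "empty snp id")
  flag(duplicated(v$snp), "duplicate snp id")
  flag(is.na(v$beta), "unparseable or missing beta")
  flag(is.na(v$se), "unparseable or missing se")
  flag(!is.na(v$se) & v$se <= 0, "se not > 0")
  flag(is.na(v$pval), "unparseable or missing pval")
  flag(!is.na(v$pval) & (v$pval <= 0 | v$pval > 1), "pval outside (0, 1]")
  flag(!is.na(v$eaf) & (v$eaf <= 0 | v$eaf >= 1), "eaf outside (0, 1)")
  flag(is.na(v$effect_allele) | is.na(v$other_allele) |
         toupper(v$effect_allele) == toupper(v$other_allele),
       "effect_allele equals other_allele")
  if (traitType == "binary" && is.finite(nCase) && is.finite(nControl))
    flag(!is.na(v$n) & v$n != nCase + nControl,
         "n inconsistent with nCase + nControl")

  bad <- !is.na(reason)
  rejected <- if (any(bad)) cbind(v[bad, , drop = FALSE],
                                  reason = reason[bad]) else
    data.frame()
  keep <- v[!bad, , drop = FALSE]
  rownames(keep) <- NULL
  if (nrow(rejected)) rownames(rejected) <- NULL
  new("SummaryStats", traitId = traitId, traitType = traitType,
      nCase = as.numeric(nCase), nControl = as.numeric(nControl),
      variants = keep, rejected = rejected)
}

#' Read GWAS summary statistics from a delimited file
#'
#' Reads a (possibly gzip-compressed) delimited summary-statistic table,
#' renames columns to the canonical schema through a user dialect map,
#' validates every record and logs per-row rejections. A missing mandatory
#' column is a fatal schema error; an unparseable numeric rejects only that
#' row.
#'
#' @param path file path (plain or `.gz`).
#' @param dialect named character vector mapping canonical names to the file's
#'   column names, e.g. `c(snp = "SNP", effect_allele = "EA", beta = "b")`.
#'   Canonical names: `r paste(.CANONICAL_COLS, collapse = ", ")`.
#' @param rejectionLog optional path; when given, rejected rows are written
#'   there as a tab-delimited audit with their reasons.
#' @inheritParams SummaryStats
#' @return A [SummaryStats-class] object.
#' @export
readSummaryStats <- function(path, dialect = NULL, traitId = NULL,
                             traitType = c("quantitative", "binary"),
                             nCase = NA_real_, nControl = NA_real_,
                             rejectionLog = NULL) {
  traitType <- match.arg(traitType)
  if (!file.exists(path)) stop("file not found: ", path)
  if (grepl("\\.gz$", path)) {
    con <- gzfile(path, "rt")
    txt <- paste(readLines(con), collapse = "\n")
    close(con)
    dt <- data.table::fread(text = txt, header = TRUE, data.table = FALSE,
                            na.strings = c("NA", ""), showProgress = FALSE)
  } else {
    dt <- data.table::fread(path, header = TRUE, data.table = FALSE,
                            na.strings = c("NA", ""), showProgress = FALSE)
  }
  if (!is.null(dialect)) {
    bad <- setdiff(unname(dialect), names(dt))
    if (length(bad))
      stop("dialect names columns absent from file: ",
           paste(bad, collapse = ", "))
    idx <- match(unname(dialect), names(dt))
    names(dt)[idx] <- names(dialect)
  }
  miss <- setdiff(.MANDATORY_COLS, names(dt))
  if (length(miss))
    stop("schema error: mandatory column(s) not resolvable: ",
         paste(miss, collapse = ", "))
  out <- SummaryStats(dt, traitId = traitId %||%
                        sub("\\.(tsv|txt)(\\.gz)?$", "", basename(path)),
                      traitType = traitType, nCase = nCase,
                      nControl = nControl)
  if (!is.null(rejectionLog) && nrow(out@rejected))
    data.table::fwrite(out@rejected, rejectionLog, sep = "\t", quote = FALSE)
  out
}

#' Write a SummaryStats table as canonical tab-delimited text
#'
#' Emits the canonical columns in fixed order. Numerics are written with 17
#' significant digits so that [readSummaryStats()] on the output reproduces
#' the table exactly (round-trip identity).
#'
#' @param table a [SummaryStats-class] object.
#' @param path output file path (`.gz` suffix compresses).
#' @return Invisibly, `path`.
#' @export
writeSummaryStats <- function(table, path) {
  stopifnot(is(table, "SummaryStats"))
  v <- variants(table)
  out <- v
  for (col in names(out)) {
    if (is.numeric(out[[col]])) {
      x <- formatC(out[[col]], digits = 17, format = "g")
      x[is.na(out[[col]])] <- "NA"
      out[[col]] <- x
    }
  }
  con <- if (grepl("\\.gz$", path)) gzfile(path, "wt") else file(path, "wt")
  on.exit(close(con))
  ok <- try({
    writeLines(paste(names(out), collapse = "\t"), con)
    if (nrow(out))
      writeLines(do.call(paste, c(lapply(out, as.character), sep = "\t")), con)
  }, silent = TRUE)
  if (inherits(ok, "try-error")) stop("failed to write: ", path)
  invisible(path)
}

#' Keep a subset of variants of a SummaryStats table
#'
#' @param x a [SummaryStats-class] object.
#' @param snps character vector of `snp` ids to retain (input order is kept).
#' @return A [SummaryStats-class] object with only the listed variants.
#' @export
subsetSnps <- function(x, snps) {
  stopifnot(is(x, "SummaryStats"))
  v <- variants(x)
  keep <- v[v$snp %in% snps, , drop = FALSE]
  rownames(keep) <- NULL
  methods::initialize(x, variants = keep)
}

#' Construct a HarmonizedSet directly from aligned effect vectors
#'
#' Convenience constructor for data already on a common effect allele (e.g.
#' externally harmonized estimates), mirroring how practitioners feed
#' beta/SE vectors straight into estimators.
#'
#' @param betaExposure,seExposure,betaOutcome,seOutcome numeric vectors.
#' @param snp variant identifiers (defaults to `snp_1 ... snp_J`).
#' @param effectAllele,otherAllele allele labels (defaults `A`/`G`).
#' @param eaf effect-allele frequencies (optional).
#' @param exposureId,outcomeId trait identifiers.
#' @return A [HarmonizedSet-class] object.
#' @export
HarmonizedSet <- function(betaExposure, seExposure, betaOutcome, seOutcome,
                          snp = NULL, effectAllele = "A", otherAllele = "G",
                          eaf = NA_real_, exposureId = "exposure",
                          outcomeId = "outcome") {
  J <- length(betaExposure)
  stopifnot(length(seExposure) == J, length(betaOutcome) == J,
            length(seOutcome) == J)
  d <- data.frame(
    snp = snp %||% sprintf("snp_%d", seq_len(J)),
    effect_allele = rep_len(effectAllele, J),
    other_allele = rep_len(otherAllele, J),
    beta_exposure = as.numeric(betaExposure),
    se_exposure = as.numeric(seExposure),
    beta_outcome = as.numeric(betaOutcome),
    se_outcome = as.numeric(seOutcome),
    eaf = rep_len(as.numeric(eaf), J),
    flipped = FALSE, palindromic = FALSE,
    stringsAsFactors = FALSE
  )
  new("HarmonizedSet", exposureId = exposureId, outcomeId = outcomeId,
      data = d, dropped = data.frame(snp = character(), reason = character()))
}

#' Subset a HarmonizedSet by row
#'
#' @param h a [HarmonizedSet-class] object.
#' @param keep logical or integer index, or character vector of snp ids.
#' @return A [HarmonizedSet-class] with the selected rows.
#' @export
subsetHarmonized <- function(h, keep) {
  stopifnot(is(h, "HarmonizedSet"))
  d <- harmonizedData(h)
  if (is.character(keep)) keep <- d$snp %in% keep
  d <- d[keep, , drop = FALSE]
  rownames(d) <- NULL
  methods::initialize(h, data = d)
}

# Orientation of one table's rows onto reference alleles. Returns a list with
# `status` ("aligned", "flip", "mismatch"), vectorized over rows; palindromic
# handling is done by the caller.
.orientAlleles <- function(refEA, refOA, ea, oa) {
  refEA <- toupper(refEA); refOA <- toupper(refOA)
  ea <- toupper(ea); oa <- toupper(oa)
  pal <- isPalindromicPair(refEA, refOA)
  direct <- ea == refEA & oa == refOA
  swapped <- ea == refOA & oa == refEA
  cea <- complementAllele(ea); coa <- complementAllele(oa)
  canFlip <- !pal & !is.na(cea) & !is.na(coa)
  sdirect <- !direct & !swapped & canFlip & cea == refEA & coa == refOA
  sswapped <- !direct & !swapped & canFlip & cea == refOA & coa == refEA
  status <- rep("mismatch", length(ea))
  status[direct | sdirect] <- "aligned"
  status[swapped | sswapped] <- "flip"
  list(status = status, palindromic = pal)
}

#' Harmonize exposure and outcome summary statistics
#'
#' Intersects the two tables on `snp` and aligns every shared variant to the
#' exposure's effect allele. Where the outcome's alleles are swapped relative
#' to the exposure, the outcome beta sign is flipped and its frequency
#' complemented (`flipped = TRUE`). Non-palindromic single-base variants whose
#' alleles match only after strand complementation are treated as reported on
#' the opposite strand. Palindromic variants (A/T or C/G) are handled per
#' `palindromePolicy`:
#'
#' * `"infer_by_eaf"` (default): use allele frequencies to resolve the strand;
#'   a variant is dropped as ambiguous when either study's frequency is
#'   missing or within `eafWindow` of 0.5. When the two frequencies fall on
#'   opposite sides of 0.5 the outcome is taken to be on the other strand and
#'   is flipped.
#' * `"drop"`: drop every palindromic variant.
#' * `"keep"`: trust the reported alleles as-is.
#'
#' Rows with irreconcilable alleles are dropped with reason
#' `"allele_mismatch"`. Retained + dropped row counts always add up to the
#' intersection size.
#'
#' @param exposure,outcome [SummaryStats-class] objects.
#' @param palindromePolicy `"infer_by_eaf"`, `"drop"` or `"keep"`.
#' @param eafWindow half-width of the ambiguity window around eaf = 0.5 used
#'   by `"infer_by_eaf"` (default 0.08).
#' @return A [HarmonizedSet-class] object.
#' @export
harmonize <- function(exposure, outcome,
                      palindromePolicy = c("infer_by_eaf", "drop", "keep"),
                      eafWindow = 0.08) {
  stopifnot(is(exposure, "SummaryStats"), is(outcome, "SummaryStats"))
  palindromePolicy <- match.arg(palindromePolicy)
  ex <- variants(exposure); ou <- variants(outcome)
  shared <- intersect(ex$snp, ou$snp)
  if (!length(shared))
    stop("no shared instruments between '", traitId(exposure), "' and '",
         traitId(outcome), "'")
  ex <- ex[match(shared, ex$snp), , drop = FALSE]
  ou <- ou[match(shared, ou$snp), , drop = FALSE]

  ori <- .orientAlleles(ex$effect_allele, ex$other_allele,
                        ou$effect_allele, ou$other_allele)
  status <- ori$status
  pal <- ori$palindromic
  flip <- status == "flip"
  betaOut <- ifelse(flip, -ou$beta, ou$beta)
  eafOut <- ifelse(flip, 1 - ou$eaf, ou$eaf)
  reason <- ifelse(status == "mismatch", "allele_mismatch", NA_character_)

  if (palindromePolicy == "drop") {
    reason[pal & is.na(reason)] <- "palindromic"
  } else if (palindromePolicy == "infer_by_eaf") {
    amb <- pal & is.na(reason) &
      (is.na(ex$eaf) | is.na(eafOut) |
         abs(ex$eaf - 0.5) <= eafWindow | abs(eafOut - 0.5) <= eafWindow)
    reason[amb] <- "palindromic_ambiguous_eaf"
    # unambiguous palindromic rows whose frequencies disagree in direction
    # are on the opposite strand: flip once more
    strandFlip <- pal & is.na(reason) &
      (sign(ex$eaf - 0.5) != sign(eafOut - 0.5))
    betaOut[strandFlip] <- -betaOut[strandFlip]
    eafOut[strandFlip] <- 1 - eafOut[strandFlip]
    flip[strandFlip] <- !flip[strandFlip]
  }

  keep <- is.na(reason)
  d <- data.frame(
    snp = shared[keep],
    effect_allele = toupper(ex$effect_allele[keep]),
    other_allele = toupper(ex$other_allele[keep]),
    beta_exposure = ex$beta[keep],
    se_exposure = ex$se[keep],
    beta_outcome = betaOut[keep],
    se_outcome = ou$se[keep],
    eaf = ifelse(is.na(ex$eaf[keep]), eafOut[keep], ex$eaf[keep]),
    flipped = flip[keep],
    palindromic = pal[keep],
    stringsAsFactors = FALSE
  )
  rownames(d) <- NULL
  dropped <- data.frame(snp = shared[!keep], reason = reason[!keep],
                        stringsAsFactors = FALSE)
  new("HarmonizedSet", exposureId = traitId(exposure),
      outcomeId = traitId(outcome), data = d, dropped = dropped)
}
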
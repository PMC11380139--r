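#' @keywords internal
"_PACKAGE"

#' @importFrom methods new is validObject slot setClass setGeneric setMethod
#'   setValidity show slotNames
#' @importFrom stats pnorm pchisq pt qnorm rnorm runif sd mad median quantile
#'   dnorm lm optimize setNames rbinom
#' @importFrom utils head
NULL

`%||%` <- function(a, b) if (is.null(a)) b else a

# Evaluate `code` under a temporary RNG state seeded with `seed`; the caller's
# RNG stream is restored afterwards so seeded estimators do not perturb
# surrounding simulations. seed = NULL runs on the ambient stream.
withSeed <- function(seed, code) {
  if (is.null(seed)) return(force(code))
  genv <- globalenv()
  had <- exists(".Random.seed", envir = genv, inherits = FALSE)
  if (had) {
    old <- get(".Random.seed", envir = genv, inherits = FALSE)
    on.exit(assign(".Random.seed", old, envir = genv), add = TRUE)
  } else {
    on.exit(suppressWarnings(rm(".Random.seed", envir = genv)), add = TRUE)
  }
  set.seed(as.integer(seed))
  force(code)
}

# Deterministic sub-seed derivation: one user-facing seed drives every
# stochastic stage, each stage offset by a distinct small prime multiple.
# Kept below 2^31 - 1 so it is always a valid R integer.
deriveSeed <- function(seed, k) {
  if (is.null(seed)) return(NULL)
  as.integer((as.numeric(seed) + 7919 * as.numeric(k)) %% 2147483647L)
}

.COMPLEMENT <- c(A = "T", T = "A", C = "G", G = "C")

# Single-base strand complement; multi-base (indel) alleles return NA and are
# never strand-flipped.
complementAllele <- function(x) {
  out <- unname(.COMPLEMENT[toupper(x)])
  out[nchar(x) != 1L] <- NA_character_
  out
}

isPalindromicPair <- function(ea, oa) {
  ea <- toupper(ea); oa <- toupper(oa)
  ok <- nchar(ea) == 1L & nchar(oa) == 1L & !is.na(.COMPLEMENT[ea])
  ok & !is.na(oa) & unname(.COMPLEMENT[ea]) == oa
}

twoSidedNormalP <- function(z) 2 * pnorm(-abs(z))

twoSidedTP <- function(t, df) 2 * pt(-abs(t), df = df)

# Canonical column order for summary-statistic tables.
.CANONICAL_COLS <- c("snp", "chr", "pos", "effect_allele", "other_allele",
                     "eaf", "beta", "se", "pval", "n", "n_case", "n_control")
.MANDATORY_COLS <- c("snp", "effect_allele", "other_allele", "beta", "se", "pval")
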
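# in-code fixtures: small summary tables and harmonized sets built on the fly

makeTable <- function(beta, se, pval = NULL,
                      snp = sprintf("rs%03d", seq_along(beta)),
                      ea = "A", oa = "G", eaf = 0.3, chr = "1",
                      pos = seq_along(beta) * 2e7 + 1e6, n = 10000,
                      traitId = "trait", traitType = "quantitative",
                      nCase = NA_real_, nControl = NA_real_) {
  J <- length(beta)
  pval <- pval %||% pmax(2 * pnorm(-abs(beta / se)), 1e-300)
  SummaryStats(data.frame(
    snp = snp, chr = rep_len(chr, J), pos = rep_len(pos, J),
    effect_allele = rep_len(ea, J), other_allele = rep_len(oa, J),
    eaf = rep_len(eaf, J), beta = beta, se = rep_len(se, J),
    pval = rep_len(pval, J), n = rep_len(n, J),
    stringsAsFactors = FALSE
  ), traitId = traitId, traitType = traitType, nCase = nCase,
  nControl = nControl)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# harmonized set with chosen effects (exposure SEs small by default so
# first-order ratio variances dominate)
makeH <- function(bx, by, sy, sx = 0.01) {
  HarmonizedSet(betaExposure = bx, seExposure = rep_len(sx, length(bx)),
                betaOutcome = by, seOutcome = rep_len(sy, length(bx)))
}

randomH <- function(J = 10, seed = 1) {
  set.seed(seed)
  bx <- sample(c(-1, 1), J, TRUE) * runif(J, 0.3, 1.5)
  sy <- runif(J, 0.05, 0.3)
  by <- 0.3 * bx + rnorm(J, 0, sy)
  makeH(bx, by, sy, sx = runif(J, 0.01, 0.05))
}

# rebuild exposure/outcome SummaryStats tables from a HarmonizedSet (used by
# the involution property)
tablesFromH <- function(h) {
  d <- harmonizedData(h)
  base <- data.frame(snp = d$snp, chr = "1",
                     pos = seq_len(nrow(d)) * 2e7,
                     effect_allele = d$effect_allele,
                     other_allele = d$other_allele, eaf = d$eaf,
                     stringsAsFactors = FALSE)
  ex <- cbind(base, beta = d$beta_exposure, se = d$se_exposure, pval = 0.5,
              n = 10000)
  ou <- cbind(base, beta = d$beta_outcome, se = d$se_outcome, pval = 0.5,
              n = 10000)
  list(exposure = SummaryStats(ex, traitId = exposureId(h)),
       outcome = SummaryStats(ou, traitId = outcomeId(h)))
}
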
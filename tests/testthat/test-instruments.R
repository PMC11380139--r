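test_that("p-value thresholding is strict and order-preserving", {
  tab <- makeTable(beta = c(1, 1, 1), se = 0.1,
                   pval = c(4.9e-6, 5e-6, 5.1e-6))
  kept <- selectByPvalue(tab, 5e-6)
  expect_equal(variants(kept)$snp, "rs001")        # only p strictly below
  expect_equal(nSnp(selectByPvalue(tab, 0.9999)), 3L)
  expect_error(selectByPvalue(tab, 0))
  expect_error(selectByPvalue(tab, 1))
})

test_that("null variants are retained at the threshold rate", {
  set.seed(7)
  nNull <- 5e5
  z <- rnorm(nNull)
  tab <- SummaryStats(data.frame(
    snp = sprintf("s%d", seq_len(nNull)), effect_allele = "A",
    other_allele = "G", beta = z, se = 1,
    pval = pmax(2 * pnorm(-abs(z)), 1e-300), stringsAsFactors = FALSE))
  kept <- nSnp(selectByPvalue(tab, 1e-5))
  # Binomial(5e5, 1e-5): mean 5; [0, 17] covers all but ~3e-6 of the mass
  expect_lte(kept, 17L)
})

test_that("greedy clumping follows p-order, LD and distance rules", {
  # two correlated SNPs at one locus: only the smaller p survives
  tab <- makeTable(beta = c(1, 1), se = 0.1, pval = c(1e-8, 1e-6),
                   chr = "1", pos = c(1e6, 2e6))
  ld <- matrix(c(1, 0.5, 0.5, 1), 2, 2,
               dimnames = list(c("rs001", "rs002"), c("rs001", "rs002")))
  out <- clumpVariants(tab, ld = ld, r2Max = 0.001, windowKb = 10000)
  expect_equal(variants(out)$snp, "rs001")

  # identity LD (no correlation anywhere): table unchanged
  ld0 <- diag(2); dimnames(ld0) <- dimnames(ld)
  expect_equal(variants(clumpVariants(tab, ld = ld0))$snp, c("rs001", "rs002"))

  # 10 SNPs inside one window, no LD matrix: distance rule keeps the best p
  tab10 <- makeTable(beta = rep(1, 10), se = 0.1,
                     pval = c(1e-6, 1e-9, rep(1e-5, 8)),
                     chr = "2", pos = seq(1e6, by = 1e5, length.out = 10))
  out10 <- clumpVariants(tab10, windowKb = 10000)
  expect_equal(variants(out10)$snp, "rs002")

  # different chromosomes never conflict on distance
  tabChr <- makeTable(beta = rep(1, 2), se = 0.1, pval = c(1e-8, 1e-6),
                      chr = c("1", "2"), pos = c(1e6, 1e6))
  expect_equal(nSnp(clumpVariants(tabChr)), 2L)

  # no LD and no positions is fatal
  tabNoPos <- makeTable(beta = c(1, 1), se = 0.1, pos = NA_real_)
  expect_error(clumpVariants(tabNoPos), "cannot clump")
})

test_that("clumped output has no retained pair violating the r2/window rule", {
  set.seed(3)
  J <- 25
  ids <- sprintf("rs%03d", 1:J)
  r2 <- matrix(runif(J * J, 0, 0.2), J, J); r2 <- (r2 + t(r2)) / 2
  diag(r2) <- 1
  dimnames(r2) <- list(ids, ids)
  tab <- makeTable(beta = rnorm(J), se = 0.1, pval = runif(J, 1e-10, 1e-4),
                   chr = as.character(rep(1:5, each = 5)),
                   pos = rep(seq(1e6, by = 4e6, length.out = 5), 5))
  out <- clumpVariants(tab, ld = r2, r2Max = 0.05, windowKb = 10000)
  v <- variants(out)
  if (nrow(v) > 1) {
    for (i in seq_len(nrow(v) - 1)) for (j in (i + 1):nrow(v)) {
      within <- v$chr[i] == v$chr[j] && abs(v$pos[i] - v$pos[j]) <= 1e7
      expect_false(within && r2[v$snp[i], v$snp[j]] >= 0.05)
    }
  }
  expect_true(all(v$snp %in% variants(tab)$snp))
})

test_that("exclusion lists remove listed variants and log absences", {
  tab <- makeTable(beta = rnorm(5), se = 0.1)
  expect_equal(nSnp(excludeSnps(tab, character())), 5L)
  out <- excludeSnps(tab, c("rs001", "rs003"), reason = "confounder")
  expect_equal(nSnp(out), 3L)
  out2 <- excludeSnps(tab, c("rs001", "rs_absent"))
  expect_equal(nSnp(out2), 4L)
  log <- attr(out2, "exclusions")
  expect_equal(log$present, c(TRUE, FALSE))
})

test_that("per-SNP F is the squared Wald statistic", {
  expect_equal(perSnpF(0.1, 0.02), 25)
  expect_equal(perSnpF(0, 0.5), 0)
  expect_equal(perSnpF(-0.3, 0.1), 9)          # sign-invariant
  expect_equal(perSnpF(0.3, 0.1), perSnpF(-0.3, 0.1))
  expect_error(perSnpF(0.1, 0), "se")
  # monotone decreasing in se
  ses <- seq(0.01, 0.5, length.out = 20)
  expect_true(all(diff(perSnpF(0.2, ses)) < 0))
})

test_that("group F follows the variance-explained formula", {
  # k = 1, eaf = 0.5, beta chosen so R^2 = 0.01, n = 1002 -> ~10.101
  beta <- sqrt(0.01 / (2 * 0.5 * 0.5))
  tab <- makeTable(beta = beta, se = 0.01, eaf = 0.5)
  expect_equal(groupF(tab, n = 1002, k = 1), 1000 * 0.01 / 0.99,
               tolerance = 1e-12)
  # R^2 -> 0 drives F -> 0
  tiny <- makeTable(beta = 1e-8, se = 0.01, eaf = 0.5)
  expect_lt(groupF(tiny, n = 1002), 1e-10)
  # random instance vs an independent recomputation
  set.seed(9)
  eaf <- runif(8, 0.1, 0.9); b <- rnorm(8, 0, 0.1)
  tab2 <- makeTable(beta = b, se = 0.02, eaf = eaf)
  r2 <- sum(2 * eaf * (1 - eaf) * b^2)
  expect_equal(groupF(tab2, n = 5000),
               ((5000 - 8 - 1) / 8) * r2 / (1 - r2), tolerance = 1e-12)
  # missing eaf is a domain error pointing at perSnpF
  expect_error(groupF(makeTable(beta = 0.1, se = 0.01, eaf = NA_real_),
                      n = 1000), "perSnpF")
  expect_error(groupF(tab, n = 2), "exceed")
})

test_that("weak instruments are removed at the F threshold", {
  # F values 25, 9.9, 11.16: the F = 11.16 boundary instrument survives
  fvals <- c(25, 9.9, 11.16)
  tab <- makeTable(beta = sqrt(fvals) * 0.1, se = 0.1)
  iset <- selectInstruments(tab, pThreshold = 0.999, fMin = 10)
  expect_setequal(instrumentRecords(iset)$snp, c("rs001", "rs003"))
  expect_equal(sort(instrumentRecords(iset)$F), c(11.16, 25), tolerance = 1e-9)
  # fMin = 0 keeps everything; all strong keeps everything
  expect_equal(nSnp(selectInstruments(tab, pThreshold = 0.999, fMin = 0)), 3L)
  # removing every instrument is fatal
  weak <- makeTable(beta = rep(0.01, 3), se = 0.1)
  expect_error(selectInstruments(weak, pThreshold = 0.999, fMin = 10),
               "no valid instruments")
})

test_that("full selection is the identity when no filter bites", {
  tab <- makeTable(beta = rep(0.5, 6), se = 0.05, pval = rep(1e-9, 6),
                   chr = as.character(1:6))
  ld <- diag(6); dimnames(ld) <- list(variants(tab)$snp, variants(tab)$snp)
  iset <- selectInstruments(tab, pThreshold = 5e-6, ld = ld, fMin = 10)
  expect_equal(instrumentRecords(iset)$snp, variants(tab)$snp)
  # the selection log reproduces the counts of every stage
  log <- selectionLog(iset)
  expect_equal(log$step,
               c("select_by_pvalue", "clump", "filter_weak"))
  expect_equal(log$n_before, c(6L, 6L, 6L))
  expect_equal(log$n_after, c(6L, 6L, 6L))
  expect_true(is.finite(groupFStat(iset)))
})

test_that("selection log records threshold, clump and exclusion counts", {
  tab <- makeTable(beta = c(rep(0.5, 4), 0.01), se = 0.05,
                   pval = c(1e-9, 1e-9, 1e-9, 1e-3, 1e-9),
                   chr = as.character(1:5))
  iset <- selectInstruments(tab, pThreshold = 5e-6,
                            exclude = "rs002", fMin = 10)
  log <- selectionLog(iset)
  expect_equal(log$n_after[log$step == "select_by_pvalue"], 4L)
  expect_equal(log$n_after[log$step == "exclude"], 3L)
  expect_equal(log$n_after[log$step == "filter_weak"], 2L)
  expect_setequal(instrumentRecords(iset)$snp, c("rs001", "rs003"))
})
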
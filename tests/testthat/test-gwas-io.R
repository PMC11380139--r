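test_that("reading validates rows and logs per-row rejections", {
  tmp <- tempfile(fileext = ".tsv")
  writeLines(c(
    "snp\teffect_allele\tother_allele\teaf\tbeta\tse\tpval\tn",
    "rs1\tA\tG\t0.2\t0.10\t0.02\t1e-8\t5000",
    "rs2\tT\tC\t0.4\t-0.05\t0.01\t1e-6\t5000",
    "rs3\tG\tA\t0.6\t0.20\t0.05\t1e-4\t5000"), tmp)
  tab <- readSummaryStats(tmp, traitId = "x")
  expect_s4_class(tab, "SummaryStats")
  expect_equal(nSnp(tab), 3L)
  expect_equal(nrow(rejectedVariants(tab)), 0L)

  tmp2 <- tempfile(fileext = ".tsv")
  writeLines(c(
    "snp\teffect_allele\tother_allele\teaf\tbeta\tse\tpval\tn",
    "rs1\tA\tG\t0.2\t0.10\t0\t1e-8\t5000",       # se = 0
    "rs2\tT\tC\t0.4\t-0.05\t0.01\t1e-6\t5000",
    "rs3\tG\tA\t0.6\tnot_a_number\t0.05\t1e-4\t5000"), tmp2)
  logPath <- tempfile()
  tab2 <- readSummaryStats(tmp2, traitId = "x", rejectionLog = logPath)
  expect_equal(nSnp(tab2), 1L)
  rej <- rejectedVariants(tab2)
  expect_equal(nrow(rej), 2L)
  expect_setequal(rej$reason, c("se not > 0", "unparseable or missing beta"))
  expect_true(file.exists(logPath))

  # a missing mandatory column is fatal, not a row rejection
  tmp3 <- tempfile(fileext = ".tsv")
  writeLines(c("snp\teffect_allele\tbeta\tse\tpval", "rs1\tA\t0.1\t0.02\t1e-8"),
             tmp3)
  expect_error(readSummaryStats(tmp3), "mandatory")
})

test_that("a custom dialect reads identically to canonical column names", {
  tab <- makeTable(beta = c(0.1, -0.2, 0.05), se = 0.02, traitId = "t1")
  canonical <- tempfile(fileext = ".tsv")
  writeSummaryStats(tab, canonical)
  lines <- readLines(canonical)
  hdr <- strsplit(lines[1], "\t")[[1]]
  map <- c(snp = "SNP", effect_allele = "EA", other_allele = "NEA",
           beta = "b", se = "sebeta", pval = "P")
  hdr[match(names(map), hdr)] <- unname(map)
  renamed <- tempfile(fileext = ".tsv")
  writeLines(c(paste(hdr, collapse = "\t"), lines[-1]), renamed)
  viaDialect <- readSummaryStats(renamed, dialect = map, traitId = "t1")
  expect_equal(variants(viaDialect), variants(tab), tolerance = 0)
  # dialect naming a column absent from the file is a schema error
  expect_error(readSummaryStats(renamed, dialect = c(snp = "nope")), "absent")
})

test_that("write then read is the identity on valid tables", {
  # empty table -> header-only file
  empty <- SummaryStats(data.frame(snp = character(), effect_allele = character(),
                                   other_allele = character(), beta = numeric(),
                                   se = numeric(), pval = numeric()),
                        traitId = "empty")
  f0 <- tempfile(fileext = ".tsv")
  writeSummaryStats(empty, f0)
  expect_length(readLines(f0), 1L)

  # 3 records -> 4 lines
  f1 <- tempfile(fileext = ".tsv")
  writeSummaryStats(makeTable(beta = c(1, 2, 3) / 10, se = 0.02), f1)
  expect_length(readLines(f1), 4L)

  # random 100-record table: field-by-field round-trip identity, also
  # through gzip
  set.seed(42)
  big <- makeTable(beta = rnorm(100) * 10^runif(100, -3, 1),
                   se = exp(rnorm(100, -3, 1)),
                   eaf = runif(100, 0.01, 0.99), traitId = "big")
  for (ext in c(".tsv", ".tsv.gz")) {
    f <- tempfile(fileext = ext)
    writeSummaryStats(big, f)
    back <- readSummaryStats(f, traitId = "big")
    expect_equal(variants(back), variants(big), tolerance = 0)
    expect_equal(nrow(rejectedVariants(back)), 0L)
  }
})

test_that("harmonization aligns, flips and drops as specified", {
  ex <- makeTable(beta = 0.10, se = 0.02, snp = "rs1", ea = "A", oa = "G")
  # same alleles: retained unchanged
  ouSame <- makeTable(beta = 0.05, se = 0.03, snp = "rs1", ea = "A", oa = "G")
  h1 <- harmonize(ex, ouSame)
  expect_equal(harmonizedData(h1)$beta_outcome, 0.05)
  expect_false(harmonizedData(h1)$flipped)

  # swapped alleles: sign flipped
  ouSwap <- makeTable(beta = 0.05, se = 0.03, snp = "rs1", ea = "G", oa = "A",
                      eaf = 0.7)
  h2 <- harmonize(ex, ouSwap)
  expect_equal(harmonizedData(h2)$beta_outcome, -0.05)
  expect_true(harmonizedData(h2)$flipped)

  # strand-complement alleles (T/C vs A/G) align after complementation
  ouStrand <- makeTable(beta = 0.05, se = 0.03, snp = "rs1", ea = "T", oa = "C")
  h3 <- harmonize(ex, ouStrand)
  expect_equal(harmonizedData(h3)$beta_outcome, 0.05)

  # irreconcilable alleles dropped with reason
  ouBad <- makeTable(beta = 0.05, se = 0.03, snp = "rs1", ea = "A", oa = "C")
  h4 <- harmonize(ex, ouBad)
  expect_equal(nSnp(h4), 0L)
  expect_equal(droppedVariants(h4)$reason, "allele_mismatch")

  # empty intersection is fatal
  ouOther <- makeTable(beta = 0.05, se = 0.03, snp = "rs9")
  expect_error(harmonize(ex, ouOther), "no shared instruments")
})

test_that("palindromic variants follow the configured policy", {
  exAmb <- makeTable(beta = 0.1, se = 0.02, snp = "rs1", ea = "A", oa = "T",
                     eaf = 0.50)
  ou <- makeTable(beta = 0.05, se = 0.03, snp = "rs1", ea = "A", oa = "T",
                  eaf = 0.50)
  # ambiguous frequency under infer_by_eaf -> dropped
  hAmb <- harmonize(exAmb, ou, palindromePolicy = "infer_by_eaf")
  expect_equal(nSnp(hAmb), 0L)
  expect_match(droppedVariants(hAmb)$reason, "palindromic")

  # clear frequencies on the same side of 0.5: kept as reported
  exClear <- makeTable(beta = 0.1, se = 0.02, snp = "rs1", ea = "A", oa = "T",
                       eaf = 0.2)
  ouClear <- makeTable(beta = 0.05, se = 0.03, snp = "rs1", ea = "A", oa = "T",
                       eaf = 0.25)
  hClear <- harmonize(exClear, ouClear)
  expect_equal(harmonizedData(hClear)$beta_outcome, 0.05)

  # opposite sides of 0.5: the outcome is on the other strand -> flipped
  ouOpp <- makeTable(beta = 0.05, se = 0.03, snp = "rs1", ea = "A", oa = "T",
                     eaf = 0.8)
  hOpp <- harmonize(exClear, ouOpp)
  expect_equal(harmonizedData(hOpp)$beta_outcome, -0.05)

  # drop policy removes every palindromic variant, keep trusts the report
  expect_equal(nSnp(harmonize(exClear, ouClear, palindromePolicy = "drop")), 0L)
  expect_equal(nSnp(harmonize(exAmb, ou, palindromePolicy = "keep")), 1L)

  # missing frequency cannot be inferred
  exNoEaf <- makeTable(beta = 0.1, se = 0.02, snp = "rs1", ea = "A", oa = "T",
                       eaf = NA_real_)
  expect_equal(nSnp(harmonize(exNoEaf, ouClear)), 0L)
})

test_that("harmonization is an involution and orientation-invariant", {
  for (seed in 1:5) {
    sim <- simulatePair(simConfig(nSnp = 20, theta = 0.2,
                                  palindromicFraction = 0.3, seed = seed))
    h <- harmonize(sim$exposure, sim$outcome)
    # retained + dropped = intersection
    expect_equal(nSnp(h) + nrow(droppedVariants(h)), 20L)

    # harmonizing the already-harmonized pair changes nothing
    tabs <- tablesFromH(h)
    h2 <- harmonize(tabs$exposure, tabs$outcome)
    expect_equal(harmonizedData(h2)$beta_outcome,
                 harmonizedData(h)$beta_outcome)
    expect_equal(harmonizedData(h2)$snp, harmonizedData(h)$snp)
    expect_false(any(harmonizedData(h2)$flipped))

    # flipping outcome alleles, beta sign and eaf is a pure re-orientation:
    # the harmonized effects are unchanged
    ov <- variants(sim$outcome)
    flipped <- ov
    flipped$effect_allele <- ov$other_allele
    flipped$other_allele <- ov$effect_allele
    flipped$beta <- -ov$beta
    flipped$eaf <- 1 - ov$eaf
    ouFlip <- SummaryStats(flipped, traitId = "sim_outcome")
    hf <- harmonize(sim$exposure, ouFlip)
    expect_equal(harmonizedData(hf)$snp, harmonizedData(h)$snp)
    expect_equal(harmonizedData(hf)$beta_outcome,
                 harmonizedData(h)$beta_outcome)
    expect_equal(harmonizedData(hf)$eaf, harmonizedData(h)$eaf)
  }
})
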
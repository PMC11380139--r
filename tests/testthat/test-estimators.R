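test_that("Wald ratio point estimate and first-order SE", {
  r <- waldRatio(bx = 0.1, by = 0.2, sy = 0.05)
  expect_equal(mrBeta(r), 2.0)
  expect_equal(mrSE(r), 0.5)
  expect_equal(oddsRatio(r), exp(2))

  r0 <- waldRatio(bx = 0.1, by = 0, sy = 0.05)
  expect_equal(mrBeta(r0), 0)
  expect_equal(oddsRatio(r0), 1)

  expect_error(waldRatio(bx = 0, by = 0.2, sy = 0.05), "null instrument")

  # first-order SE tracks the numeric delta-method oracle in the
  # strong-instrument regime (sx/|bx| < 0.1, sy not tiny)
  set.seed(11)
  for (i in 1:100) {
    bx <- sample(c(-1, 1), 1) * runif(1, 0.5, 1)
    by <- runif(1, -1, 1)
    sx <- runif(1, 0.01, 0.02)
    sy <- runif(1, 0.1, 0.2)
    first <- mrSE(waldRatio(bx, by, sx, sy))
    full <- ratioSEOracle(bx, by, sx, sy)
    expect_lte(first, full + 1e-12)
    expect_lt(abs(first - full) / full, 0.1)
    # the second-order option matches the oracle tightly
    second <- mrSE(waldRatio(bx, by, sx, sy, secondOrder = TRUE))
    expect_equal(second, full, tolerance = 1e-6)
  }
})

test_that("IVW reproduces hand arithmetic and degenerate cases", {
  # unit weights, ratios 1 and 3 -> beta 2, fixed se sqrt(1/2)
  h <- makeH(bx = c(1, 1), by = c(1, 3), sy = 1)
  r <- mrIVW(h, mode = "fixed")
  expect_equal(mrBeta(r), 2)
  expect_equal(mrSE(r), sqrt(1 / 2))

  # identical ratios: beta equals the ratio, Q = 0, random equals fixed
  h2 <- makeH(bx = c(0.5, 1, 2), by = 0.7 * c(0.5, 1, 2), sy = c(1, 2, 1))
  rf <- mrIVW(h2, mode = "fixed")
  rr <- mrIVW(h2, mode = "random")
  expect_equal(mrBeta(rf), 0.7, tolerance = 1e-12)
  expect_equal(mrExtras(rf)$Q, 0, tolerance = 1e-20)
  expect_equal(mrSE(rr), mrSE(rf))

  expect_error(mrIVW(makeH(1, 1, 1)), "waldRatio")
  expect_error(mrIVW(makeH(c(0, 1), c(1, 1), 1)), "null instrument")
})

test_that("IVW equals the closed-form WLS oracle on random instances", {
  for (seed in 1:50) {
    h <- randomH(J = sample(4:15, 1), seed = seed)
    d <- harmonizedData(h)
    w <- 1 / d$se_outcome^2
    orc <- wlsOracle(matrix(d$beta_exposure, ncol = 1), d$beta_outcome, w)
    r <- mrIVW(h, mode = "fixed")
    expect_equal(mrBeta(r), unname(orc$coef), tolerance = 1e-10)
    expect_equal(mrSE(r), sqrt(orc$covUnscaled[1, 1]), tolerance = 1e-10)
    # dual route: stats::lm agrees too
    fit <- lm(beta_outcome ~ 0 + beta_exposure, data = d, weights = w)
    expect_equal(mrBeta(r), unname(coef(fit)), tolerance = 1e-10)
  }
})

test_that("the automatic fixed/random switch keys on the Q p-value", {
  hHet <- makeH(bx = rep(1, 5), by = c(0, 1, 2, 3, 8), sy = 0.1)
  rAuto <- mrIVW(hHet, mode = "auto")
  expect_equal(mrExtras(rAuto)$mode_used, "random")
  expect_lt(mrExtras(rAuto)$Q_pval, 0.05)
  expect_equal(mrSE(rAuto), mrSE(mrIVW(hHet, mode = "random")))

  hHom <- makeH(bx = rep(1, 5), by = rep(2, 5) + c(-1, 1, 0, -1, 1) * 0.01,
                sy = 1)
  rAuto2 <- mrIVW(hHom, mode = "auto")
  expect_equal(mrExtras(rAuto2)$mode_used, "fixed")
})

test_that("Egger recovers an exact line and matches the WLS oracle", {
  # noise-free by = 0.5 + 1.0 * bx
  h <- makeH(bx = c(1, 2, 3), by = 0.5 + 1.0 * c(1, 2, 3), sy = 1)
  r <- mrEgger(h)
  expect_equal(mrBeta(r), 1.0, tolerance = 1e-10)
  expect_equal(mrExtras(r)$intercept, 0.5, tolerance = 1e-10)

  for (seed in 1:50) {
    h <- randomH(J = sample(5:15, 1), seed = seed + 100)
    d <- harmonizedData(h)
    flip <- d$beta_exposure < 0
    bx <- abs(d$beta_exposure)
    by <- ifelse(flip, -d$beta_outcome, d$beta_outcome)
    w <- 1 / d$se_outcome^2
    orc <- wlsOracle(cbind(1, bx), by, w)
    r <- mrEgger(h)
    expect_equal(mrExtras(r)$intercept, unname(orc$coef[1]),
                 tolerance = 1e-10)
    expect_equal(mrBeta(r), unname(orc$coef[2]), tolerance = 1e-10)
    # SEs carry the floored overdispersion on the oracle's unscaled cov
    res <- by - orc$coef[1] - orc$coef[2] * bx
    phi <- max(1, sum(w * res^2) / (nrow(d) - 2))
    expect_equal(mrSE(r), sqrt(orc$covUnscaled[2, 2] * phi),
                 tolerance = 1e-10)
  }
  expect_error(mrEgger(makeH(c(1, 2), c(1, 2), 1)), ">= 3")
})

test_that("Egger with the intercept pinned at zero is IVW fixed", {
  h <- randomH(J = 8, seed = 5)
  d <- harmonizedData(h)
  flip <- d$beta_exposure < 0
  fit <- lm(I(ifelse(flip, -1, 1) * beta_outcome) ~
              0 + I(abs(beta_exposure)),
            data = d, weights = 1 / d$se_outcome^2)
  expect_equal(unname(coef(fit)), mrBeta(mrIVW(h, mode = "fixed")),
               tolerance = 1e-12)
})

test_that("weighted median matches hand cases and the scan oracle", {
  # equal weights, ratios {1, 2, 9} -> 2
  h <- makeH(bx = c(1, 1, 1), by = c(1, 2, 9), sy = 1)
  expect_equal(mrBeta(mrWeightedMedian(h, nBoot = 50, seed = 1)), 2)

  # dominant weight pulls the estimate toward its ratio
  w <- c(0.9, 0.05, 0.05)
  hDom <- makeH(bx = c(1, 1, 1), by = c(1, 5, 9), sy = 1 / sqrt(w))
  bDom <- mrBeta(mrWeightedMedian(hDom, nBoot = 50, seed = 1))
  expect_lt(bDom, 5)
  expect_lt(abs(bDom - 1), 1.5)

  # equal weights, odd J: exactly the sample median
  set.seed(21)
  ratios <- rnorm(7)
  hOdd <- makeH(bx = rep(1, 7), by = ratios, sy = 1)
  expect_identical(mrBeta(mrWeightedMedian(hOdd, nBoot = 50, seed = 1)),
                   median(ratios))

  # percentile-scan oracle on random instances
  for (seed in 1:100) {
    h <- randomH(J = sample(3:12, 1), seed = seed + 300)
    d <- harmonizedData(h)
    theta <- d$beta_outcome / d$beta_exposure
    w <- d$beta_exposure^2 / d$se_outcome^2
    expect_equal(mrBeta(mrWeightedMedian(h, nBoot = 2, seed = 1)),
                 wmedianOracle(theta, w), tolerance = 1e-12)
  }
  expect_error(mrWeightedMedian(h, nBoot = 0), "positive")
})

test_that("weighted mode finds the dominant cluster", {
  # three of four ratios agree at 1
  h <- makeH(bx = rep(1, 4), by = c(1, 1, 1, 5), sy = 1)
  expect_lt(abs(mrBeta(mrWeightedMode(h, nBoot = 50, seed = 1)) - 1), 0.05)

  # a single tight cluster returns its center
  set.seed(4)
  center <- 2
  hTight <- makeH(bx = rep(1, 5), by = center + rnorm(5, 0, 1e-9), sy = 1)
  expect_lt(abs(mrBeta(mrWeightedMode(hTight, nBoot = 50, seed = 1)) - center),
            1e-6)

  # argmax agrees with a fine-grid brute-force scan of the same kernel sum
  for (seed in 1:20) {
    h <- randomH(J = sample(5:12, 1), seed = seed + 500)
    d <- harmonizedData(h)
    theta <- d$beta_outcome / d$beta_exposure
    w <- d$beta_exposure^2 / d$se_outcome^2
    wn <- w / sum(w)
    iqr <- IQR(theta) / 1.349
    spread <- min(sd(theta), if (iqr > 0) iqr else sd(theta))
    bw <- 0.9 * spread / length(theta)^0.2
    grid <- seq(min(theta) - 3 * bw, max(theta) + 3 * bw, length.out = 20001)
    dens <- vapply(grid, function(x) sum(wn * dnorm(x, theta, bw)),
                   numeric(1))
    step <- diff(grid[1:2])
    expect_lt(abs(mrBeta(mrWeightedMode(h, nBoot = 2, seed = 1)) -
                    grid[which.max(dens)]), step * 2)
  }
  expect_error(mrWeightedMode(h, phi = 0), "phi")
})

test_that("estimates react correctly to sign flips of the inputs", {
  h <- randomH(J = 9, seed = 77)
  d <- harmonizedData(h)
  negOutcome <- makeH(d$beta_exposure, -d$beta_outcome, d$se_outcome,
                      d$se_exposure)
  bothFlipped <- makeH(-d$beta_exposure, -d$beta_outcome, d$se_outcome,
                       d$se_exposure)
  run <- function(hh) list(
    ivw = mrIVW(hh, mode = "fixed"),
    egger = mrEgger(hh),
    wm = mrWeightedMedian(hh, nBoot = 200, seed = 3),
    mode = mrWeightedMode(hh, nBoot = 200, seed = 3))
  base <- run(h); neg <- run(negOutcome); both <- run(bothFlipped)
  for (nm in names(base)) {
    # negating the outcome effects negates the estimate; the SE is unchanged
    # (exactly for the analytic SEs, up to resampling noise for the
    # bootstrap ones)
    expect_equal(mrBeta(neg[[nm]]), -mrBeta(base[[nm]]), tolerance = 1e-8)
    tolSE <- if (nm %in% c("ivw", "egger")) 1e-10 else 0.2 * mrSE(base[[nm]])
    expect_lt(abs(mrSE(neg[[nm]]) - mrSE(base[[nm]])), tolSE + 1e-12)
    # jointly flipping both betas is allele re-orientation: invariant
    expect_equal(mrBeta(both[[nm]]), mrBeta(base[[nm]]), tolerance = 1e-8)
  }
})

test_that("odds-ratio reporting matches normal theory and printed precision", {
  o <- orCI(0, 0.1)
  expect_equal(o$or, 1)
  expect_equal(o$ci_low, exp(-qnorm(0.975) * 0.1), tolerance = 1e-12)
  expect_equal(round(o$ci_low, 3), 0.822)
  expect_equal(round(o$ci_high, 3), 1.217)

  # a published OR of 2.055 with CI 1.260-3.352 back-derives p = 0.004
  se <- (log(3.352) - log(1.260)) / (2 * qnorm(0.975))
  o2 <- orCI(log(2.055), se)
  expect_equal(round(o2$pval, 3), 0.004)

  # CI width is monotone increasing in se
  widths <- vapply(seq(0.05, 1, by = 0.05),
                   function(s) { oo <- orCI(0.3, s); oo$ci_high - oo$ci_low },
                   numeric(1))
  expect_true(all(diff(widths) > 0))
  expect_error(orCI(0.1, 0.1, level = 1.2))
})

test_that("the method battery flags direction consistency", {
  sim <- simulatePair(simConfig(nSnp = 15, theta = 0.4, seed = 8,
                                palindromicFraction = 0))
  h <- harmonize(sim$exposure, sim$outcome)
  res <- mrAllMethods(h, nBoot = 100, seed = 2)
  expect_named(res, c("ivw_auto", "egger", "weighted_median", "weighted_mode"))
  expect_true(attr(res, "direction_consistent"))
  expect_true(all(vapply(res, function(r) mrBeta(r) > 0, logical(1))))
})
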
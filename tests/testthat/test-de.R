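test_that("the df = 3 spline design matches its boundary behavior and an
           independent de Boor oracle", {
  b <- buildSplineBasis(c(0, 12, 24, 48, 96))
  expect_equal(unname(b$basis[1, ]), c(0, 0, 0))
  expect_equal(unname(b$basis[5, ]), c(0, 0, 1))
  expect_true(all(b$basis >= 0 & b$basis <= 1))
  # oracle: splines::bs with the same boundary knots and df
  ts <- c(0, 7, 12, 24, 48, 48.5, 77, 96)
  oracle <- unclass(splines::bs(ts, df = 3, Boundary.knots = c(0, 96)))
  mine <- buildSplineBasis(ts)$basis
  expect_lt(max(abs(mine - oracle)), 1e-10)
  expect_error(buildSplineBasis(c(0, 100)), "within")
})

test_that("the rich P-spline basis matches splines::splineDesign", {
  ts <- sort(runif(20, 0, 96))
  ps <- psplineBasis(c(0, ts, 96), nInterior = 5)
  oracle <- splines::splineDesign(ps$knots, c(0, ts, 96), ord = 4)
  expect_lt(max(abs(ps$basis - oracle)), 1e-10)
})

test_that("median-of-ratios size factors obey their closed forms", {
  m <- tinyCounts()  # columns are proportional: 10,30 | 20,60
  expect_equal(unname(computeSizeFactors(m)), c(sqrt(0.5), sqrt(2)),
               tolerance = 1e-12)
  same <- cbind(a = c(5L, 9L), b = c(5L, 9L), c = c(5L, 9L))
  rownames(same) <- c("g1", "g2")
  expect_equal(unname(computeSizeFactors(same)), c(1, 1, 1))
  # scaling one sample's column by c multiplies its factor relative to the
  # others by c (the per-gene geometric means rescale all factors jointly)
  m2 <- m; m2[, 2] <- m2[, 2] * 3L
  sf1 <- computeSizeFactors(m); sf2 <- computeSizeFactors(m2)
  expect_equal(sf2[["s2"]] / sf2[["s1"]], 3 * sf1[["s2"]] / sf1[["s1"]],
               tolerance = 1e-12)
  zero <- matrix(c(0L, 1L, 2L, 0L), 2, 2,
                 dimnames = list(c("g1", "g2"), c("s1", "s2")))
  expect_error(computeSizeFactors(zero), "filter")
})

test_that("the variance-stabilizing transform is the documented log2 map", {
  m <- matrix(c(0L, 1023L, 7L, 3L), 2, 2,
              dimnames = list(c("g1", "g2"), c("s1", "s2")))
  v <- vstCounts(m)
  expect_equal(v["g1", "s1"], 0)
  expect_equal(v["g2", "s1"], 10)
  expect_true(all(diff(vstCounts(matrix(0:50, ncol = 1))) > 0))
  expect_equal(vstCounts(m, sf = c(2, 2)), log2(m / 2 + 1))
})

test_that("BH adjustment matches the step-up definition and p.adjust", {
  expect_equal(bhAdjust(c(0.01, 0.02, 0.03)), rep(0.03, 3))
  expect_equal(bhAdjust(0.4), 0.4)
  set.seed(1)
  for (i in 1:5) {
    p <- runif(50)^2
    expect_equal(bhAdjust(p), p.adjust(p, "BH"), tolerance = 1e-14)
    perm <- sample(50)
    expect_equal(bhAdjust(p)[perm], bhAdjust(p[perm]))
  }
  expect_error(bhAdjust(c(0.5, 1.2)), "\\[0, 1\\]")
})

test_that("the NB GLM recovers closed forms and limiting cases", {
  set.seed(42)
  # constant design: intercept is the log mean of normalized counts
  y <- rnbinom(60, mu = 50, size = 5)
  f <- fitNbGlm(y, matrix(1, 60, 1))
  expect_equal(unname(f$coefficients), log(mean(y)), tolerance = 1e-6)
  expect_true(f$converged)
  # Poisson data drive the dispersion estimate to the floor
  yp <- rpois(100, 40)
  fp <- fitNbGlm(yp, matrix(1, 100, 1))
  expect_lte(fp$alpha, 0.01)
  # planted (mu, alpha) recovered within 10% at n = 500
  y5 <- rnbinom(500, mu = 100, size = 1 / 0.2)
  f5 <- fitNbGlm(y5, matrix(1, 500, 1))
  expect_lt(abs(exp(f5$coefficients) - 100) / 100, 0.1)
  expect_lt(abs(f5$alpha - 0.2) / 0.2, 0.35)
  expect_error(fitNbGlm(y, cbind(1, 1)), "rank")
})

test_that("NB log-likelihoods agree with a glm.nb-style oracle and the LRT
           is invariant to rescaled size factors", {
  set.seed(7)
  n <- 48
  x <- rnorm(n)
  X <- cbind(1, x)
  mu <- exp(3 + 0.8 * x)
  y <- rnbinom(n, mu = mu, size = 4)
  f <- fitNbGlm(y, X, alpha = 0.25)
  oracle <- suppressWarnings(
    glm(y ~ x, family = MASS::negative.binomial(theta = 1 / 0.25)))
  expect_equal(unname(f$coefficients), unname(coef(oracle)), tolerance = 1e-5)
  # identical full and reduced designs give a zero statistic
  f2 <- fitNbGlm(y, X, alpha = 0.25)
  expect_equal(2 * (f$logLik - f2$logLik), 0)
  # statistic invariant to multiplying all size factors by a constant
  sf <- runif(n, 0.5, 2)
  full <- fitNbGlm(y, X, sf = sf)
  red <- fitNbGlm(y, X[, 1, drop = FALSE], sf = sf, alpha = full$alpha)
  stat1 <- 2 * (full$logLik - red$logLik)
  full2 <- fitNbGlm(y, X, sf = 5 * sf, alpha = full$alpha)
  red2 <- fitNbGlm(y, X[, 1, drop = FALSE], sf = 5 * sf, alpha = full$alpha)
  expect_equal(stat1, 2 * (full2$logLik - red2$logLik), tolerance = 1e-6)
})

test_that("lrtContrast tests the documented designs and flags bad input", {
  sim <- simulateExperiment(simulationSpec(nGenes = 50, seed = 3,
                                           fracInteractionDegs = 0.2))
  res <- lrtContrast(sim$experiment, "RB_time")
  tab <- resultsTable(res)
  expect_equal(nrow(tab), 50)
  expect_true(all(tab$df[!is.na(tab$df)] == 3))
  expect_true(all(tab$stat[!is.na(tab$stat)] >= 0))
  expect_true(all(tab$padj >= tab$pvalue, na.rm = TRUE))
  # genes below the count floor are excluded from testing but reported
  cts <- counts(sim$experiment)
  cts[1, ] <- 0L
  pe2 <- PhaseExperiment(cts, sampleInfo(sim$experiment))
  tab2 <- resultsTable(lrtContrast(pe2, "RB_time"))
  expect_true(is.na(tab2$pvalue[1]))
  # degenerate design: a single shared time level
  md <- sampleInfo(sim$experiment)
  md$time_h <- 0
  expect_error(lrtContrast(PhaseExperiment(counts(sim$experiment), md),
                           "interaction"),
               "rank deficient")
})

test_that("per-transition DEG hits concentrate in the dynamic transition", {
  sim <- simulateExperiment(simulationSpec(nGenes = 120, seed = 13,
                                           fracInteractionDegs = 0.5))
  rb <- resultsTable(lrtContrast(sim$experiment, "RB_time"))
  dynRB <- sim$truth$clusterRB > 0
  hit <- !is.na(rb$padj) & rb$padj < 0.05
  expect_gt(mean(hit[dynRB]), 0.8)
  expect_lt(mean(hit[!dynRB & !sim$truth$isDeg]), 0.15)
})

test_that("set-overlap summaries reproduce the published arithmetic", {
  A <- paste0("g", 1:2043)
  B <- c(paste0("g", 1:185), paste0("x", 1:441))
  ov <- degOverlap(A, B)
  expect_equal(ov$nUnion, 2484)
  expect_equal(ov$percentShared, 7.4)
  expect_equal(degOverlap(A, A)$percentShared, 100)
  expect_equal(degOverlap(A, paste0("z", 1:5))$percentShared, 0)
  expect_equal(degOverlap(character(0), character(0))$percentShared, 0)
})
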
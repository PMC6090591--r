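times5 <- c(0, 12, 24, 48, 96)

# well-separated planted trajectory groups around `shapes` (rows), `n` genes
# per group, Gaussian noise
plantedTrajectories <- function(shapes, n = 50, noise = 0.5, seed = 1) {
  set.seed(seed)
  Y <- do.call(rbind, lapply(seq_len(nrow(shapes)), function(k)
    matrix(rep(shapes[k, ], each = n), n) +
      matrix(rnorm(n * ncol(shapes), 0, noise), n)))
  rownames(Y) <- paste0("g", seq_len(nrow(Y)))
  colnames(Y) <- colnames(shapes)
  list(Y = Y, truth = rep(seq_len(nrow(shapes)), each = n))
}

test_that("the single-component fit solves the penalized criterion", {
  sim <- plantedTrajectories(matrix(c(5, 6, 7, 7.5, 8), 1), n = 40, seed = 3)
  fit <- fitPsplineMixture(sim$Y, times5, K = 1, lambda = 2, seed = 1)
  # oracle: numeric minimizer of the criterion at the converged variances
  ps <- psplineBasis(times5, 5)
  A <- diag(5) / fit@sigma2 -
    (fit@tau2 / (fit@sigma2 * (fit@sigma2 + 5 * fit@tau2))) * matrix(1, 5, 5)
  crit <- function(th) {
    r <- sweep(sim$Y, 2, drop(ps$basis %*% th))
    sum(diag(r %*% A %*% t(r))) + 2 * drop(th %*% ps$penalty %*% th)
  }
  opt <- optim(fit@coefficients[, 1], crit, method = "BFGS",
               control = list(maxit = 500, reltol = 1e-14))
  expect_lt(max(abs(drop(ps$basis %*% opt$par) -
                      drop(ps$basis %*% fit@coefficients[, 1]))), 1e-4)
})

test_that("well-separated trajectory groups are recovered and the EM
           objective is monotone", {
  shapes <- rbind(c(4, 4, 4, 4, 4), c(8, 8, 8, 8, 8))
  sim <- plantedTrajectories(shapes, n = 60, noise = 0.5, seed = 5)
  fit <- fitPsplineMixture(sim$Y, times5, K = 2, seed = 2)
  expect_true(fit@converged)
  expect_true(all(diff(fit@objective) >= -1e-6))
  lab <- clusterLabels(hardAssignment(fit, sim$Y))
  expect_gte(mclust::adjustedRandIndex(lab, sim$truth), 0.95)
  # responsibilities stay a valid simplex
  expect_true(all(abs(rowSums(responsibilities(fit)) - 1) < 1e-8))
  # label structure is seed-stable up to permutation
  lab2 <- clusterLabels(hardAssignment(
    fitPsplineMixture(sim$Y, times5, K = 2, seed = 77), sim$Y))
  expect_gte(mclust::adjustedRandIndex(lab, lab2), 0.95)
})

test_that("the BIC scan is deterministic and prefers the planted K", {
  shapes <- rbind(c(4, 4, 4, 4, 4), c(8, 8, 8, 8, 8),
                  c(4, 8, 8, 8, 8), c(8, 8, 8, 8, 4))
  sim <- plantedTrajectories(shapes, n = 40, noise = 0.5, seed = 6)
  scan <- bicScan(sim$Y, times5, Ks = c(2, 4, 6), seed = 3)
  expect_equal(nrow(scan$table), 3)
  expect_lt(scan$table$bic[scan$table$K == 4],
            scan$table$bic[scan$table$K == 2])
  scan2 <- bicScan(sim$Y, times5, Ks = c(2, 4, 6), seed = 3)
  expect_identical(scan$table, scan2$table)
  expect_error(bicScan(sim$Y, times5, Ks = 1000), "exceed")
})

test_that("the plateau rule selects the documented K", {
  tab <- function(b) data.frame(K = seq(2, by = 2, length.out = length(b)),
                                bic = b)
  # decreasing then flat: first K on the flat region
  expect_equal(selectK(tab(c(100, 80, 60, 50, 50.01, 49.99))), 8)
  # strictly increasing: the first entry wins
  expect_equal(selectK(tab(c(10, 20, 30))), 2)
  # a near-minimum that precedes a higher value is skipped
  expect_equal(selectK(tab(c(100, 50, 49.9, 60, 49.8, 49.8))), 10)
})

test_that("maximum change vectors match their definition and tie rules", {
  m <- computeMcv(c(10, 12, 20, 19, 18), times5)
  expect_equal(m$interval, "12-24")
  expect_equal(m$magnitude, 8)
  expect_equal(m$direction, "+")
  flat <- computeMcv(c(3, 3, 3, 3, 3), times5)
  expect_equal(flat$interval, "0-12")
  expect_equal(flat$magnitude, 0)
  expect_equal(flat$direction, "+")
  expect_error(computeMcv(5), "at least 2")
  # brute-force oracle, including forced ties
  set.seed(9)
  for (i in 1:200) {
    y <- round(rnorm(5, 0, 2), 1)
    d <- diff(y)
    best <- which(abs(d) == max(abs(d)))[1]
    m <- computeMcv(y, times5)
    expect_equal(m$intervalIndex, best)
    expect_equal(m$magnitude, abs(d[best]))
    expect_equal(m$direction, if (d[best] < 0) "-" else "+")
  }
})

test_that("fitted cluster-mean MCVs agree with member-average MCVs", {
  shapes <- rbind(c(4, 4, 4, 8, 8), c(9, 5, 5, 5, 5))
  sim <- plantedTrajectories(shapes, n = 60, noise = 0.3, seed = 8)
  fit <- fitPsplineMixture(sim$Y, times5, K = 2, seed = 2)
  asg <- hardAssignment(fit, sim$Y)
  fittedMcv <- clusterMcvs(asg)
  for (k in 1:2) {
    avg <- colMeans(sim$Y[clusterLabels(asg) == k, ])
    memberMcv <- computeMcv(avg, times5)
    expect_equal(fittedMcv[k, "interval"], memberMcv$interval)
    expect_equal(fittedMcv[k, "direction"], memberMcv$direction)
    expect_equal(fittedMcv[k, "magnitude"], memberMcv$magnitude,
                 tolerance = 0.15)
  }
  # MCV is linear under scaling of a trajectory
  y <- c(1, 4, 2, 6, 3)
  expect_equal(computeMcv(3 * y, times5)$magnitude,
               3 * computeMcv(y, times5)$magnitude)
})

test_that("interval gene counts conserve cluster sizes", {
  lab <- setNames(rep(1:3, c(50, 30, 20)), paste0("g", 1:100))
  means <- rbind(c(0, 0, 0, 0, 5), c(0, 4, 4, 4, 4), c(1, 1, 1, 1, 1))
  colnames(means) <- times5
  asg <- new("ClusterAssignment", labels = lab, means = means,
             times = times5, K = 3L, transition = "RB")
  mcvs <- clusterMcvs(asg)
  ic <- intervalGeneCounts(asg, mcvs, enrichedClusters = 1)
  expect_equal(unname(ic), c(0, 0, 0, 50))
  expect_equal(sum(intervalGeneCounts(asg, mcvs, integer(0))), 0)
  # conservation under random enrichment subsets
  set.seed(11)
  for (i in 1:10) {
    enr <- sample(1:3, sample(1:3, 1))
    expect_equal(sum(intervalGeneCounts(asg, mcvs, enr)),
                 sum(table(lab)[as.character(enr)]))
  }
  expect_error(intervalGeneCounts(asg, mcvs[1:2, ], enrichedClusters = 3),
               "missing")
})

test_that("MCV concordance reproduces the published 55.7% arithmetic", {
  genes <- paste0("g", 1:185)
  mA <- data.frame(interval = rep("0-12", 185), direction = rep("+", 185),
                   row.names = genes)
  mB <- mA
  mB$direction[104:185] <- "-"     # 103 of 185 concordant
  expect_equal(mcvConcordance(mA, mB)$percentSame, 55.7)
})

test_that("the chi-square homogeneity test matches the contingency oracle", {
  same <- chi2Homogeneity(c(5, 10, 15), c(5, 10, 15))
  expect_equal(same$statistic, 0)
  expect_equal(same$pvalue, 1)
  hand <- chi2Homogeneity(c(30, 10), c(10, 30))
  expect_equal(hand$statistic, 20)
  expect_equal(hand$df, 1)
  set.seed(14)
  for (i in 1:25) {
    a <- rpois(4, 20) + 1
    b <- rpois(4, 20) + 1
    mine <- chi2Homogeneity(a, b)
    oracle <- suppressWarnings(chisq.test(rbind(a, b), correct = FALSE))
    expect_equal(mine$statistic, unname(oracle$statistic), tolerance = 1e-9)
    expect_equal(mine$pvalue, oracle$p.value, tolerance = 1e-9)
  }
  expect_warning(dropped <- chi2Homogeneity(c(5, 0, 10), c(5, 0, 10)), "zero")
  expect_equal(dropped$df, 1)
  expect_error(chi2Homogeneity(c(0, 0), c(5, 5)), "all zeros")
})
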
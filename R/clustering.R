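# P-spline mixed-effects mixture clustering of expression trajectories.
# Genes x time mean trajectories are modeled as a K-component mixture of
# penalized-spline mean curves with a per-gene random intercept (variance
# tau2) and i.i.d. Gaussian noise (variance sigma2); fitting is by EM with
# k-means++ style initialization, the smoothing weight lambda is chosen once
# by GCV on the single-component fit and held fixed across K so BIC scans
# stay comparable.

.kmeansppCenters <- function(Y, K) {
  n <- nrow(Y)
  centers <- integer(K)
  centers[1L] <- sample.int(n, 1L)
  d2 <- rowSums(sweep(Y, 2, Y[centers[1L], ])^2)
  for (k in seq_len(K)[-1L]) {
    p <- if (sum(d2) > 0) d2 / sum(d2) else rep(1 / n, n)
    centers[k] <- sample.int(n, 1L, prob = p)
    d2 <- pmin(d2, rowSums(sweep(Y, 2, Y[centers[k], ])^2))
  }
  centers
}

# log density of rows of E under N(0, sigma2 I + tau2 J)
.csLogDens <- function(E, sigma2, tau2) {
  T0 <- ncol(E)
  c2 <- sigma2 + T0 * tau2
  qf <- rowSums(E^2) / sigma2 -
    (tau2 / (sigma2 * c2)) * rowSums(E)^2
  -0.5 * (T0 * log(2 * pi) + (T0 - 1) * log(sigma2) + log(c2) + qf)
}

.csInverse <- function(T0, sigma2, tau2) {
  diag(T0) / sigma2 - (tau2 / (sigma2 * (sigma2 + T0 * tau2))) *
    matrix(1, T0, T0)
}

#' Choose the P-spline penalty by generalized cross-validation
#'
#' GCV on the single-component (K = 1) fit: all gene trajectories are stacked
#' around one penalized mean curve, and `RSS * nT / (nT - edf)^2` is scanned
#' over a log-spaced grid. Held fixed across K so BIC scans stay comparable.
#'
#' @param Y genes x times trajectory matrix.
#' @param times design times.
#' @param grid candidate penalties (default `10^seq(-2, 4, length.out = 13)`).
#' @param nInterior interior knots of the basis (default 5).
#' @return the GCV-minimizing penalty.
#' @export
selectLambda <- function(Y, times, grid = 10^seq(-2, 4, length.out = 13),
                         nInterior = 5L) {
  bs <- psplineBasis(times, nInterior)
  B <- bs$basis; P <- bs$penalty
  n <- nrow(Y); T0 <- ncol(Y); ybar <- colMeans(Y)
  gcv <- vapply(grid, function(l) {
    M <- solve(n * crossprod(B) + l * P, n * crossprod(B))
    fhat <- drop(B %*% solve(n * crossprod(B) + l * P,
                             n * crossprod(B, ybar)))
    rss <- sum(sweep(Y, 2, fhat)^2)
    edf <- sum(diag(M))
    n * T0 * rss / (n * T0 - edf)^2
  }, numeric(1))
  grid[which.min(gcv)]
}

#' Fit a P-spline mixture to gene expression trajectories
#'
#' EM algorithm: E-step responsibilities from Gaussian densities of whole
#' trajectories around cluster spline mean curves with compound-symmetric
#' covariance (residual variance plus gene random-intercept variance);
#' M-step penalized weighted least squares for the spline coefficients with
#' second-difference penalty `lambda`, followed by closed-form variance and
#' mixing-proportion updates. Convergence when the penalized objective
#' changes by less than `tol`; deterministic for a fixed `seed` (k-means++
#' style initialization on the trajectories). An emptied component is
#' re-initialized once, then the fit fails with a diagnostic.
#'
#' @param Y genes x times matrix of mean trajectories (VST units).
#' @param times design times (hours), one per column of `Y`.
#' @param K number of mixture components (>= 1, at most `nrow(Y)`).
#' @param lambda second-difference penalty weight. The default 1 is a light
#'   regularization: with few design times and a rich basis the penalty's job
#'   is to pin down the excess basis dimensions, not to smooth away timing
#'   signal (heavy smoothing relocates maximum changes into the widest
#'   interval). [selectLambda()] offers a GCV-based alternative.
#' @param seed RNG seed for initialization. Each of the `nStarts` restarts
#'   derives its own stream from it, so fits are reproducible end to end.
#' @param nInterior interior knots of the shared cubic basis (default 5).
#' @param maxIter maximum EM iterations (default 200).
#' @param tol convergence tolerance on the objective (default 1e-6).
#' @param nStarts independent EM restarts; the fit with the best final
#'   objective wins (default 5, guarding against local optima).
#' @return a [PSplineMixture-class].
#' @export
fitPsplineMixture <- function(Y, times, K, lambda = 1, seed = 1L,
                              nInterior = 5L, maxIter = 200L, tol = 1e-6,
                              nStarts = 5L) {
  best <- NULL
  for (s in seq_len(max(1L, nStarts))) {
    fit <- tryCatch(
      .fitPsplineMixtureOnce(Y, times, K, lambda = lambda,
                             seed = seed + 997L * (s - 1L),
                             nInterior = nInterior, maxIter = maxIter,
                             tol = tol),
      error = function(e) e)
    if (inherits(fit, "error")) {
      if (s == nStarts && is.null(best)) stop(conditionMessage(fit))
      next
    }
    if (is.null(best) ||
        fit@objective[length(fit@objective)] >
          best@objective[length(best@objective)])
      best <- fit
  }
  best
}

.fitPsplineMixtureOnce <- function(Y, times, K, lambda, seed, nInterior,
                                   maxIter, tol) {
  Y <- as.matrix(Y)
  n <- nrow(Y); T0 <- ncol(Y)
  if (K < 1L || K > n) stop("K must lie in [1, number of genes]")
  if (length(times) != T0) stop("times must match the columns of Y")
  bs <- psplineBasis(times, nInterior)
  B <- bs$basis; P <- bs$penalty; m <- ncol(B)

  set.seed(seed)
  centers <- .kmeansppCenters(Y, K)
  d2 <- vapply(centers, function(cc) rowSums(sweep(Y, 2, Y[cc, ])^2),
               numeric(n))
  hard <- max.col(-matrix(d2, n, K))
  R <- matrix(1e-6, n, K)
  R[cbind(seq_len(n), hard)] <- 1
  R <- R / rowSums(R)

  sigma2 <- max(mean(apply(Y, 1, var)), 1e-4)
  tau2 <- 0.1 * sigma2
  pi_k <- pmax(colMeans(R), 1e-8); pi_k <- pi_k / sum(pi_k)
  theta <- matrix(0, m, K)
  reinit_used <- logical(K)

  objective <- numeric(0)
  converged <- FALSE
  ll <- NA_real_
  for (iter in seq_len(maxIter)) {
    # M-step: spline coefficients under the current covariance
    A <- .csInverse(T0, sigma2, tau2)
    BAB <- t(B) %*% A %*% B
    nk <- colSums(R)
    for (k in seq_len(K)) {
      if (nk[k] < 1e-8) {
        if (reinit_used[k])
          stop("component ", k, " emptied twice during EM; ",
               "reduce K or change the seed")
        reinit_used[k] <- TRUE
        g <- sample.int(n, 1L)
        R[, k] <- 1e-3; R[g, k] <- 1
        R <- R / rowSums(R)
        nk <- colSums(R)
      }
      ybark <- colSums(R[, k] * Y) / nk[k]
      theta[, k] <- solve(nk[k] * BAB + lambda * P,
                          nk[k] * t(B) %*% A %*% ybark)
    }
    mu_k <- B %*% theta                      # T0 x K cluster mean curves

    # variance and proportion updates from responsibility-weighted residuals
    Q1 <- 0; Q2 <- 0
    for (k in seq_len(K)) {
      E <- sweep(Y, 2, mu_k[, k])
      ebar <- rowMeans(E)
      Q1 <- Q1 + sum(R[, k] * rowSums((E - ebar)^2))
      Q2 <- Q2 + sum(R[, k] * ebar^2)
    }
    s2 <- Q1 / (n * (T0 - 1))
    c2 <- T0 * Q2 / n
    if (c2 >= s2) {
      sigma2 <- max(s2, 1e-8)
      tau2 <- (c2 - sigma2) / T0
    } else {                      # boundary tau2 = 0: pooled variance MLE
      sigma2 <- max((Q1 + T0 * Q2) / (n * T0), 1e-8)
      tau2 <- 0
    }
    pi_k <- pmax(colSums(R) / n, 1e-12); pi_k <- pi_k / sum(pi_k)

    # E-step and objective
    logd <- vapply(seq_len(K), function(k)
      .csLogDens(sweep(Y, 2, mu_k[, k]), sigma2, tau2), numeric(n))
    logd <- matrix(logd, n, K)
    lw <- sweep(logd, 2, log(pi_k), "+")
    mx <- apply(lw, 1, max)
    ll <- sum(mx + log(rowSums(exp(lw - mx))))
    obj <- ll - 0.5 * lambda * sum(vapply(seq_len(K), function(k)
      drop(theta[, k] %*% P %*% theta[, k]), numeric(1)))
    R <- exp(lw - mx)
    R <- R / rowSums(R)

    objective <- c(objective, obj)
    if (iter > 1L &&
        abs(objective[iter] - objective[iter - 1L]) < tol) {
      converged <- TRUE
      break
    }
  }
  p_bic <- K * m + (K - 1L) + 2L
  new("PSplineMixture", K = as.integer(K), coefficients = theta, basis = B,
      knots = bs$knots, lambda = lambda, times = as.numeric(times),
      proportions = as.numeric(pi_k), sigma2 = sigma2, tau2 = tau2,
      responsibilities = R, logLik = ll, objective = objective,
      bic = -2 * ll + p_bic * log(n), converged = converged)
}

#' Hard cluster assignment from a fitted mixture
#'
#' @param fit a [PSplineMixture-class].
#' @param Y the trajectory matrix the mixture was fitted to (for gene names).
#' @param transition optional transition label carried in the result.
#' @return a [ClusterAssignment-class] with argmax-responsibility labels and
#'   cluster mean trajectories evaluated at the design times.
#' @export
hardAssignment <- function(fit, Y, transition = "") {
  lab <- max.col(responsibilities(fit), ties.method = "first")
  genes <- rownames(Y)
  if (is.null(genes)) genes <- paste0("g", seq_len(nrow(Y)))
  means <- t(fit@basis %*% fit@coefficients)   # K x T
  dimnames(means) <- list(NULL, fit@times)
  new("ClusterAssignment", labels = setNames(as.integer(lab), genes),
      means = means, times = fit@times, K = fit@K, transition = transition)
}

#' BIC scan over candidate cluster counts
#'
#' One mixture fit per K (same penalty and seed throughout); failed fits are
#' recorded and the scan continues.
#'
#' @param Y genes x times trajectory matrix.
#' @param times design times.
#' @param Ks candidate cluster counts (e.g. even integers 2..120).
#' @param lambda penalty, shared across all K (default 1, as in
#'   [fitPsplineMixture()]) so the scanned BICs are comparable.
#' @param seed RNG seed.
#' @param ... further arguments to [fitPsplineMixture()].
#' @return list with `table` (data.frame K, bic, logLik, converged, error)
#'   and `fits` (named list of fitted mixtures).
#' @export
bicScan <- function(Y, times, Ks, lambda = 1, seed = 1L, ...) {
  if (any(Ks > nrow(Y))) stop("K values must not exceed the number of genes")
  fits <- list()
  rows <- lapply(Ks, function(K) {
    f <- tryCatch(fitPsplineMixture(Y, times, K, lambda = lambda,
                                    seed = seed, ...),
                  error = function(e) e)
    if (inherits(f, "error"))
      return(data.frame(K = K, bic = NA_real_, logLik = NA_real_,
                        converged = FALSE, error = conditionMessage(f)))
    fits[[as.character(K)]] <<- f
    data.frame(K = K, bic = mixtureBIC(f), logLik = f@logLik,
               converged = f@converged, error = NA_character_)
  })
  list(table = do.call(rbind, rows), fits = fits, lambda = lambda)
}

#' Select the cluster count from a BIC scan
#'
#' Plateau rule: the smallest K whose BIC lies within a tolerance of the
#' global minimum and that is not followed, anywhere later in the scan, by a
#' BIC exceeding it by more than the tolerance. The tolerance defaults to
#' 0.5 percent of the scanned BIC range.
#'
#' @param bicTable data.frame with columns `K` and `bic` (NA rows ignored).
#' @param tolFrac tolerance as a fraction of the BIC range (default 0.005).
#' @return the selected K.
#' @export
selectK <- function(bicTable, tolFrac = 0.005) {
  tab <- bicTable[!is.na(bicTable$bic), , drop = FALSE]
  if (!nrow(tab)) stop("empty BIC table")
  tab <- tab[order(tab$K), , drop = FALSE]
  tau <- tolFrac * diff(range(tab$bic))
  lo <- min(tab$bic)
  for (i in seq_len(nrow(tab))) {
    near_min <- tab$bic[i] <= lo + tau
    later <- tab$bic[seq_len(nrow(tab)) > i]
    stable <- !length(later) || all(later <= tab$bic[i] + tau)
    if (near_min && stable) return(tab$K[i])
  }
  tab$K[which.min(tab$bic)]
}

#' Maximum change vector of a trajectory
#'
#' The interval, magnitude and direction of the largest average expression
#' change between consecutive time points. Ties take the earliest interval;
#' a zero-magnitude change is reported with direction "+".
#'
#' @param traj numeric trajectory (>= 2 points), or a matrix of trajectories
#'   in rows.
#' @param times time points (default taken from names/colnames).
#' @return data.frame with `interval` (label), `intervalIndex`, `magnitude`
#'   and `direction` ("+" or "-"); one row per trajectory.
#' @export
computeMcv <- function(traj, times = NULL) {
  if (is.matrix(traj)) {
    if (is.null(times)) times <- as.numeric(colnames(traj))
    out <- do.call(rbind, lapply(seq_len(nrow(traj)), function(i)
      computeMcv(traj[i, ], times)))
    rownames(out) <- rownames(traj)
    return(out)
  }
  if (length(traj) < 2L) stop("a trajectory needs at least 2 time points")
  if (is.null(times)) times <- as.numeric(names(traj))
  if (is.null(times) || anyNA(times)) times <- seq_along(traj)
  d <- diff(traj)
  i <- which.max(abs(d))        # first index on exact ties = earliest interval
  data.frame(interval = paste0(times[i], "-", times[i + 1L]),
             intervalIndex = as.integer(i),
             magnitude = abs(d[i]),
             direction = if (d[i] < 0) "-" else "+",
             stringsAsFactors = FALSE)
}

#' Maximum change vectors of the cluster mean trajectories
#'
#' @param assignment a [ClusterAssignment-class].
#' @return data.frame, one row per cluster (rownames = cluster id).
#' @export
clusterMcvs <- function(assignment) {
  m <- clusterMeans(assignment)
  out <- computeMcv(m, as.numeric(colnames(m)))
  rownames(out) <- seq_len(nrow(m))
  out
}

#' Gene counts per maximum-change interval
#'
#' Each gene in a DEG-enriched cluster contributes one count to the interval
#' of its cluster's maximum change vector; counts therefore sum to the total
#' size of the enriched clusters.
#'
#' @param assignment a [ClusterAssignment-class].
#' @param mcvs per-cluster MCV table from [clusterMcvs()].
#' @param enrichedClusters integer ids of the DEG-enriched clusters.
#' @return named integer vector, one entry per consecutive time interval.
#' @export
intervalGeneCounts <- function(assignment, mcvs, enrichedClusters) {
  times <- assignment@times
  intervals <- paste0(times[-length(times)], "-", times[-1L])
  counts <- setNames(integer(length(intervals)), intervals)
  if (!all(as.character(enrichedClusters) %in% rownames(mcvs)))
    stop("MCV missing for enriched cluster(s): ",
         paste(setdiff(as.character(enrichedClusters), rownames(mcvs)),
               collapse = ", "))
  sizes <- table(factor(clusterLabels(assignment),
                        levels = seq_len(assignment@K)))
  for (cl in enrichedClusters) {
    iv <- mcvs[as.character(cl), "interval"]
    counts[iv] <- counts[iv] + sizes[[cl]]
  }
  counts
}

#' Concordance of maximum change vectors between transitions
#'
#' Two MCVs agree when both interval and direction match (magnitude ignored).
#'
#' @param mcvA,mcvB MCV tables (rownames = gene ids) from [computeMcv()].
#' @return list with `nShared`, `nSame` and `percentSame` (one decimal).
#' @export
mcvConcordance <- function(mcvA, mcvB) {
  shared <- intersect(rownames(mcvA), rownames(mcvB))
  same <- sum(mcvA[shared, "interval"] == mcvB[shared, "interval"] &
                mcvA[shared, "direction"] == mcvB[shared, "direction"])
  list(nShared = length(shared), nSame = same,
       percentSame = if (length(shared)) round(100 * same / length(shared), 1)
                     else 0)
}

.pearsonChi2 <- function(tab) {
  E <- outer(rowSums(tab), colSums(tab)) / sum(tab)
  sum((tab - E)^2 / E)
}

#' Chi-square homogeneity test of two per-interval count vectors
#'
#' Pearson chi-square of the 2 x m table (no continuity correction) with
#' df = m - 1; columns with zero total are dropped with a warning.
#'
#' @param countsA,countsB non-negative integer vectors of equal length.
#' @return list with `statistic`, `df`, `pvalue` and the `table` used.
#' @export
chi2Homogeneity <- function(countsA, countsB) {
  if (length(countsA) != length(countsB))
    stop("count vectors must have equal length")
  tab <- rbind(A = countsA, B = countsB)
  zero <- colSums(tab) == 0
  if (any(zero)) {
    warning("dropping ", sum(zero), " interval(s) with zero total")
    tab <- tab[, !zero, drop = FALSE]
  }
  if (ncol(tab) < 2L) stop("need at least 2 intervals with positive totals")
  if (any(rowSums(tab) == 0)) stop("a row of the table is all zeros")
  stat <- .pearsonChi2(tab)
  df <- ncol(tab) - 1L
  list(statistic = stat, df = df,
       pvalue = pchisq(stat, df, lower.tail = FALSE), table = tab)
}
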
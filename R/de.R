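# Negative binomial GLM differential expression over spline time designs.
# The model, fitting (IRLS with step halving), dispersion estimation
# (Cox-Reid adjusted profile likelihood) and the likelihood-ratio contrasts
# are authored here; only generic numerics (QR least squares, chi-square
# tail) come from base R.

#' Median-of-ratios size factors
#'
#' Per-sample median of the ratios of counts to the per-gene geometric mean,
#' computed over genes with strictly positive counts in all samples.
#'
#' @param counts integer count matrix (genes x samples).
#' @return named positive numeric vector of size factors.
#' @export
computeSizeFactors <- function(counts) {
  lc <- log(counts)
  ok <- rowSums(is.finite(lc)) == ncol(counts)
  if (!any(ok))
    stop("no gene has positive counts in every sample; ",
         "filter low-count genes before normalization")
  lgeo <- rowMeans(lc[ok, , drop = FALSE])
  sf <- apply(lc[ok, , drop = FALSE], 2, function(x) exp(median(x - lgeo)))
  setNames(sf, colnames(counts))
}

#' Variance-stabilizing transform of normalized counts
#'
#' `log2(count / sizeFactor + 1)`: monotone in counts and approximately the
#' log2 scale on which expression trajectories are clustered and plotted.
#'
#' @param counts count matrix.
#' @param sf size factors (default all 1).
#' @return transformed matrix of the same shape.
#' @export
vstCounts <- function(counts, sf = rep(1, ncol(counts))) {
  log2(sweep(counts, 2, sf, "/") + 1)
}

.nbLogLik <- function(y, mu, alpha) {
  alpha <- max(alpha, 1e-8)
  sum(dnbinom(y, size = 1 / alpha, mu = mu, log = TRUE))
}

# IRLS for the NB log-link GLM at fixed dispersion, with step halving on the
# log-likelihood; offset = log size factors.
.nbIrls <- function(y, X, offset, alpha, beta = NULL,
                    maxit = 100L, tol = 1e-8) {
  if (is.null(beta)) {
    z0 <- log(y + 0.5) - offset
    beta <- qr.coef(qr(X), z0)
    beta[is.na(beta)] <- 0
  }
  eta <- pmin(pmax(drop(X %*% beta) + offset, -30), 30)
  mu <- exp(eta)
  ll <- .nbLogLik(y, mu, alpha)
  converged <- FALSE
  for (it in seq_len(maxit)) {
    W <- mu / (1 + alpha * mu)
    z <- (eta - offset) + (y - mu) / mu
    fit <- lm.wfit(X, z, W)
    bnew <- fit$coefficients
    bnew[is.na(bnew)] <- 0
    step <- bnew - beta
    accepted <- FALSE
    for (h in 0:12) {
      btry <- beta + step * 0.5^h
      etat <- pmin(pmax(drop(X %*% btry) + offset, -30), 30)
      mut <- exp(etat)
      llt <- .nbLogLik(y, mut, alpha)
      if (is.finite(llt) && llt >= ll - 1e-12) {
        beta <- btry; eta <- etat; mu <- mut
        dll <- llt - ll; ll <- llt; accepted <- TRUE
        break
      }
    }
    if (!accepted) { converged <- TRUE; break }   # no uphill step left
    if (abs(dll) < tol * (abs(ll) + 1)) { converged <- TRUE; break }
  }
  list(beta = beta, mu = mu, W = mu / (1 + alpha * mu),
       logLik = ll, converged = converged)
}

#' Fit a negative binomial GLM to one gene
#'
#' Log-link NB regression with `log(sf)` offset, fitted by iteratively
#' reweighted least squares with step halving. When `alpha` is `NULL` the
#' dispersion is estimated by maximizing the Cox-Reid adjusted profile
#' likelihood over a floor of 1e-8 (variance mu + alpha * mu^2).
#'
#' @param y integer counts for one gene.
#' @param X full-rank design matrix (samples x p).
#' @param sf positive size factors.
#' @param alpha fixed dispersion, or `NULL` to estimate it.
#' @return list with `coefficients`, `alpha`, `mu`, `logLik`, `converged`.
#' @export
fitNbGlm <- function(y, X, sf = rep(1, length(y)), alpha = NULL) {
  offset <- log(sf)
  if (qr(X)$rank < ncol(X)) stop("design matrix is rank deficient")
  if (is.null(alpha)) {
    warm <- NULL
    apl <- function(la) {
      f <- .nbIrls(y, X, offset, exp(la), beta = warm)
      warm <<- f$beta
      cr <- 0.5 * as.numeric(determinant(crossprod(X * sqrt(f$W)),
                                         logarithm = TRUE)$modulus)
      -(f$logLik - cr)
    }
    opt <- optimize(apl, lower = log(1e-8), upper = log(30), tol = 1e-3)
    alpha <- max(exp(opt$minimum), 1e-8)
  }
  f <- .nbIrls(y, X, offset, alpha)
  list(coefficients = f$beta, alpha = alpha, mu = f$mu,
       logLik = f$logLik, converged = f$converged)
}

.designForContrast <- function(meta, contrast) {
  tr <- factor(meta$transition, levels = VALID_TRANSITIONS)
  colony <- factor(meta$colony_id)
  B <- buildSplineBasis(meta$time_h)$basis
  if (contrast %in% c("RB_time", "BR_time")) {
    Xr <- model.matrix(~colony)
    Xf <- cbind(Xr, B)
  } else {
    Xr <- cbind(model.matrix(~ colony + tr), B)
    Xf <- cbind(Xr, B * (as.integer(tr) - 1L))
    colnames(Xf)[(ncol(Xr) + 1L):ncol(Xf)] <- paste0("trBR:bs", 1:3)
  }
  if (qr(Xf)$rank < ncol(Xf))
    stop("design is rank deficient; check that every colony and time level ",
         "has samples for contrast ", contrast)
  list(full = Xf, reduced = Xr)
}

#' Likelihood-ratio contrasts for time and time-by-transition effects
#'
#' For `"RB_time"` / `"BR_time"` the samples of that transition (controls
#' coded time 0) are modeled with full design `colony + bs(time, df = 3)`
#' against the reduced design `colony`. For `"interaction"` all samples are
#' modeled with full design `colony + transition + bs(time, df = 3) +
#' transition:bs(time, df = 3)` against the same design without the
#' interaction. Per gene, the dispersion is estimated once under the full
#' model (Cox-Reid adjusted profile likelihood) and shared with the reduced
#' fit; the statistic `2 * (llFull - llReduced)` is referred to a chi-square
#' with 3 degrees of freedom and Benjamini-Hochberg adjusted over all tested
#' genes.
#'
#' @param pe a [PhaseExperiment-class].
#' @param contrast one of `"RB_time"`, `"BR_time"`, `"interaction"`.
#' @param minCount genes with fewer total counts across the used samples are
#'   excluded from testing (default 10) and reported with NA statistics.
#' @return a [DEResultSet-class].
#' @export
lrtContrast <- function(pe, contrast = c("RB_time", "BR_time", "interaction"),
                        minCount = 10L) {
  contrast <- match.arg(contrast)
  meta <- sampleInfo(pe)
  keep_s <- if (contrast == "interaction") rep(TRUE, nrow(meta))
            else meta$transition == substr(contrast, 1, 2)
  if (!any(keep_s)) stop("no samples available for contrast ", contrast)
  cts <- counts(pe)[, keep_s, drop = FALSE]
  meta <- meta[keep_s, , drop = FALSE]
  des <- .designForContrast(meta, contrast)
  sf <- computeSizeFactors(cts)
  genes <- rownames(cts)
  tested <- rowSums(cts) >= minCount
  n_df <- ncol(des$full) - ncol(des$reduced)
  stat <- p <- rep(NA_real_, length(genes))
  conv <- rep(NA, length(genes))
  for (i in which(tested)) {
    y <- cts[i, ]
    ff <- fitNbGlm(y, des$full, sf)
    fr <- .nbIrls(y, des$reduced, log(sf), ff$alpha)
    conv[i] <- ff$converged && fr$converged
    if (!conv[i]) next
    stat[i] <- max(0, 2 * (ff$logLik - fr$logLik))
    p[i] <- pchisq(stat[i], df = n_df, lower.tail = FALSE)
  }
  n_failed <- sum(tested & !is.na(conv) & !conv)
  if (n_failed)
    warning(n_failed, " gene fits did not converge and were excluded")
  padj <- rep(NA_real_, length(genes))
  ok <- !is.na(p)
  padj[ok] <- bhAdjust(p[ok])
  new("DEResultSet", contrast = contrast,
      table = data.frame(gene_id = genes,
                         baseMean = rowMeans(sweep(cts, 2, sf, "/")),
                         stat = stat, df = ifelse(is.na(p), NA, n_df),
                         pvalue = p, padj = padj, converged = conv,
                         row.names = NULL))
}

#' Benjamini-Hochberg step-up adjustment
#'
#' @param p raw p-values in \[0, 1\].
#' @return adjusted p-values in the input order, monotone and clipped at 1.
#' @export
bhAdjust <- function(p) {
  if (any(is.na(p) | p < 0 | p > 1)) stop("p-values must lie in [0, 1]")
  n <- length(p)
  if (n <= 1L) return(p)
  o <- order(p, decreasing = TRUE)
  pmin(1, cummin(n / (n:1) * p[o]))[order(o)]
}

#' Overlap summary of two gene (or term) sets
#'
#' Reports set sizes, intersection, union and the shared percentage
#' `100 * |A n B| / |A u B|` rounded to one decimal (0 for an empty union).
#'
#' @param setA,setB character vectors over a common universe.
#' @return list with `nA`, `nB`, `nIntersect`, `nUnion`, `percentShared`.
#' @export
degOverlap <- function(setA, setB) {
  setA <- unique(setA); setB <- unique(setB)
  ni <- length(intersect(setA, setB))
  nu <- length(union(setA, setB))
  list(nA = length(setA), nB = length(setB), nIntersect = ni, nUnion = nu,
       percentShared = if (nu == 0) 0 else round(100 * ni / nu, 1))
}

#' Per-gene mean expression trajectories for one transition
#'
#' Variance-stabilized counts (size factors computed within the transition)
#' averaged per design time point; rows are genes, columns the sorted unique
#' times (controls at 0 h).
#'
#' @param pe a [PhaseExperiment-class].
#' @param transition `"RB"` or `"BR"`.
#' @param genes optional gene subset.
#' @return matrix genes x times with times as column names.
#' @export
trajectoryMatrix <- function(pe, transition = c("RB", "BR"), genes = NULL) {
  transition <- match.arg(transition)
  meta <- sampleInfo(pe)
  sel <- meta$transition == transition
  cts <- counts(pe)[, sel, drop = FALSE]
  if (!is.null(genes)) cts <- cts[genes, , drop = FALSE]
  v <- vstCounts(cts, computeSizeFactors(counts(pe)[, sel, drop = FALSE]))
  tt <- meta$time_h[sel]
  times <- sort(unique(tt))
  out <- vapply(times, function(t0) rowMeans(v[, tt == t0, drop = FALSE]),
                numeric(nrow(v)))
  out <- matrix(out, nrow = nrow(v),
                dimnames = list(rownames(cts), times))
  out
}
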
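# Outlier screening via the twofold-change criterion and ordination of
# time-point mean expression profiles (PCA, k-means, Euclidean distances and
# an average-linkage dendrogram).

.groupFactor <- function(meta) {
  factor(paste(meta$transition, meta$time_h, sep = "_"))
}

.groupMeans <- function(mat, groups) {
  g <- as.factor(groups)
  t(vapply(levels(g), function(l)
    rowMeans(mat[, g == l, drop = FALSE]), numeric(nrow(mat))))
}

#' Twofold-change screen of genes across sample groups
#'
#' Group (transition x time) means are computed on the variance-stabilized
#' scale and compared as linear-scale ratios `2^(maxMean - minMean)`; a gene
#' is flagged when the ratio reaches `threshold`. The +1 offset inherited
#' from [vstCounts()] keeps zero-mean groups finite.
#'
#' @param vst variance-stabilized matrix (genes x samples).
#' @param meta sample metadata with `transition` and `time_h`.
#' @param threshold minimum max/min group-mean ratio (default 2; must be >= 1).
#' @return list with `genes` (flagged set), `ratio` (named per-gene ratios)
#'   and `threshold`.
#' @export
foldChangeScreen <- function(vst, meta, threshold = 2) {
  if (threshold < 1) stop("threshold must be >= 1")
  gm <- .groupMeans(vst, .groupFactor(meta))     # groups x genes
  ratio <- 2^(apply(gm, 2, max) - apply(gm, 2, min))
  names(ratio) <- rownames(vst)
  list(genes = names(ratio)[ratio >= threshold], ratio = ratio,
       threshold = threshold)
}

#' Sensitivity accounting for removing the 6-h samples
#'
#' Quantifies how many early-responding candidate genes (genes at or above
#' the fold-change threshold between 6-h control and treatment samples) are
#' lost when the screen is re-run without the 6-h time points.
#'
#' @param screenAll [foldChangeScreen()] result on all samples.
#' @param screenNo6h [foldChangeScreen()] result after dropping 6-h samples.
#' @param earlyCandidates character vector of early-responding candidates.
#' @return list with `nLostOverall`, `nCandidates`, `nCandidatesLost` and
#'   `percentLost` (one decimal; 0 with a warning for an empty candidate set).
#' @export
outlierImpact <- function(screenAll, screenNo6h, earlyCandidates) {
  lostOverall <- setdiff(screenAll$genes, screenNo6h$genes)
  if (length(earlyCandidates) == 0L) {
    warning("empty early-candidate set; percentLost reported as 0")
    return(list(nLostOverall = length(lostOverall), nCandidates = 0L,
                nCandidatesLost = 0L, percentLost = 0))
  }
  lost <- setdiff(earlyCandidates, screenNo6h$genes)
  list(nLostOverall = length(lostOverall),
       nCandidates = length(earlyCandidates),
       nCandidatesLost = length(lost),
       percentLost = round(100 * length(lost) / length(earlyCandidates), 1))
}

#' Ordination of time-point mean expression profiles
#'
#' Computes, over an optional gene subset, the mean expression profile of
#' every transition x time group, then a centered PCA of those profiles,
#' k-means grouping (default k = 3, 50 restarts, seeded), the Euclidean
#' distance matrix between groups and an average-linkage dendrogram.
#'
#' @param vst variance-stabilized matrix (genes x samples).
#' @param meta sample metadata with `transition` and `time_h`.
#' @param genes optional gene subset (e.g. interaction DEGs).
#' @param k number of k-means groups (default 3).
#' @param seed RNG seed for k-means.
#' @param nstart k-means restarts (default 50; the restart with the lowest
#'   within-group sum of squares wins).
#' @return list with `coordinates` (groups x PCs), `percentVar`, `kmeans`
#'   (named labels), `distances` (symmetric matrix), `hclust` and `newick`.
#' @export
ordinateTimepoints <- function(vst, meta, genes = NULL, k = 3L, seed = 1L,
                               nstart = 50L) {
  if (!is.null(genes)) vst <- vst[genes, , drop = FALSE]
  prof <- .groupMeans(vst, .groupFactor(meta))   # groups x genes
  if (k > nrow(prof))
    stop("k exceeds the number of time-point groups (", nrow(prof), ")")
  pca <- prcomp(prof, center = TRUE, scale. = FALSE)
  pv <- 100 * pca$sdev^2 / sum(pca$sdev^2)
  set.seed(seed)
  km <- kmeans(prof, centers = k, nstart = nstart)
  d <- as.matrix(dist(prof))
  hc <- hclust(dist(prof), method = "average")
  list(coordinates = pca$x, percentVar = pv,
       kmeans = setNames(km$cluster, rownames(prof)),
       distances = d, hclust = hc,
       newick = ape::write.tree(ape::as.phylo(hc)))
}
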
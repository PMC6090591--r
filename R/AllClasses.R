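#' @import methods
#' @importFrom stats median optimize pchisq quantile rnbinom rnorm runif
#'   setNames dist hclust kmeans prcomp cor phyper dnbinom lm.wfit
#'   model.matrix var approx
#' @importFrom utils read.delim write.table head
#' @importClassesFrom SummarizedExperiment SummarizedExperiment
#' @importFrom SummarizedExperiment SummarizedExperiment assay assayNames
#'   colData
#' @importFrom S4Vectors DataFrame
NULL

VALID_TIMES <- c(0, 6, 12, 24, 48, 96)
VALID_TRANSITIONS <- c("RB", "BR")

#' Container for a phase-transition time-course experiment
#'
#' `PhaseExperiment` extends [SummarizedExperiment::SummarizedExperiment]
#' with validity checks for the brood-swap design: a `"counts"` assay of
#' non-negative integers and column data with `transition` (RB or BR),
#' `time_h` (hours; controls coded 0) and `colony_id`.
#'
#' @slot .Data inherited SummarizedExperiment slots.
#' @seealso [PhaseExperiment()] for construction from a matrix and metadata.
#' @export
setClass("PhaseExperiment", contains = "SummarizedExperiment")

setValidity("PhaseExperiment", function(object) {
  msg <- character()
  if (!"counts" %in% SummarizedExperiment::assayNames(object))
    return("assay 'counts' is required")
  cts <- SummarizedExperiment::assay(object, "counts")
  if (anyNA(cts) || any(cts < 0))
    msg <- c(msg, "counts must be non-negative and non-missing")
  if (any(abs(cts - round(cts)) > 1e-8))
    msg <- c(msg, "counts must be integers")
  if (anyDuplicated(rownames(object)))
    msg <- c(msg, "duplicated gene identifiers")
  if (anyDuplicated(colnames(object)))
    msg <- c(msg, "duplicated sample identifiers")
  cd <- SummarizedExperiment::colData(object)
  need <- c("transition", "time_h", "colony_id")
  miss <- setdiff(need, colnames(cd))
  if (length(miss))
    return(paste("missing column data:", paste(miss, collapse = ", ")))
  if (!all(cd$transition %in% VALID_TRANSITIONS))
    msg <- c(msg, "transition must be 'RB' or 'BR'")
  if (!all(cd$time_h %in% VALID_TIMES))
    msg <- c(msg, sprintf("time_h must be one of {%s}",
                          paste(VALID_TIMES, collapse = ", ")))
  if ("ovary_score" %in% colnames(cd)) {
    os <- cd$ovary_score
    if (any(!is.na(os) & (os < 0 | os > 4)))
      msg <- c(msg, "ovary_score must lie in [0, 4]")
  }
  if (length(msg)) msg else TRUE
})

#' Position weight matrix over the DNA alphabet
#'
#' Column-stochastic probabilities (rows A, C, G, T) derived from a count
#' matrix plus a pseudocount, as read from JASPAR-format motif files.
#'
#' @slot name motif identifier.
#' @slot counts raw 4 x L count matrix (before pseudocount).
#' @slot probs 4 x L column-stochastic probability matrix.
#' @slot pseudocount pseudocount added to every count before normalization.
#' @export
setClass("PositionWeightMatrix",
         representation(name = "character", counts = "matrix",
                        probs = "matrix", pseudocount = "numeric"))

setValidity("PositionWeightMatrix", function(object) {
  p <- object@probs
  if (nrow(p) != 4L || !identical(rownames(p), c("A", "C", "G", "T")))
    return("probs must have rows A, C, G, T")
  if (ncol(p) < 1L) return("motif length must be at least 1")
  if (any(p <= 0)) return("all probabilities must be positive (increase pseudocount)")
  if (any(abs(colSums(p) - 1) > 1e-9)) return("columns must sum to 1")
  TRUE
})

#' Fitted P-spline mixture over expression trajectories
#'
#' Result of EM fitting a K-component mixture of penalized-spline mean
#' curves with a per-gene random intercept and i.i.d. Gaussian noise.
#'
#' @slot K number of components.
#' @slot coefficients basis-dimension x K spline coefficient matrix.
#' @slot basis evaluation of the B-spline basis at the design times.
#' @slot knots full knot vector of the basis.
#' @slot lambda second-difference penalty weight.
#' @slot times design time points (hours).
#' @slot proportions mixing proportions (sum to 1).
#' @slot sigma2 residual variance.
#' @slot tau2 gene random-intercept variance.
#' @slot responsibilities genes x K posterior membership matrix.
#' @slot logLik observed-data mixture log-likelihood (unpenalized).
#' @slot objective trace of the penalized EM objective per iteration.
#' @slot bic Bayesian information criterion.
#' @slot converged logical convergence flag.
#' @export
setClass("PSplineMixture",
         representation(K = "integer", coefficients = "matrix",
                        basis = "matrix", knots = "numeric",
                        lambda = "numeric", times = "numeric",
                        proportions = "numeric", sigma2 = "numeric",
                        tau2 = "numeric", responsibilities = "matrix",
                        logLik = "numeric", objective = "numeric",
                        bic = "numeric", converged = "logical"))

setValidity("PSplineMixture", function(object) {
  msg <- character()
  if (abs(sum(object@proportions) - 1) > 1e-6)
    msg <- c(msg, "mixing proportions must sum to 1")
  rs <- rowSums(object@responsibilities)
  if (any(abs(rs - 1) > 1e-6))
    msg <- c(msg, "responsibility rows must sum to 1")
  if (length(msg)) msg else TRUE
})

#' Hard cluster assignment of gene trajectories
#'
#' @slot labels named integer vector, gene -> cluster in 1..K.
#' @slot means K x T matrix of cluster mean trajectories at the design times.
#' @slot times design time points.
#' @slot K number of clusters.
#' @slot transition transition the assignment belongs to ("RB", "BR" or "").
#' @export
setClass("ClusterAssignment",
         representation(labels = "integer", means = "matrix",
                        times = "numeric", K = "integer",
                        transition = "character"))

setValidity("ClusterAssignment", function(object) {
  if (is.null(names(object@labels))) return("labels must be named by gene")
  if (any(object@labels < 1L | object@labels > object@K))
    return("labels must lie in 1..K")
  TRUE
})

#' Bipartite cluster-membership network between two transitions
#'
#' Nodes are trajectory clusters of each transition; an edge joins clusters
#' from opposite transitions that share at least one gene, weighted by the
#' shared-gene count and annotated with the Jaccard index. Each gene
#' clustered in both transitions contributes to exactly one edge, so edge
#' weights sum to the shared gene universe.
#'
#' @slot edges data.frame with columns a, b, weight, jaccard and (after
#'   [conservedNetwork()] / [edgeDirectionClasses()]) conserved, direction.
#' @slot sharedGenes list of gene-id vectors, one per edge.
#' @slot sizesA,sizesB named cluster sizes in the shared universe.
#' @slot universe gene identifiers clustered in both transitions.
#' @slot threshold conserved-edge Jaccard threshold (NA until computed).
#' @export
setClass("ClusterNetwork",
         representation(edges = "data.frame", sharedGenes = "list",
                        sizesA = "integer", sizesB = "integer",
                        universe = "character", threshold = "numeric"))

setValidity("ClusterNetwork", function(object) {
  if (sum(object@edges$weight) != length(object@universe))
    return("edge weights must sum to the shared gene universe size")
  if (any(object@edges$jaccard < 0 | object@edges$jaccard > 1))
    return("Jaccard indices must lie in [0, 1]")
  TRUE
})

#' Permutation null distribution of cluster-pair Jaccard indices
#'
#' @slot scores pooled Jaccard indices over all replicate x pair combinations.
#' @slot R number of permutation replicates.
#' @slot threshold empirical 95th percentile of the pooled scores.
#' @slot seed RNG seed used.
#' @export
setClass("NullJaccard",
         representation(scores = "numeric", R = "integer",
                        threshold = "numeric", seed = "integer"))

#' Per-contrast differential expression results
#'
#' @slot contrast one of "RB_time", "BR_time", "interaction".
#' @slot table data.frame with gene_id, baseMean, stat, df, pvalue, padj,
#'   converged; untested (low-count) genes carry NA statistics.
#' @export
setClass("DEResultSet",
         representation(contrast = "character", table = "data.frame"))

setMethod("show", "PhaseExperiment", function(object) {
  callNextMethod()
  cd <- SummarizedExperiment::colData(object)
  cat(sprintf("design: %s\n", paste(sprintf(
    "%s (n=%d)", levels(factor(paste(cd$transition, cd$time_h, sep = "-"))),
    table(paste(cd$transition, cd$time_h, sep = "-"))), collapse = ", ")))
})

setMethod("show", "PositionWeightMatrix", function(object) {
  cat(sprintf("PositionWeightMatrix '%s', length %d, pseudocount %g\n",
              object@name, ncol(object@probs), object@pseudocount))
})

setMethod("show", "PSplineMixture", function(object) {
  cat(sprintf(
    "PSplineMixture: K=%d, %d genes, lambda=%.3g, logLik=%.2f, BIC=%.2f%s\n",
    object@K, nrow(object@responsibilities), object@lambda, object@logLik,
    object@bic, if (object@converged) "" else " (not converged)"))
})

setMethod("show", "ClusterAssignment", function(object) {
  cat(sprintf("ClusterAssignment%s: %d genes in %d clusters\n",
              if (nzchar(object@transition))
                paste0(" [", object@transition, "]") else "",
              length(object@labels), object@K))
})

setMethod("show", "ClusterNetwork", function(object) {
  n_cons <- if ("conserved" %in% names(object@edges))
    sum(object@edges$conserved) else NA_integer_
  cat(sprintf(
    "ClusterNetwork: %d x %d clusters, %d edges over %d shared genes%s\n",
    length(object@sizesA), length(object@sizesB), nrow(object@edges),
    length(object@universe),
    if (!is.na(n_cons)) sprintf(", %d conserved", n_cons) else ""))
})

setMethod("show", "NullJaccard", function(object) {
  cat(sprintf(
    "NullJaccard: %d pooled scores from %d replicates, 95th pct = %.4f\n",
    length(object@scores), object@R, object@threshold))
})

setMethod("show", "DEResultSet", function(object) {
  tab <- object@table
  cat(sprintf("DEResultSet '%s': %d genes tested (%d NA), %d at padj < 0.05\n",
              object@contrast, sum(!is.na(tab$pvalue)), sum(is.na(tab$pvalue)),
              sum(tab$padj < 0.05, na.rm = TRUE)))
})
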
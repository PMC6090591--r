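#' Accessors for phasecycle S4 objects
#'
#' Small accessor generics so downstream code never touches slots directly:
#' `clusterLabels()` and `clusterMeans()` for [ClusterAssignment-class],
#' `networkEdges()`, `sharedGenes()` and `jaccardThreshold()` for
#' [ClusterNetwork-class] / [NullJaccard-class], `pwmProbs()` for
#' [PositionWeightMatrix-class], `resultsTable()` for [DEResultSet-class],
#' `responsibilities()` and `mixtureBIC()` for [PSplineMixture-class].
#'
#' @param object an object of the documented class.
#' @return the slot contents (see each class's documentation).
#' @name accessors
NULL

#' @rdname accessors
#' @export
setGeneric("clusterLabels", function(object) standardGeneric("clusterLabels"))
#' @rdname accessors
#' @export
setMethod("clusterLabels", "ClusterAssignment", function(object) object@labels)

#' @rdname accessors
#' @export
setGeneric("clusterMeans", function(object) standardGeneric("clusterMeans"))
#' @rdname accessors
#' @export
setMethod("clusterMeans", "ClusterAssignment", function(object) object@means)

#' @rdname accessors
#' @export
setGeneric("networkEdges", function(object) standardGeneric("networkEdges"))
#' @rdname accessors
#' @export
setMethod("networkEdges", "ClusterNetwork", function(object) object@edges)

#' @rdname accessors
#' @export
setGeneric("sharedGenes", function(object) standardGeneric("sharedGenes"))
#' @rdname accessors
#' @export
setMethod("sharedGenes", "ClusterNetwork", function(object) object@sharedGenes)

#' @rdname accessors
#' @export
setGeneric("jaccardThreshold",
           function(object) standardGeneric("jaccardThreshold"))
#' @rdname accessors
#' @export
setMethod("jaccardThreshold", "NullJaccard", function(object) object@threshold)
#' @rdname accessors
#' @export
setMethod("jaccardThreshold", "ClusterNetwork",
          function(object) object@threshold)

#' @rdname accessors
#' @export
setGeneric("pwmProbs", function(object) standardGeneric("pwmProbs"))
#' @rdname accessors
#' @export
setMethod("pwmProbs", "PositionWeightMatrix", function(object) object@probs)

#' @rdname accessors
#' @export
setGeneric("resultsTable", function(object) standardGeneric("resultsTable"))
#' @rdname accessors
#' @export
setMethod("resultsTable", "DEResultSet", function(object) object@table)

#' @rdname accessors
#' @export
setGeneric("responsibilities",
           function(object) standardGeneric("responsibilities"))
#' @rdname accessors
#' @export
setMethod("responsibilities", "PSplineMixture",
          function(object) object@responsibilities)

#' @rdname accessors
#' @export
setGeneric("mixtureBIC", function(object) standardGeneric("mixtureBIC"))
#' @rdname accessors
#' @export
setMethod("mixtureBIC", "PSplineMixture", function(object) object@bic)

#' Count matrix of a PhaseExperiment
#'
#' @param object a [PhaseExperiment-class].
#' @return integer matrix of read counts, genes x samples.
#' @importFrom BiocGenerics counts
#' @export counts
#' @aliases counts,PhaseExperiment-method
#' @export
setMethod("counts", "PhaseExperiment", function(object) {
  SummarizedExperiment::assay(object, "counts")
})

#' Sample metadata of a PhaseExperiment
#'
#' @param object a [PhaseExperiment-class].
#' @return data.frame with one row per sample (sample_id, transition,
#'   time_h, colony_id, optional lineage_id and ovary_score).
#' @export
sampleInfo <- function(object) {
  stopifnot(is(object, "PhaseExperiment"))
  cd <- as.data.frame(SummarizedExperiment::colData(object))
  cd$sample_id <- colnames(object)
  cd[, c("sample_id", setdiff(colnames(cd), "sample_id")), drop = FALSE]
}
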
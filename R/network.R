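# Bipartite cluster-membership network between the two transitions, with a
# size-preserving permutation null for the Jaccard index and the conserved
# sub-network of edges exceeding its 95th percentile.

#' Jaccard index of two sets
#'
#' @param setX,setY character vectors.
#' @return `|X n Y| / |X u Y|`; 0 when both sets are empty.
#' @export
jaccard <- function(setX, setY) {
  u <- length(union(setX, setY))
  if (u == 0L) return(0)
  length(intersect(setX, setY)) / u
}

.labelsOf <- function(assign) {
  if (is(assign, "ClusterAssignment")) clusterLabels(assign)
  else if (!is.null(names(assign))) assign
  else stop("cluster assignments must be ClusterAssignment objects or ",
            "named label vectors")
}

#' Build the complete cluster-membership network
#'
#' Nodes are the clusters of each transition over the genes clustered in
#' both; an edge joins every cross-transition cluster pair sharing at least
#' one gene, weighted by the shared-gene count, with the pair's Jaccard
#' index. No two clusters of the same transition are ever connected, and
#' every shared gene contributes to exactly one edge.
#'
#' @param assignA,assignB [ClusterAssignment-class] objects (or named label
#'   vectors) for the two transitions, over a shared gene universe.
#' @return a [ClusterNetwork-class].
#' @export
buildClusterNetwork <- function(assignA, assignB) {
  la <- .labelsOf(assignA); lb <- .labelsOf(assignB)
  universe <- intersect(names(la), names(lb))
  if (!length(universe)) stop("the two assignments share no genes")
  la <- la[universe]; lb <- lb[universe]
  fa <- factor(la); fb <- factor(lb)
  O <- table(fa, fb)
  sizesA <- setNames(as.integer(table(fa)), levels(fa))
  sizesB <- setNames(as.integer(table(fb)), levels(fb))
  idx <- which(O > 0, arr.ind = TRUE)
  w <- as.integer(O[idx])
  a <- levels(fa)[idx[, 1L]]
  b <- levels(fb)[idx[, 2L]]
  jac <- w / (sizesA[a] + sizesB[b] - w)
  shared <- lapply(seq_along(w), function(i)
    universe[la == a[i] & lb == b[i]])
  edges <- data.frame(a = a, b = b, weight = w, jaccard = as.numeric(jac),
                      stringsAsFactors = FALSE)
  o <- order(edges$a, edges$b)
  new("ClusterNetwork", edges = edges[o, , drop = FALSE],
      sharedGenes = shared[o], sizesA = sizesA, sizesB = sizesB,
      universe = universe, threshold = NA_real_)
}

#' Permutation null distribution of cluster-pair Jaccard indices
#'
#' For each of `R` replicates, genes are uniformly permuted into clusters of
#' the fixed original sizes, independently for the two transitions, and the
#' Jaccard indices of all cross-transition cluster pairs (including
#' zero-overlap pairs) are pooled. The conserved-edge threshold is the
#' empirical 95th percentile of the pooled scores.
#'
#' @param sizesA,sizesB cluster sizes; each must sum to `nUniverse`.
#' @param nUniverse number of genes in the shared universe.
#' @param R permutation replicates (default 1000).
#' @param seed RNG seed.
#' @return a [NullJaccard-class].
#' @export
nullJaccardDistribution <- function(sizesA, sizesB, nUniverse, R = 1000L,
                                    seed = 1L) {
  if (sum(sizesA) != nUniverse || sum(sizesB) != nUniverse)
    stop("cluster sizes must sum to the universe size")
  set.seed(seed)
  baseA <- rep.int(seq_along(sizesA), sizesA)
  baseB <- rep.int(seq_along(sizesB), sizesB)
  denom0 <- outer(as.integer(sizesA), as.integer(sizesB), "+")
  scores <- vector("list", R)
  for (r in seq_len(R)) {
    la <- baseA[sample.int(nUniverse)]
    lb <- baseB[sample.int(nUniverse)]
    O <- tabulate((la - 1L) * length(sizesB) + lb,
                  nbins = length(sizesA) * length(sizesB))
    O <- matrix(O, length(sizesA), length(sizesB), byrow = TRUE)
    scores[[r]] <- as.numeric(O / (denom0 - O))
  }
  scores <- unlist(scores)
  new("NullJaccard", scores = scores, R = as.integer(R),
      threshold = as.numeric(quantile(scores, 0.95, names = FALSE)),
      seed = as.integer(seed))
}

#' Flag conserved edges of a cluster network
#'
#' An edge is conserved when its Jaccard index strictly exceeds the null
#' threshold (greater than 95 percent of all permutation scores).
#'
#' @param net a [ClusterNetwork-class].
#' @param null a [NullJaccard-class] computed on matching cluster sizes.
#' @return the network with a logical `conserved` edge column and the
#'   threshold recorded.
#' @export
conservedNetwork <- function(net, null) {
  net@edges$conserved <- net@edges$jaccard > jaccardThreshold(null)
  net@threshold <- jaccardThreshold(null)
  net
}

#' Classify edges by direction concordance of their clusters' MCVs
#'
#' An edge is `"opposite"` when the two clusters' maximum-change directions
#' differ, `"same"` otherwise.
#'
#' @param net a [ClusterNetwork-class].
#' @param mcvA,mcvB per-cluster MCV tables (rownames = cluster ids) for the
#'   two transitions, e.g. from [clusterMcvs()].
#' @return the network with a `direction` edge column.
#' @export
edgeDirectionClasses <- function(net, mcvA, mcvB) {
  e <- net@edges
  missA <- setdiff(unique(e$a), rownames(mcvA))
  missB <- setdiff(unique(e$b), rownames(mcvB))
  if (length(missA) || length(missB))
    stop("MCV missing for cluster(s): ",
         paste(c(missA, missB), collapse = ", "))
  net@edges$direction <- ifelse(
    mcvA[e$a, "direction"] == mcvB[e$b, "direction"], "same", "opposite")
  net
}

#' Compare opposite-direction edge proportions between networks
#'
#' Builds the 2 x 2 table of edge counts, network (conserved vs the complete
#' network's non-conserved remainder, so the compared sets are disjoint) by
#' direction class (opposite vs same), and applies the Pearson chi-square
#' test without continuity correction (df = 1). Also reports the
#' opposite-direction proportion of the conserved and of the full complete
#' network.
#'
#' @param net a [ClusterNetwork-class] carrying both `conserved` and
#'   `direction` edge columns.
#' @return list with `proportions` (percent opposite: conserved, complete,
#'   nonConserved), `table`, `statistic`, `df`, `pvalue`.
#' @export
compareDirectionProportions <- function(net) {
  e <- net@edges
  if (!all(c("conserved", "direction") %in% names(e)))
    stop("network must carry 'conserved' and 'direction' edge columns; run ",
         "conservedNetwork() and edgeDirectionClasses() first")
  if (!nrow(e)) stop("empty network")
  grp <- factor(ifelse(e$conserved, "conserved", "nonConserved"),
                levels = c("conserved", "nonConserved"))
  tab <- table(grp, factor(e$direction, levels = c("opposite", "same")))
  pct <- function(x) if (sum(x)) 100 * x[["opposite"]] / sum(x) else NA_real_
  props <- c(conserved = pct(tab["conserved", ]),
             complete = pct(colSums(tab)),
             nonConserved = pct(tab["nonConserved", ]))
  stat <- .pearsonChi2(tab)
  list(proportions = props, table = tab, statistic = stat, df = 1L,
       pvalue = pchisq(stat, 1L, lower.tail = FALSE))
}

#' Export a cluster network as an igraph object
#'
#' Bipartite graph with transition-tagged vertex names; requires the igraph
#' package.
#'
#' @param net a [ClusterNetwork-class].
#' @return an igraph graph with edge attributes weight, jaccard and (when
#'   present) conserved and direction.
#' @export
asIgraph <- function(net) {
  if (!requireNamespace("igraph", quietly = TRUE))
    stop("the igraph package is required for asIgraph()")
  e <- net@edges
  d <- data.frame(from = paste0("A_", e$a), to = paste0("B_", e$b),
                  e[, setdiff(names(e), c("a", "b")), drop = FALSE])
  g <- igraph::graph_from_data_frame(d, directed = FALSE)
  igraph::V(g)$type <- startsWith(igraph::V(g)$name, "B_")
  g
}
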
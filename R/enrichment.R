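# Fisher-exact enrichment of trajectory clusters for DEGs, GO terms and
# TFBS-bearing genes, and log-odds PWM scanning of promoter sequences at a
# relative-score threshold.

#' One-sided Fisher enrichment of a cluster for a gene set
#'
#' Hypergeometric upper-tail p-value for over-representation of `target`
#' within `cluster` against `universe`. The odds ratio gets a 0.5 continuity
#' addition to every cell for reporting when any cell is zero (the p-value is
#' unaffected).
#'
#' @param cluster,target gene sets; both must be subsets of `universe`.
#' @param universe gene universe.
#' @return one-row data.frame with the 2 x 2 cells (`inClusterInSet`,
#'   `inClusterNotSet`, `outClusterInSet`, `outClusterNotSet`), `oddsRatio`
#'   and `pvalue`.
#' @export
fisherEnrichment <- function(cluster, target, universe) {
  cluster <- unique(cluster); target <- unique(target)
  universe <- unique(universe)
  if (length(setdiff(cluster, universe)))
    stop("cluster contains genes outside the universe")
  if (length(setdiff(target, universe)))
    stop("target contains genes outside the universe")
  N <- length(universe)
  a <- length(intersect(cluster, target))
  b <- length(cluster) - a
  cc <- length(target) - a
  d <- N - a - b - cc
  p <- phyper(a - 1, length(target), N - length(target), length(cluster),
              lower.tail = FALSE)
  cells <- c(a, b, cc, d)
  if (any(cells == 0)) cells <- cells + 0.5
  or <- (cells[1L] * cells[4L]) / (cells[2L] * cells[3L])
  data.frame(inClusterInSet = a, inClusterNotSet = b, outClusterInSet = cc,
             outClusterNotSet = d, oddsRatio = or, pvalue = p)
}

#' Enrichment of every cluster for every gene set
#'
#' One Fisher test per (cluster, set) pair; Benjamini-Hochberg adjustment is
#' applied within the supplied family (call once per annotation source and
#' per transition). Empty sets are skipped with a warning.
#'
#' @param assign a [ClusterAssignment-class] (or named label vector).
#' @param sets named list of gene sets (term -> genes; see
#'   [invertAnnotation()]), or a single gene set given as a character vector
#'   (named `"set"` in the output).
#' @param universe gene universe (defaults to the clustered genes).
#' @param alpha adjusted-p enrichment cutoff (default 0.05).
#' @return data.frame with columns `cluster`, `set`, the 2 x 2 cells,
#'   `oddsRatio`, `pvalue`, `padj` and `enriched`.
#' @export
enrichAllClusters <- function(assign, sets, universe = NULL, alpha = 0.05) {
  labels <- .labelsOf(assign)
  if (is.null(universe)) universe <- names(labels)
  if (is.character(sets)) sets <- list(set = sets)
  empty <- lengths(sets) == 0L
  if (any(empty)) {
    warning("skipping empty set(s): ", paste(names(sets)[empty], collapse = ", "))
    sets <- sets[!empty]
  }
  clusters <- sort(unique(labels))
  rows <- list()
  for (cl in clusters) {
    members <- names(labels)[labels == cl]
    for (s in names(sets)) {
      r <- fisherEnrichment(members, intersect(sets[[s]], universe), universe)
      rows[[length(rows) + 1L]] <- cbind(
        data.frame(cluster = cl, set = s, stringsAsFactors = FALSE), r)
    }
  }
  out <- do.call(rbind, rows)
  out$padj <- bhAdjust(out$pvalue)
  out$enriched <- out$padj < alpha
  out
}

#' Invert a gene -> terms annotation into term gene sets
#'
#' @param annotation named list gene -> character vector of terms, as read by
#'   [readAnnotationTable()].
#' @return named list term -> character vector of genes, suitable for
#'   [enrichAllClusters()].
#' @export
invertAnnotation <- function(annotation) {
  long <- data.frame(
    gene = rep(names(annotation), lengths(annotation)),
    term = unlist(annotation, use.names = FALSE))
  lapply(split(long$gene, long$term), unique)
}

.BASE_IDX <- setNames(1:5, c("A", "C", "G", "T", "N"))
.COMP_IDX <- c(4L, 3L, 2L, 1L, 5L)   # A<->T, C<->G, N->N

#' Scan a DNA sequence with a position weight matrix
#'
#' Log2-odds scoring against a uniform 0.25 background at every window on
#' both strands; `N` bases contribute the background score (0). The relative
#' score of a window is `(score - minScore) / (maxScore - minScore)` over the
#' achievable score range; windows at or above `threshold` are reported.
#' Positions are 0-based forward-strand coordinates of the window start.
#'
#' @param sequence DNA string (characters ACGT, plus N).
#' @param pwm a [PositionWeightMatrix-class].
#' @param threshold relative-score cutoff in \[0, 1\] (default 0.95,
#'   inclusive).
#' @return data.frame with `position`, `strand` ("+"/"-") and `relScore`.
#' @export
scanPwm <- function(sequence, pwm, threshold = 0.95) {
  sequence <- toupper(as.character(sequence))
  chars <- strsplit(sequence, "")[[1L]]
  idx <- .BASE_IDX[chars]
  if (anyNA(idx))
    stop("invalid characters in sequence: ",
         paste(unique(chars[is.na(idx)]), collapse = ", "))
  L <- rbind(log2(pwmProbs(pwm) / 0.25), N = 0)
  w <- ncol(L)
  n <- length(idx)
  if (n < w) stop("sequence shorter than the motif")
  smax <- sum(apply(L[1:4, , drop = FALSE], 2, max))
  smin <- sum(apply(L[1:4, , drop = FALSE], 2, min))
  rng <- if (smax > smin) smax - smin else 1
  nwin <- n - w + 1L
  pos <- outer(seq_len(nwin), 0:(w - 1L), "+")     # nwin x w base positions
  colIdx <- rep(seq_len(w), each = nwin)
  fwd <- rowSums(matrix(L[cbind(idx[pos], colIdx)], nwin, w))
  # minus strand: motif column j reads the complement of base (start + w - j)
  rcpos <- outer(seq_len(nwin), (w - 1L):0, "+")
  rev <- rowSums(matrix(L[cbind(.COMP_IDX[idx[rcpos]], colIdx)], nwin, w))
  rel <- c((fwd - smin) / rng, (rev - smin) / rng)
  strand <- rep(c("+", "-"), each = nwin)
  position <- rep(seq_len(nwin) - 1L, 2L)
  hit <- rel >= threshold
  data.frame(position = position[hit], strand = strand[hit],
             relScore = rel[hit], stringsAsFactors = FALSE)[
               order(position[hit], strand[hit]), , drop = FALSE]
}

#' Genes whose promoter carries at least one motif hit
#'
#' @param promoters named [Biostrings::DNAStringSet] (or named character
#'   vector), one promoter per gene.
#' @param pwm a [PositionWeightMatrix-class].
#' @param threshold relative-score cutoff (default 0.95, inclusive).
#' @return character vector of gene ids with >= 1 hit.
#' @export
genesWithSite <- function(promoters, pwm, threshold = 0.95) {
  seqs <- as.character(promoters)
  names(seqs)[vapply(seqs, function(s)
    nrow(scanPwm(s, pwm, threshold)) > 0L, logical(1))]
}
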
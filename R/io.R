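#' Read a gene x sample count matrix
#'
#' Parses a tab-separated file whose first column holds gene identifiers and
#' whose header row holds sample identifiers. Cells must be non-negative
#' integers; violations are reported with the offending gene/sample.
#'
#' @param path file path.
#' @return integer matrix with gene rownames and sample colnames, in file
#'   order.
#' @export
readCountMatrix <- function(path) {
  df <- read.delim(path, check.names = FALSE, stringsAsFactors = FALSE)
  gene_ids <- as.character(df[[1L]])
  if (anyDuplicated(gene_ids))
    stop("duplicated gene identifiers: ",
         paste(unique(gene_ids[duplicated(gene_ids)]), collapse = ", "))
  sample_ids <- colnames(df)[-1L]
  if (anyDuplicated(sample_ids))
    stop("duplicated sample identifiers: ",
         paste(unique(sample_ids[duplicated(sample_ids)]), collapse = ", "))
  mat <- as.matrix(df[, -1L, drop = FALSE])
  if (!is.numeric(mat))
    stop("non-numeric entries in count matrix")
  bad <- which(is.na(mat) | mat < 0 | abs(mat - round(mat)) > 1e-8,
               arr.ind = TRUE)
  if (nrow(bad))
    stop(sprintf("invalid count at gene '%s', sample '%s': %s",
                 gene_ids[bad[1L, 1L]], sample_ids[bad[1L, 2L]],
                 mat[bad[1L, , drop = FALSE]]))
  storage.mode(mat) <- "integer"
  dimnames(mat) <- list(gene_ids, sample_ids)
  mat
}

#' Write a count matrix as tab-separated text
#'
#' Inverse of [readCountMatrix()]; round-trips are lossless.
#'
#' @param counts integer matrix with dimnames.
#' @param path output file path.
#' @export
writeCountMatrix <- function(counts, path) {
  df <- data.frame(gene_id = rownames(counts), counts, check.names = FALSE)
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read and validate sample metadata against a count matrix
#'
#' Requires columns `sample_id`, `transition`, `time_h`, `colony_id`;
#' `lineage_id` and `ovary_score` are optional. Controls are coded
#' `time_h = 0`. Every sample of the count matrix must be present exactly
#' once; times outside \{0, 6, 12, 24, 48, 96\} h are rejected.
#'
#' @param path file path of a tab-separated metadata table.
#' @param counts count matrix the metadata binds to.
#' @return data.frame ordered like `colnames(counts)`.
#' @export
readSampleMetadata <- function(path, counts) {
  md <- read.delim(path, check.names = FALSE, stringsAsFactors = FALSE)
  need <- c("sample_id", "transition", "time_h", "colony_id")
  miss <- setdiff(need, colnames(md))
  if (length(miss))
    stop("metadata is missing required columns: ", paste(miss, collapse = ", "))
  md$sample_id <- as.character(md$sample_id)
  if (anyDuplicated(md$sample_id))
    stop("duplicated sample_id in metadata: ",
         paste(unique(md$sample_id[duplicated(md$sample_id)]), collapse = ", "))
  absent <- setdiff(colnames(counts), md$sample_id)
  if (length(absent))
    stop("samples present in counts but missing from metadata: ",
         paste(absent, collapse = ", "))
  if (!all(md$transition %in% VALID_TRANSITIONS))
    stop("transition must be one of: ", paste(VALID_TRANSITIONS, collapse = ", "))
  badt <- setdiff(unique(md$time_h), VALID_TIMES)
  if (length(badt))
    stop("invalid time_h value(s): ", paste(badt, collapse = ", "),
         " (allowed: ", paste(VALID_TIMES, collapse = ", "), ")")
  if ("ovary_score" %in% colnames(md) &&
      any(!is.na(md$ovary_score) & (md$ovary_score < 0 | md$ovary_score > 4)))
    stop("ovary_score must lie in [0, 4]")
  md <- md[match(colnames(counts), md$sample_id), , drop = FALSE]
  rownames(md) <- md$sample_id
  md
}

#' Write sample metadata as tab-separated text
#'
#' @param meta metadata data.frame.
#' @param path output file path.
#' @export
writeSampleMetadata <- function(meta, path) {
  write.table(meta, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Construct a PhaseExperiment from counts and metadata
#'
#' @param counts validated integer count matrix (genes x samples).
#' @param meta metadata data.frame with one row per sample; matched to
#'   `colnames(counts)` via its `sample_id` column.
#' @return a [PhaseExperiment-class].
#' @export
PhaseExperiment <- function(counts, meta) {
  meta <- as.data.frame(meta)
  if (!"sample_id" %in% colnames(meta))
    stop("metadata must contain a sample_id column")
  if (!setequal(meta$sample_id, colnames(counts)))
    stop("metadata samples do not match count matrix samples")
  meta <- meta[match(colnames(counts), meta$sample_id), , drop = FALSE]
  cd <- S4Vectors::DataFrame(meta[, setdiff(colnames(meta), "sample_id"),
                                  drop = FALSE])
  rownames(cd) <- colnames(counts)
  se <- SummarizedExperiment::SummarizedExperiment(
    assays = list(counts = counts), colData = cd)
  new("PhaseExperiment", se)
}

.parseJasparBlock <- function(lines) {
  rows <- lapply(lines, function(l) {
    l <- sub("^[ACGT]\\s*", "", l)
    l <- gsub("\\[|\\]", " ", l)
    as.numeric(strsplit(trimws(l), "\\s+")[[1L]])
  })
  lens <- lengths(rows)
  if (length(unique(lens)) != 1L)
    stop("JASPAR matrix rows have unequal lengths: ",
         paste(lens, collapse = ", "))
  do.call(rbind, rows)
}

#' Read a JASPAR-format position frequency matrix
#'
#' Parses the 4-line JASPAR text format (optionally headed by a `>` line;
#' rows A, C, G, T with bracketed counts), adds a uniform pseudocount and
#' normalizes columns to probabilities.
#'
#' @param path file path.
#' @param pseudocount non-negative count added to every cell before
#'   normalization (default 0.8). Columns with zero probability after the
#'   pseudocount are rejected.
#' @return a [PositionWeightMatrix-class].
#' @export
readJasparPwm <- function(path, pseudocount = 0.8) {
  lines <- trimws(readLines(path))
  lines <- lines[nzchar(lines)]
  name <- "motif"
  if (startsWith(lines[1L], ">")) {
    name <- trimws(sub("^>", "", lines[1L]))
    lines <- lines[-1L]
  }
  if (length(lines) < 4L) stop("expected 4 count rows (A, C, G, T)")
  cnt <- .parseJasparBlock(lines[1:4])
  rownames(cnt) <- c("A", "C", "G", "T")
  if (any(is.na(cnt) | cnt < 0)) stop("counts must be non-negative numbers")
  probs <- sweep(cnt + pseudocount, 2, colSums(cnt + pseudocount), "/")
  if (any(probs <= 0))
    stop("zero probability after pseudocount; use a positive pseudocount")
  new("PositionWeightMatrix", name = name, counts = cnt, probs = probs,
      pseudocount = pseudocount)
}

#' Write a position frequency matrix in JASPAR text format
#'
#' Writes the raw counts so that [readJasparPwm()] with the same pseudocount
#' round-trips the object.
#'
#' @param pwm a [PositionWeightMatrix-class].
#' @param path output file path.
#' @export
writeJasparPwm <- function(pwm, path) {
  stopifnot(is(pwm, "PositionWeightMatrix"))
  cnt <- pwm@counts
  lines <- c(paste0(">", pwm@name),
             vapply(1:4, function(i)
               sprintf("%s  [ %s ]", rownames(cnt)[i],
                       paste(format(cnt[i, ], trim = TRUE), collapse = " ")),
               character(1)))
  writeLines(lines, path)
  invisible(path)
}

#' Read a two-column gene annotation table
#'
#' Tab-separated `gene_id`, `term_id` pairs mapping genes to GO terms or
#' other gene-set labels. Genes absent from the declared universe are
#' rejected; genes of the universe without annotation get empty term sets.
#'
#' @param path file path.
#' @param universe character vector of gene identifiers.
#' @return named list, gene -> character vector of terms.
#' @export
readAnnotationTable <- function(path, universe) {
  df <- read.delim(path, check.names = FALSE, stringsAsFactors = FALSE)
  if (ncol(df) < 2L) stop("annotation table needs two columns (gene, term)")
  genes <- as.character(df[[1L]])
  unknown <- setdiff(genes, universe)
  if (length(unknown))
    stop("annotated genes absent from the universe: ",
         paste(head(unknown, 5L), collapse = ", "))
  ann <- split(as.character(df[[2L]]), genes)
  out <- setNames(vector("list", length(universe)), universe)
  out[names(ann)] <- lapply(ann, unique)
  out[vapply(out, is.null, logical(1))] <- list(character(0))
  out
}

#' Read promoter sequences from a FASTA file
#'
#' @param path FASTA file with one sequence per gene, named by gene id.
#' @return a [Biostrings::DNAStringSet].
#' @export
readPromoters <- function(path) Biostrings::readDNAStringSet(path)

#' Write promoter sequences to a FASTA file
#'
#' @param seqs a named [Biostrings::DNAStringSet] (or named character vector).
#' @param path output file path.
#' @export
writePromoters <- function(seqs, path) {
  if (is.character(seqs)) seqs <- Biostrings::DNAStringSet(seqs)
  Biostrings::writeXStringSet(seqs, path)
  invisible(path)
}

#' Read a YAML pipeline configuration
#'
#' One section per analysis stage; missing sections fall back to defaults.
#'
#' @param path YAML file path.
#' @return named list of configuration sections.
#' @export
readPipelineConfig <- function(path) yaml::read_yaml(path)

#' Append a machine-readable run-log record
#'
#' Writes one JSON object per line (seed, parameters, package version,
#' timestamp) so that runs can be audited and replayed.
#'
#' @param path log file path (created if absent).
#' @param event short event label.
#' @param ... named scalar parameters to record.
#' @export
logRun <- function(path, event, ...) {
  rec <- c(list(time = format(Sys.time(), "%Y-%m-%dT%H:%M:%S"),
                package = as.character(utils::packageVersion("phasecycle")),
                event = event), list(...))
  cat(jsonlite::toJSON(rec, auto_unbox = TRUE), "\n",
      file = path, append = TRUE, sep = "")
  invisible(path)
}
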
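#' Counts per million
#'
#' Scales each sample (column) so that its counts sum to one million.
#'
#' @param counts Non-negative gene-by-sample matrix, or a
#'   [CyclePhaseExperiment-class].
#' @param log If `TRUE`, return `log2(CPM + pseudocount)` instead of
#'   linear CPM.
#' @param pseudocount Added before the log (default 0.5, avoiding
#'   `log(0)`). Ignored when `log = FALSE`.
#' @return Matrix of the same shape as `counts`.
#' @examples
#' computeCPM(matrix(c(1, 1, 2), ncol = 1))
#' @export
computeCPM <- function(counts, log = FALSE, pseudocount = 0.5) {
  if (is(counts, "SummarizedExperiment")) counts <- assay(counts, "counts")
  counts <- as.matrix(counts)
  if (any(counts < 0)) stop("counts must be non-negative")
  tot <- colSums(counts)
  zero <- tot == 0
  if (any(zero))
    stop("all-zero sample(s): ",
         paste(colnames(counts)[zero] %||% which(zero), collapse = ", "))
  cpm <- sweep(counts, 2, tot / 1e6, "/")
  if (log) log2(cpm + pseudocount) else cpm
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Length-normalised expression rescaled to one million per sample
#'
#' Divides each gene's count by its length and rescales every sample so
#' the length-normalised values sum to one million. Note this is the
#' per-sample-rescaled variant, not classic RPKM (which divides CPM by
#' kilobases without rescaling).
#'
#' @param counts Gene-by-sample matrix, or a
#'   [CyclePhaseExperiment-class] with a `length` column in its
#'   `rowData`.
#' @param geneLength Gene lengths in bp, one per row (taken from
#'   `rowData` when `counts` is a `CyclePhaseExperiment`).
#' @return Matrix of the same shape as `counts`; each column sums to 1e6.
#' @export
computeRPKM <- function(counts, geneLength = NULL) {
  if (is(counts, "SummarizedExperiment")) {
    if (is.null(geneLength)) geneLength <- rowData(counts)$length
    counts <- assay(counts, "counts")
  }
  counts <- as.matrix(counts)
  if (is.null(geneLength))
    stop("gene lengths are required for RPKM normalisation")
  if (length(geneLength) != nrow(counts) || any(!(geneLength > 0)))
    stop("geneLength must be positive, one value per gene")
  v <- counts / geneLength
  tot <- colSums(v)
  zero <- tot == 0
  if (any(zero))
    stop("all-zero sample(s): ",
         paste(colnames(counts)[zero] %||% which(zero), collapse = ", "))
  sweep(v, 2, tot / 1e6, "/")
}
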
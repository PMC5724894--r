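#' @importFrom methods setClass setValidity new validObject is callNextMethod
#' @importFrom S4Vectors DataFrame metadata metadata<-
#' @import SummarizedExperiment
NULL

PHASE_LEVELS <- c("G1", "S", "G2M")

#' Container for phase-sorted count data
#'
#' A `CyclePhaseExperiment` is a
#' [SummarizedExperiment::SummarizedExperiment] whose columns are
#' phase-sorted RNA-seq samples. The `colData` must carry a `phase` factor
#' with all three levels `G1`, `S`, `G2M` present, and the first assay
#' (`counts`) must be a non-negative numeric matrix. Optional `colData`
#' columns are `replicate` and `batch`; an optional `rowData` column
#' `length` holds gene lengths in base pairs (used by [computeRPKM()]).
#'
#' @seealso [CyclePhaseExperiment()] for construction from a raw matrix
#'   and a design table; [simulateCycleCounts()] which returns one with
#'   ground-truth `rowData`.
#' @export
setClass("CyclePhaseExperiment", contains = "SummarizedExperiment")

setValidity("CyclePhaseExperiment", function(object) {
  msg <- character()
  if (!"counts" %in% assayNames(object))
    msg <- c(msg, "assay 'counts' is required")
  else {
    cnt <- assay(object, "counts")
    if (!is.numeric(cnt) || any(cnt < 0, na.rm = TRUE))
      msg <- c(msg, "counts must be a non-negative numeric matrix")
  }
  cd <- colData(object)
  if (!"phase" %in% colnames(cd)) {
    msg <- c(msg, "colData must contain a 'phase' column")
  } else {
    ph <- as.character(cd$phase)
    bad <- setdiff(unique(ph), PHASE_LEVELS)
    if (length(bad))
      msg <- c(msg, paste0("unknown phase label(s): ",
                           paste(bad, collapse = ", ")))
    missing <- setdiff(PHASE_LEVELS, unique(ph))
    if (length(missing))
      msg <- c(msg, paste0("phase(s) absent from design: ",
                           paste(missing, collapse = ", ")))
  }
  if (length(msg)) msg else TRUE
})

#' Construct a CyclePhaseExperiment
#'
#' Bundles a gene-by-sample count matrix with a design table assigning
#' each sample to one of the three ordered cell-cycle phases.
#'
#' @param counts Non-negative integer matrix, genes in rows (rownames are
#'   gene identifiers), samples in columns.
#' @param design A `data.frame` or `DataFrame` with one row per sample and
#'   columns `sample_id`, `phase` (`G1`/`S`/`G2M`), and optionally
#'   `replicate` and `batch`. Rows are matched to count columns by
#'   `sample_id` (or by position when count columns are unnamed).
#' @param geneLength Optional numeric vector of gene lengths (bp), one per
#'   row of `counts`.
#' @return A [CyclePhaseExperiment-class] object.
#' @examples
#' cnt <- matrix(rpois(30, 50), nrow = 5,
#'               dimnames = list(paste0("g", 1:5), paste0("s", 1:6)))
#' des <- data.frame(sample_id = paste0("s", 1:6),
#'                   phase = rep(c("G1", "S", "G2M"), each = 2),
#'                   replicate = rep(1:2, 3))
#' cpe <- CyclePhaseExperiment(cnt, des)
#' @export
CyclePhaseExperiment <- function(counts, design, geneLength = NULL) {
  counts <- as.matrix(counts)
  design <- as.data.frame(design)
  if (!all(c("sample_id", "phase") %in% colnames(design)))
    stop("design must have columns 'sample_id' and 'phase'")
  if (nrow(design) != ncol(counts))
    stop("design has ", nrow(design), " rows but counts has ",
         ncol(counts), " columns")
  if (!is.null(colnames(counts))) {
    idx <- match(colnames(counts), design$sample_id)
    if (anyNA(idx))
      stop("samples missing from design: ",
           paste(colnames(counts)[is.na(idx)], collapse = ", "))
    design <- design[idx, , drop = FALSE]
  } else {
    colnames(counts) <- as.character(design$sample_id)
  }
  cd <- DataFrame(design, row.names = as.character(design$sample_id))
  cd$phase <- factor(as.character(cd$phase), levels = PHASE_LEVELS)
  rd <- DataFrame(row.names = rownames(counts))
  if (!is.null(geneLength)) {
    if (length(geneLength) != nrow(counts))
      stop("geneLength must have one entry per gene")
    rd$length <- as.numeric(geneLength)
  }
  se <- SummarizedExperiment(assays = list(counts = counts),
                             colData = cd, rowData = rd)
  new("CyclePhaseExperiment", se)
}

#' Per-gene polar pattern descriptors
#'
#' A `TriCompResult` is a [S4Vectors::DataFrame] with one row per gene and
#' the columns `gene_id`, `d21`, `d31` (log2 fold changes of group 2 and
#' group 3 over group 1), `p`, `q` (plane coordinates, log2 units), `r`
#' (pattern magnitude, log2 units), `theta` (degrees in `[0, 360)`,
#' clockwise from straight up; `NA` when `r == 0`) and `category`
#' (integer 1-6; `NA` when `theta` is undefined).
#'
#' @seealso [triComp()], the constructor-transform; accessors [theta()],
#'   [radius()], [categories()].
#' @export
setClass("TriCompResult", contains = "DFrame")

.TRICOMP_COLS <- c("gene_id", "d21", "d31", "p", "q", "r", "theta",
                   "category")

setValidity("TriCompResult", function(object) {
  msg <- character()
  missing <- setdiff(.TRICOMP_COLS, colnames(object))
  if (length(missing))
    return(paste0("missing column(s): ", paste(missing, collapse = ", ")))
  th <- object$theta
  ok <- is.na(th) | (th >= 0 & th < 360)
  if (!all(ok)) msg <- c(msg, "theta must lie in [0, 360) or be NA")
  if (any(object$r < 0, na.rm = TRUE)) msg <- c(msg, "r must be >= 0")
  if (!all(is.na(th) == (object$r == 0)))
    msg <- c(msg, "theta must be NA exactly when r is 0")
  cat_ok <- is.na(object$category) |
    (object$category %in% 1:6 & !is.na(th))
  if (!all(cat_ok)) msg <- c(msg, "category must be 1..6 or NA")
  if (length(msg)) msg else TRUE
})

setMethod("show", "TriCompResult", function(object) {
  ndef <- sum(!is.na(object$theta))
  cat(sprintf("TriCompResult with %d genes (%d with defined theta)\n",
              nrow(object), ndef))
  callNextMethod()
})
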
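# Tabular readers/writers. TSV is canonical; CSV is accepted on read by
# sniffing the delimiter of the header line. Readers validate and refuse
# to coerce; "NA" encodes an undefined theta/category.

.sniff_delim <- function(path) {
  first <- readLines(path, n = 1L)
  if (length(first) == 0) stop("empty file: ", path)
  if (grepl("\t", first)) "\t"
  else if (grepl(",", first)) ","
  else "\t"
}

.read_table <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  d <- .sniff_delim(path)
  df <- utils::read.table(path, header = TRUE, sep = d,
                          stringsAsFactors = FALSE, check.names = FALSE,
                          quote = "\"", comment.char = "")
  names(df) <- trimws(names(df))
  df
}

#' Read a gene-by-sample count matrix
#'
#' First column holds gene identifiers; remaining numeric columns are
#' samples. A column named `length` (case-insensitive) is treated as
#' gene length and attached as the `"geneLength"` attribute.
#'
#' @param path TSV or CSV file (delimiter sniffed from the header).
#' @return Integer matrix with gene rownames; gene lengths, if present,
#'   in `attr(, "geneLength")`.
#' @export
readCounts <- function(path) {
  df <- .read_table(path)
  if (ncol(df) < 2) stop("counts file needs a gene column plus samples")
  gid <- trimws(as.character(df[[1]]))
  dup <- unique(gid[duplicated(gid)])
  if (length(dup))
    stop("duplicate gene id(s): ", paste(dup, collapse = ", "))
  body <- df[, -1, drop = FALSE]
  lenCol <- which(tolower(names(body)) == "length")
  geneLength <- NULL
  if (length(lenCol)) {
    geneLength <- as.numeric(body[[lenCol[1]]])
    body <- body[, -lenCol, drop = FALSE]
  }
  for (j in seq_along(body)) {
    v <- body[[j]]
    if (!is.numeric(v))
      stop("non-numeric counts in column '", names(body)[j], "'")
    off <- which(v != round(v) | v < 0)
    if (length(off))
      stop("non-integer or negative count at row ", off[1],
           ", column '", names(body)[j], "'")
  }
  m <- as.matrix(body)
  storage.mode(m) <- "integer"
  rownames(m) <- gid
  if (!is.null(geneLength)) attr(m, "geneLength") <- geneLength
  m
}

#' Read a sample design table
#'
#' Requires columns `sample_id` and `phase` (values `G1`, `S`, `G2M`);
#' `replicate` and `batch` are kept when present, other columns are
#' preserved.
#'
#' @param path TSV or CSV file.
#' @return A `data.frame`, one row per sample.
#' @export
readDesign <- function(path) {
  df <- .read_table(path)
  need <- c("sample_id", "phase")
  missing <- setdiff(need, names(df))
  if (length(missing))
    stop("design file missing column(s): ",
         paste(missing, collapse = ", "))
  df$sample_id <- trimws(as.character(df$sample_id))
  df$phase <- trimws(as.character(df$phase))
  bad <- setdiff(unique(df$phase), PHASE_LEVELS)
  if (length(bad))
    stop("unknown phase label(s): ", paste(bad, collapse = ", "),
         " (expected G1, S, G2M)")
  df
}

#' Read a precomputed differential-expression table
#'
#' Ingests a per-gene statistics table in the style produced by an
#' edgeR ANOVA-like three-group analysis: gene id, the two log2 fold
#' changes versus G1, average logCPM, p value and FDR, under arbitrary
#' header names resolved through `columnMap`. `highest_logFC` is derived
#' as the largest pairwise absolute log2 difference among the three
#' phases (`max(|d21|, |d31|, |d31 - d21|)`) and `max_fc` as its linear
#' ratio.
#'
#' @param path TSV or CSV file.
#' @param columnMap Named character vector mapping the roles `gene_id`,
#'   `d21`, `d31`, `ave_logCPM`, `p_value`, `fdr` to the file's column
#'   names. Defaults match edgeR's
#'   `c(gene_id = <first column>, d21 = "logFC.S", d31 = "logFC.G2M",
#'   ave_logCPM = "logCPM", p_value = "PValue", fdr = "FDR")`.
#' @return A [S4Vectors::DataFrame] with standard columns plus any extra
#'   input columns.
#' @export
readDETable <- function(path, columnMap = NULL) {
  df <- .read_table(path)
  defaults <- c(gene_id = names(df)[1], d21 = "logFC.S",
                d31 = "logFC.G2M", ave_logCPM = "logCPM",
                p_value = "PValue", fdr = "FDR")
  map <- defaults
  if (!is.null(columnMap)) map[names(columnMap)] <- columnMap
  roles <- c("gene_id", "d21", "d31", "ave_logCPM", "p_value", "fdr")
  unresolved <- roles[!map[roles] %in% names(df)]
  if (length(unresolved))
    stop("cannot resolve column(s) for role(s): ",
         paste(unresolved, collapse = ", "))
  out <- DataFrame(gene_id = trimws(as.character(df[[map["gene_id"]]])),
                   d21 = as.numeric(df[[map["d21"]]]),
                   d31 = as.numeric(df[[map["d31"]]]),
                   ave_logCPM = as.numeric(df[[map["ave_logCPM"]]]),
                   p_value = as.numeric(df[[map["p_value"]]]),
                   fdr = as.numeric(df[[map["fdr"]]]))
  out$highest_logFC <- pmax(abs(out$d21), abs(out$d31),
                            abs(out$d31 - out$d21))
  out$max_fc <- 2^out$highest_logFC
  extra <- setdiff(names(df), c(map[roles]))
  for (nm in extra) out[[nm]] <- df[[nm]]
  rownames(out) <- out$gene_id
  out
}

#' Read gene sets from a GMT file
#'
#' Standard GMT: one set per line, tab-separated fields `name`,
#' `description`, then member identifiers. Duplicate members within a
#' set are collapsed with a warning; a line with fewer than three fields
#' is an error naming the line.
#'
#' @param path GMT file.
#' @return Named list of character vectors; set descriptions in
#'   `attr(, "description")`.
#' @export
readGMT <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines))]
  sets <- list()
  desc <- character()
  for (i in seq_along(lines)) {
    f <- strsplit(lines[i], "\t", fixed = TRUE)[[1]]
    if (length(f) < 3)
      stop("GMT line ", i, " has fewer than 3 tab-separated fields")
    members <- trimws(f[-(1:2)])
    members <- members[nzchar(members)]
    if (anyDuplicated(members)) {
      warning("duplicate members in set '", f[1], "' collapsed")
      members <- unique(members)
    }
    sets[[trimws(f[1])]] <- members
    desc[trimws(f[1])] <- f[2]
  }
  attr(sets, "description") <- desc
  sets
}

#' Write / read a per-gene polar results table
#'
#' Writes a TSV with columns `gene_id`, `logFC_2v1`, `logFC_3v1`,
#' `p_plane`, `q_plane`, `r`, `theta_deg`, `category`, plus
#' `ave_logCPM`, `max_fc`, `p_value`, `fdr`, `pass_filter` when a DE
#' table is supplied. `theta_deg` carries 4 decimals; undefined theta
#' and category are written as `NA`.
#'
#' @param polar A [TriCompResult-class].
#' @param path Output TSV path.
#' @param de Optional DE table (from [phaseDE()] / [readDETable()],
#'   possibly after [stringencyFilter()] with `drop = FALSE`) joined by
#'   `gene_id`.
#' @return `path`, invisibly.
#' @export
writePolarTable <- function(polar, path, de = NULL) {
  out <- data.frame(gene_id = polar$gene_id,
                    logFC_2v1 = polar$d21, logFC_3v1 = polar$d31,
                    p_plane = polar$p, q_plane = polar$q, r = polar$r,
                    theta_deg = ifelse(is.na(polar$theta), NA,
                                       round(polar$theta, 4)),
                    category = polar$category)
  if (!is.null(de)) {
    de <- as.data.frame(de)
    keep <- intersect(c("gene_id", "ave_logCPM", "max_fc", "p_value",
                        "fdr", "pass_filter"), colnames(de))
    out <- merge(out, de[, keep, drop = FALSE], by = "gene_id",
                 all.x = TRUE, sort = FALSE)
  }
  tryCatch(
    suppressWarnings(
      utils::write.table(out, path, sep = "\t", quote = FALSE,
                         row.names = FALSE, na = "NA")),
    error = function(e) stop("cannot write '", path, "': ",
                             conditionMessage(e)))
  invisible(path)
}

#' @rdname writePolarTable
#' @export
readPolarTable <- function(path) {
  df <- .read_table(path)
  need <- c("gene_id", "logFC_2v1", "logFC_3v1", "p_plane", "q_plane",
            "r", "theta_deg", "category")
  missing <- setdiff(need, names(df))
  if (length(missing))
    stop("polar table missing column(s): ",
         paste(missing, collapse = ", "))
  DataFrame(df)
}

#' Write a simulated dataset as plain TSV files
#'
#' Writes `counts.tsv` (with a `length` column when lengths are known),
#' `design.tsv` and, for simulated data, `truth.tsv` into a directory.
#'
#' @param cpe A [CyclePhaseExperiment-class].
#' @param dir Output directory (created if needed).
#' @return The directory path, invisibly.
#' @export
writeCycleExperiment <- function(cpe, dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  cnt <- as.data.frame(assay(cpe, "counts"))
  rd <- rowData(cpe)
  tab <- data.frame(gene_id = rownames(cpe))
  if ("length" %in% colnames(rd)) tab$length <- rd$length
  tab <- cbind(tab, cnt)
  utils::write.table(tab, file.path(dir, "counts.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  utils::write.table(as.data.frame(colData(cpe)),
                     file.path(dir, "design.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  truthCols <- intersect(c("oscillating", "theta_star", "amplitude",
                           "baseline", "category_star"), colnames(rd))
  if (length(truthCols)) {
    truth <- cbind(data.frame(gene_id = rownames(cpe)),
                   as.data.frame(rd[, truthCols, drop = FALSE]))
    utils::write.table(truth, file.path(dir, "truth.tsv"), sep = "\t",
                       quote = FALSE, row.names = FALSE)
  }
  invisible(dir)
}
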
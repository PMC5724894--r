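# Lightweight three-group test
# ----------------------------
# A per-gene one-way ANOVA of log2(CPM + 0.5) across the three phases,
# with optional within-batch mean-centering standing in for an additive
# "+ Batch" model term. With few replicates per phase the per-gene
# variance estimate is very noisy (6 residual df at 3 replicates), so by
# default the variances are squeezed toward an abundance-dependent trend
# with empirical Bayes (limma::squeezeVar) before forming the F
# statistic; `moderate = FALSE` gives the textbook per-gene ANOVA.
# Studies wanting a full negative-binomial GLM (edgeR-style) can import
# that table via readDETable() and feed it straight to triComp().

.batch_center <- function(m, batch) {
  grand <- rowMeans(m)
  for (b in unique(batch)) {
    j <- batch == b
    m[, j] <- m[, j] - rowMeans(m[, j, drop = FALSE])
  }
  m + grand
}

#' Per-gene one-way ANOVA across the three phases
#'
#' Computes, for every gene, the F statistic and p value of a one-way
#' ANOVA of `log2(CPM + 0.5)` across the G1/S/G2M groups, the two log2
#' fold changes of the phase means relative to G1, the mean expression,
#' and the largest pairwise fold change among the three phase means.
#' P values are Benjamini-Hochberg adjusted across genes.
#'
#' When a `batch` column is present (and `batchCenter = TRUE`), each
#' gene's values are mean-centered within batch (grand mean restored)
#' before testing, and the residual degrees of freedom are reduced by the
#' number of batches minus one.
#'
#' With `moderate = TRUE` (the default) the per-gene residual variances
#' are shrunk toward a mean-expression trend with empirical Bayes
#' (`limma::squeezeVar`) and the F statistic uses the posterior variance
#' with correspondingly augmented denominator degrees of freedom. This
#' borrows strength across genes the same way the variance shrinkage in
#' negative-binomial RNA-seq GLMs does and is essential for power at
#' 2-3 replicates per phase; `moderate = FALSE` is the plain per-gene
#' one-way ANOVA.
#'
#' @param x A [CyclePhaseExperiment-class], or a matrix of
#'   `log2(CPM + 0.5)` values (then `design` is required).
#' @param design Data frame with `phase` (and optionally `batch`)
#'   columns, one row per sample; ignored when `x` is a
#'   `CyclePhaseExperiment`.
#' @param batchCenter Center within batches when batch labels are
#'   available (default `TRUE`).
#' @param moderate Use empirical-Bayes variance moderation (default
#'   `TRUE`).
#' @return A [S4Vectors::DataFrame] with columns `gene_id`, `d21`, `d31`,
#'   `ave_logCPM`, `highest_logFC`, `max_fc`, `F`, `p_value`, `fdr` and
#'   `degenerate` (`TRUE` where the within-group variance was exactly
#'   zero while group means differed; those p values are reported as the
#'   smallest positive double rather than zero).
#' @examples
#' cpe <- simulateCycleCounts(simConfig(nGenes = 50, seed = 1))
#' head(phaseDE(cpe))
#' @export
phaseDE <- function(x, design = NULL, batchCenter = TRUE,
                    moderate = TRUE) {
  if (is(x, "CyclePhaseExperiment")) {
    design <- as.data.frame(colData(x))
    le <- computeCPM(assay(x, "counts"), log = TRUE)
  } else {
    if (is.null(design)) stop("a design table is required")
    le <- as.matrix(x)
  }
  ph <- as.character(design$phase)
  if (!all(PHASE_LEVELS %in% ph))
    stop("all three phases (G1, S, G2M) must be present")
  nPer <- table(factor(ph, PHASE_LEVELS))
  if (any(nPer < 2))
    stop("need at least 2 replicates per phase; got ",
         paste(nPer, collapse = "/"))

  nBatch <- 1L
  if (batchCenter && "batch" %in% colnames(design)) {
    batch <- as.character(design$batch)
    nBatch <- length(unique(batch))
    if (nBatch > 1L) le <- .batch_center(le, batch)
  }

  n <- ncol(le)
  grand <- rowMeans(le)
  means <- vapply(PHASE_LEVELS, function(g)
    rowMeans(le[, ph == g, drop = FALSE]), numeric(nrow(le)))
  ssb <- numeric(nrow(le))
  for (g in PHASE_LEVELS)
    ssb <- ssb + nPer[[g]] * (means[, g] - grand)^2
  fitted <- means[, ph, drop = FALSE]
  ssw <- rowSums((le - fitted)^2)

  dfb <- 2L
  dfw <- n - 3L - (nBatch - 1L)
  if (dfw < 1L) stop("not enough residual degrees of freedom")
  if (moderate) {
    sq <- limma::squeezeVar(ssw / dfw, df = dfw, covariate = grand)
    dfTotal <- dfw + sq$df.prior
    Fstat <- (ssb / dfb) / sq$var.post
  } else {
    dfTotal <- dfw
    Fstat <- (ssb / dfb) / (ssw / dfw)
  }
  p <- stats::pf(Fstat, dfb, dfTotal, lower.tail = FALSE)

  degenerate <- !moderate & ssw == 0 & ssb > 0
  p[degenerate] <- .Machine$double.xmin
  flat <- ssw == 0 & ssb == 0
  Fstat[flat] <- 0
  p[flat] <- 1

  hi <- apply(means, 1, max) - apply(means, 1, min)
  out <- DataFrame(gene_id = rownames(le) %||%
                     paste0("gene", seq_len(nrow(le))),
                   d21 = unname(means[, "S"] - means[, "G1"]),
                   d31 = unname(means[, "G2M"] - means[, "G1"]),
                   ave_logCPM = unname(grand),
                   highest_logFC = unname(hi),
                   max_fc = unname(2^hi),
                   F = unname(Fstat),
                   p_value = unname(p),
                   fdr = unname(bhFDR(p)),
                   degenerate = unname(degenerate))
  rownames(out) <- out$gene_id
  out
}

#' Benjamini-Hochberg adjusted p values
#'
#' Thin validating wrapper around `stats::p.adjust(method = "BH")`.
#'
#' @param p Numeric vector of p values in `[0, 1]`.
#' @return Adjusted values (q values), capped at 1.
#' @export
bhFDR <- function(p) {
  if (any(!is.finite(p)) || any(p < 0 | p > 1))
    stop("p values must be finite and in [0, 1]")
  stats::p.adjust(p, method = "BH")
}

#' Stringency filter on significance, expression and effect size
#'
#' Keeps genes with `fdr <= fdrMax`, `ave_logCPM >= logcpmMin` and
#' `max_fc >= fcMin` — the three-way stringency cut used to call a gene
#' significantly oscillating.
#'
#' @param de A `DataFrame`/`data.frame` with columns `fdr`, `ave_logCPM`
#'   and `max_fc` (as produced by [phaseDE()] or [readDETable()]).
#' @param fdrMax,logcpmMin,fcMin Thresholds; defaults 0.001, 1 and 1.5.
#'   `fcMin` is a linear-scale ratio and must be `>= 1`.
#' @param drop If `TRUE` (default) return only passing rows; otherwise
#'   return all rows with a `pass_filter` column added.
#' @return Filtered table; per-criterion attrition counts are attached as
#'   `metadata(x)$attrition` (and as `attr(x, "attrition")` for plain
#'   data frames).
#' @export
stringencyFilter <- function(de, fdrMax = 0.001, logcpmMin = 1,
                             fcMin = 1.5, drop = TRUE) {
  need <- c("fdr", "ave_logCPM", "max_fc")
  missing <- setdiff(need, colnames(de))
  if (length(missing))
    stop("missing column(s): ", paste(missing, collapse = ", "))
  if (fdrMax < 0 || fcMin < 1)
    stop("need fdrMax >= 0 and fcMin >= 1")
  okF <- de$fdr <= fdrMax
  okC <- de$ave_logCPM >= logcpmMin
  okE <- de$max_fc >= fcMin
  pass <- okF & okC & okE
  attrition <- c(n_input = nrow(de),
                 fail_fdr = sum(!okF), fail_logcpm = sum(!okC),
                 fail_fc = sum(!okE), n_pass = sum(pass))
  out <- de
  out$pass_filter <- pass
  if (drop) out <- out[pass, , drop = FALSE]
  if (is(out, "DataFrame")) metadata(out)$attrition <- attrition
  else attr(out, "attrition") <- attrition
  out
}
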
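# Geometry of the transform
# -------------------------
# Each gene's centered log2 profile (c1, c2, c3), sum(c) = 0, is projected
# onto three unit axes 120 degrees apart: G1 at 30, S at 150, G2/M at 270
# degrees, angles measured clockwise from straight up. The resulting plane
# point (p, q) has closed form
#     p = 0.5 * d21 - d31,   q = -(sqrt(3)/2) * d21
# with d21 = log2(e2/e1), d31 = log2(e3/e1). theta is the clockwise angle
# of (p, q) from the +q axis, so a gene peaking purely in G1 sits at 30
# degrees (the center of category 1), purely in S at 150, purely in G2/M
# at 270. r = sqrt(p^2 + q^2) = sqrt(d21^2 + d31^2 - d21*d31).

AXIS_DEG <- c(G1 = 30, S = 150, G2M = 270)

.check_positive <- function(e1, e2, e3, geneId = NULL, caller = "value") {
  bad <- !(e1 > 0 & e2 > 0 & e3 > 0)
  bad[is.na(bad)] <- TRUE
  if (any(bad)) {
    who <- if (!is.null(geneId)) paste(geneId[bad], collapse = ", ")
           else paste(which(bad), collapse = ", ")
    stop("expression levels must be positive (", caller, "): ", who)
  }
  invisible(TRUE)
}

#' Log2 fold changes of groups 2 and 3 over group 1
#'
#' @param e1,e2,e3 Positive expression levels on the linear scale for the
#'   three ordered groups (G1, S, G2/M). Vectorised.
#' @param geneId Optional gene identifiers used in error messages.
#' @return A two-column matrix with columns `d21 = log2(e2/e1)` and
#'   `d31 = log2(e3/e1)`.
#' @examples
#' logFoldChanges(1, 2, 4)  # 1, 2
#' @export
logFoldChanges <- function(e1, e2, e3, geneId = NULL) {
  .check_positive(e1, e2, e3, geneId, "logFoldChanges")
  cbind(d21 = log2(e2 / e1), d31 = log2(e3 / e1))
}

#' Project log2 fold changes onto the pattern plane
#'
#' Places the centered log2 profile of a gene on three unit axes 120
#' degrees apart (G1 at 30, S at 150, G2/M at 270 degrees clockwise from
#' up) and sums; equivalently `p = 0.5*d21 - d31`, `q = -(sqrt(3)/2)*d21`.
#'
#' @param d21,d31 Log2 fold changes of group 2 resp. group 3 over group 1.
#'   Vectorised; must be finite.
#' @return Two-column matrix of plane coordinates `p` (rightward) and `q`
#'   (upward), in log2 units.
#' @examples
#' triCompProject(1, 2)  # -1.5, -sqrt(3)/2
#' @export
triCompProject <- function(d21, d31) {
  stopifnot(all(is.finite(d21)), all(is.finite(d31)))
  cbind(p = 0.5 * d21 - d31, q = -(sqrt(3) / 2) * d21)
}

#' Polar coordinates of a plane point, clockwise from up
#'
#' @param p,q Plane coordinates (see [triCompProject()]). Vectorised.
#' @return Two-column matrix with `r = sqrt(p^2 + q^2)` and `theta`, the
#'   clockwise angle from the `+q` ("up") direction in degrees, reduced to
#'   `[0, 360)`. `theta` is `NA` where `r == 0` (a flat gene has no
#'   pattern direction).
#' @examples
#' polarFromPlane(0, 1)  # r = 1, theta = 0
#' polarFromPlane(1, 0)  # r = 1, theta = 90
#' @export
polarFromPlane <- function(p, q) {
  stopifnot(all(is.finite(p)), all(is.finite(q)))
  r <- sqrt(p^2 + q^2)
  th <- (atan2(p, q) * 180 / pi) %% 360
  th[r == 0] <- NA_real_
  cbind(r = r, theta = th)
}

#' Assign a 60-degree pattern category
#'
#' Bins `theta` into six half-open 60-degree sectors,
#' `category = floor(theta/60) + 1`; a boundary angle belongs to the
#' higher-numbered bin (60 degrees is category 2). Odd categories are
#' single-phase peaks (1 = G1, 3 = S, 5 = G2/M); even categories are highs
#' in two consecutive phases (2 = G1+S, 4 = S+G2/M, 6 = G2/M+G1).
#'
#' @param theta Angles in degrees, each in `[0, 360)` or `NA` (undefined,
#'   mapped to `NA`).
#' @return Integer vector of categories 1-6 (`NA` where `theta` is `NA`).
#' @examples
#' assignCategory(c(240, 0, 60, 359.99))  # 5 1 2 6
#' @export
assignCategory <- function(theta) {
  bad <- !is.na(theta) & (theta < 0 | theta >= 360)
  if (any(bad))
    stop("theta outside [0, 360): ",
         paste(format(theta[bad]), collapse = ", "))
  as.integer(floor(theta / 60) + 1)
}

#' Smallest angular difference on the circle
#'
#' @param theta1,theta2 Defined angles in degrees in `[0, 360)`.
#'   Vectorised.
#' @return Differences in degrees, each in `[0, 180]`.
#' @examples
#' circularDifference(350, 10)  # 20
#' @export
circularDifference <- function(theta1, theta2) {
  if (anyNA(theta1) || anyNA(theta2))
    stop("circularDifference requires defined angles; filter NA first")
  if (any(theta1 < 0 | theta1 >= 360 | theta2 < 0 | theta2 >= 360))
    stop("angles must lie in [0, 360)")
  d <- abs(theta1 - theta2) %% 360
  pmin(d, 360 - d)
}

#' Largest pairwise fold change among three groups
#'
#' @inheritParams logFoldChanges
#' @return `max(e1, e2, e3) / min(e1, e2, e3)`, a linear-scale ratio
#'   `>= 1`.
#' @examples
#' maxFoldChange(1, 2, 4)  # 4
#' @export
maxFoldChange <- function(e1, e2, e3, geneId = NULL) {
  .check_positive(e1, e2, e3, geneId, "maxFoldChange")
  pmax(e1, e2, e3) / pmin(e1, e2, e3)
}

.tricomp_from_logfc <- function(geneId, d21, d31) {
  pq <- triCompProject(d21, d31)
  rt <- polarFromPlane(pq[, "p"], pq[, "q"])
  df <- DataFrame(gene_id = as.character(geneId),
                  d21 = unname(as.numeric(d21)),
                  d31 = unname(as.numeric(d31)),
                  p = unname(pq[, "p"]), q = unname(pq[, "q"]),
                  r = unname(rt[, "r"]),
                  theta = unname(rt[, "theta"]),
                  category = unname(assignCategory(rt[, "theta"])))
  rownames(df) <- df$gene_id
  new("TriCompResult", df)
}

#' @rdname triComp
#' @param geneId Gene identifiers; defaults to rownames of `x`.
#' @export
setMethod("triComp", "matrix", function(x, geneId = rownames(x), ...) {
  if (ncol(x) != 3)
    stop("expected a gene-by-3 matrix of phase means (G1, S, G2M)")
  if (is.null(geneId)) geneId <- paste0("gene", seq_len(nrow(x)))
  .check_positive(x[, 1], x[, 2], x[, 3], geneId, "triComp")
  fc <- logFoldChanges(x[, 1], x[, 2], x[, 3], geneId)
  .tricomp_from_logfc(geneId, fc[, "d21"], fc[, "d31"])
})

.logfc_cols <- function(x) {
  nm <- colnames(x)
  if (all(c("d21", "d31") %in% nm)) c("d21", "d31")
  else if (all(c("logFC_2v1", "logFC_3v1") %in% nm))
    c("logFC_2v1", "logFC_3v1")
  else stop("need log2 fold change columns 'd21'/'d31' ",
            "(or 'logFC_2v1'/'logFC_3v1')")
}

#' @rdname triComp
#' @export
setMethod("triComp", "data.frame", function(x, ...) {
  cols <- .logfc_cols(x)
  gid <- if ("gene_id" %in% colnames(x)) x$gene_id else rownames(x)
  .tricomp_from_logfc(gid, x[[cols[1]]], x[[cols[2]]])
})

#' @rdname triComp
#' @export
setMethod("triComp", "DFrame", function(x, ...) {
  triComp(as.data.frame(x), ...)
})

#' @rdname triComp
#' @details For a `CyclePhaseExperiment` the per-gene log2 fold changes
#'   are differences of phase means of `log2(CPM + 0.5)`; genes with zero
#'   counts everywhere come out flat (`r = 0`), not as errors.
#' @export
setMethod("triComp", "CyclePhaseExperiment", function(x, ...) {
  le <- computeCPM(assay(x, "counts"), log = TRUE)
  ph <- as.character(colData(x)$phase)
  means <- vapply(PHASE_LEVELS, function(g) {
    rowMeans(le[, ph == g, drop = FALSE])
  }, numeric(nrow(le)))
  d21 <- means[, "S"] - means[, "G1"]
  d31 <- means[, "G2M"] - means[, "G1"]
  .tricomp_from_logfc(rownames(x), d21, d31)
})
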
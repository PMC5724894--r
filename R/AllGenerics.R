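#' @importFrom methods setGeneric setMethod
NULL

#' Polar-coordinate transform of three-group expression patterns
#'
#' `triComp` converts each gene's expression relationship across three
#' ordered groups (G1, S, G2/M) into a pattern angle `theta` and a
#' magnitude `r`. See [triCompProject()] for the geometry.
#'
#' @param x Input object: a numeric gene-by-3 matrix of positive linear
#'   phase means (columns ordered G1, S, G2/M); a
#'   [CyclePhaseExperiment-class] (phase means of `log2(CPM + 0.5)` are
#'   used); or a `data.frame`/`DataFrame` carrying precomputed log2 fold
#'   change columns `d21` and `d31` (e.g. from [readDETable()]), which are
#'   used verbatim.
#' @param ... Passed to methods.
#' @return A [TriCompResult-class] object, one row per gene.
#' @examples
#' m <- rbind(gene1 = c(1, 2, 4), gene2 = c(5, 5, 5))
#' res <- triComp(m)
#' theta(res)  # 240, NA
#' @export
setGeneric("triComp", function(x, ...) standardGeneric("triComp"))

#' @describeIn TriCompResult pattern angle in degrees (`NA` where flat).
#' @param object,x A `TriCompResult`.
#' @export
setGeneric("theta", function(x) standardGeneric("theta"))

#' @describeIn TriCompResult pattern magnitude `r` in log2 units.
#' @export
setGeneric("radius", function(x) standardGeneric("radius"))

#' @describeIn TriCompResult integer pattern category 1-6 (`NA` where
#'   flat).
#' @export
setGeneric("categories", function(x) standardGeneric("categories"))

#' @describeIn TriCompResult two-column matrix of plane coordinates
#'   `(p, q)`.
#' @export
setGeneric("planeCoords", function(x) standardGeneric("planeCoords"))

#' @export
#' @rdname TriCompResult-class
setMethod("theta", "TriCompResult", function(x) {
  stats::setNames(x$theta, x$gene_id)
})

#' @export
#' @rdname TriCompResult-class
setMethod("radius", "TriCompResult", function(x) {
  stats::setNames(x$r, x$gene_id)
})

#' @export
#' @rdname TriCompResult-class
setMethod("categories", "TriCompResult", function(x) {
  stats::setNames(x$category, x$gene_id)
})

#' @export
#' @rdname TriCompResult-class
setMethod("planeCoords", "TriCompResult", function(x) {
  cbind(p = x$p, q = x$q)
})
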
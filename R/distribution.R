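#' Bin pattern angles into the six categories
#'
#' @param thetas Defined angles in degrees in `[0, 360)`. Genes with
#'   undefined (NA) theta must be filtered out first.
#' @return Named integer vector of length 6, counts per category.
#' @examples
#' binTheta(c(30, 90, 150, 210, 270, 330))
#' @export
binTheta <- function(thetas) {
  if (anyNA(thetas))
    stop("undefined theta present; filter flat genes (r = 0) first")
  cat <- assignCategory(thetas)
  stats::setNames(tabulate(cat, nbins = 6L), paste0("cat", 1:6))
}

.as_bins <- function(x, what = "counts") {
  if (is(x, "TriCompResult")) x <- binTheta(x$theta[!is.na(x$theta)])
  x <- as.numeric(x)
  if (length(x) != 6 || any(x < 0))
    stop(what, " must be 6 non-negative bin values")
  x
}

#' G test of a subset's category distribution against a background
#'
#' Log-likelihood-ratio goodness-of-fit test comparing the observed
#' six-bin category counts of a gene subset with the counts expected
#' under the background's category proportions. Bins where both the
#' expected and observed counts are zero are dropped, reducing the
#' degrees of freedom below the nominal 5.
#'
#' @param observed Six observed bin counts (or a
#'   [TriCompResult-class], binned via [binTheta()]).
#' @param background Six background bin counts (same forms accepted).
#' @return An object of class `htest` with the G statistic, degrees of
#'   freedom and chi-square upper-tail p value. If a bin is observed
#'   where the background probability is zero the null is impossible and
#'   `p = 0` is returned with a warning.
#' @examples
#' gTestSubset(c(10, 0, 0, 0, 0, 0), rep(50, 6))
#' @export
gTestSubset <- function(observed, background) {
  O <- .as_bins(observed, "observed")
  B <- .as_bins(background, "background")
  nO <- sum(O)
  nB <- sum(B)
  if (nB <= 0) stop("background must contain at least one gene")
  if (nO <= 0) stop("observed counts are all zero")
  E <- nO * B / nB
  impossible <- O > 0 & E == 0
  keep <- !(O == 0 & E == 0)
  df <- sum(keep) - 1L
  if (any(impossible)) {
    warning("observed genes in categories with zero background ",
            "probability; p = 0")
    G <- Inf
    p <- 0
  } else {
    terms <- ifelse(O[keep] > 0, O[keep] * log(O[keep] / E[keep]), 0)
    G <- 2 * sum(terms)
    # single populated bin: O == E there, no test left
    p <- if (df < 1L) 1 else
      stats::pchisq(G, df = df, lower.tail = FALSE)
  }
  structure(list(statistic = c(G = G), parameter = c(df = df),
                 p.value = p,
                 method = "G test (log-likelihood ratio, six-bin)",
                 data.name = paste0("observed n = ", nO,
                                    " vs background n = ", nB),
                 observed = O, expected = E),
            class = "htest")
}

.compositions <- function(n, k) {
  # all k-part compositions of n, one per row (stars and bars: cut
  # positions chosen among n + k - 1 slots, then differenced)
  if (k == 1L) return(matrix(n, ncol = 1L))
  if (n == 0L) return(matrix(0L, nrow = 1L, ncol = k))
  cuts <- utils::combn(n + k - 1L, k - 1L)
  full <- rbind(0L, cuts, n + k)
  t(full[-1L, , drop = FALSE] -
      full[-nrow(full), , drop = FALSE] - 1L)
}

.with_seed <- function(seed, expr) {
  if (is.null(seed)) return(expr)
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()))
  } else {
    on.exit(rm(".Random.seed", envir = globalenv()))
  }
  set.seed(seed)
  expr
}

#' Exact multinomial goodness-of-fit p value
#'
#' P value of the exact multinomial test under likelihood ordering: the
#' total probability of all outcomes whose multinomial probability is at
#' most that of the observed outcome. Computed by full enumeration of
#' compositions when `n <= exactMax`, and otherwise by a seeded
#' Monte-Carlo estimate whose standard error is reported.
#'
#' @param observed Six observed bin counts (or a
#'   [TriCompResult-class]).
#' @param probs Six null probabilities summing to 1 (within 1e-9).
#' @param exactMax Largest total count for exact enumeration
#'   (default 30).
#' @param nMC Number of Monte-Carlo draws beyond that (default 1e6).
#' @param seed Optional integer seed for the Monte-Carlo branch; the
#'   global RNG state is restored afterwards.
#' @return An `htest` with `p.value`, `estimate` (the p), the method
#'   used, and for Monte Carlo a `stderr` element.
#' @examples
#' exactMultinomialP(c(3, 0, 0, 0, 0, 0), rep(1/6, 6))
#' @export
exactMultinomialP <- function(observed, probs, exactMax = 30,
                              nMC = 1e6, seed = NULL) {
  O <- .as_bins(observed, "observed")
  if (any(O != round(O))) stop("observed counts must be integers")
  probs <- as.numeric(probs)
  if (length(probs) != 6 || any(probs < 0))
    stop("probs must be 6 non-negative values")
  if (abs(sum(probs) - 1) > 1e-9)
    stop("probs must sum to 1 (within 1e-9)")
  n <- sum(O)
  if (O %*% (probs == 0) > 0) {
    res <- list(p.value = 0, method = "exact multinomial (impossible)")
  } else {
    nz <- probs > 0
    k <- sum(nz)
    lp <- log(probs[nz])
    x0 <- O[nz]
    logp_obs <- lgamma(n + 1) - sum(lgamma(x0 + 1)) + sum(x0 * lp)
    tol <- 1e-7
    if (n <= exactMax) {
      X <- .compositions(n, k)
      logp <- lgamma(n + 1) - rowSums(lgamma(X + 1)) +
        as.vector(X %*% lp)
      p <- sum(exp(logp[logp <= logp_obs + tol]))
      p <- min(p, 1)
      res <- list(p.value = p,
                  method = "exact multinomial (full enumeration)")
    } else {
      draws <- .with_seed(seed,
        stats::rmultinom(nMC, size = n, prob = probs[nz]))
      logp <- lgamma(n + 1) - colSums(lgamma(draws + 1)) +
        as.vector(t(draws) %*% lp)
      hits <- logp <= logp_obs + tol
      p <- mean(hits)
      res <- list(p.value = p,
                  stderr = sqrt(p * (1 - p) / nMC),
                  method = sprintf(
                    "exact multinomial (Monte Carlo, %d draws)",
                    as.integer(nMC)))
    }
  }
  structure(c(res,
              list(statistic = c(n = n),
                   data.name = deparse(substitute(observed)))),
            class = "htest")
}

#' Cross-dataset comparison of pattern angles
#'
#' Joins two per-gene polar tables on gene identifier, computes the
#' circular difference of their angles, and reports the fraction of
#' shared genes whose angles differ by less than `deltaMax` degrees.
#'
#' @param a,b [TriCompResult-class] objects (or tables with `gene_id`
#'   and `theta` columns). Genes with undefined theta in either dataset
#'   are excluded.
#' @param deltaMax Concordance threshold in degrees (default 60, one
#'   category width).
#' @return A list with `table` (a `DataFrame` of `gene_id`, `theta_a`,
#'   `theta_b`, `delta_theta`) and `fraction_within`.
#' @export
compareDatasets <- function(a, b, deltaMax = 60) {
  ga <- data.frame(gene_id = a$gene_id, theta_a = a$theta)
  gb <- data.frame(gene_id = b$gene_id, theta_b = b$theta)
  m <- merge(ga, gb, by = "gene_id")
  m <- m[!is.na(m$theta_a) & !is.na(m$theta_b), , drop = FALSE]
  if (nrow(m) == 0)
    stop("no shared genes with defined theta in both datasets")
  m$delta_theta <- circularDifference(m$theta_a, m$theta_b)
  tab <- DataFrame(m[order(m$gene_id), , drop = FALSE])
  rownames(tab) <- tab$gene_id
  list(table = tab,
       fraction_within = mean(tab$delta_theta < deltaMax))
}

#' Map an external periodic phase descriptor onto theta
#'
#' Converts a periodic phase value (e.g. circadian time in hours, or a
#' sinusoidal fit peak in radians) to degrees on the theta circle:
#' `theta = (offsetDeg + direction * 360 * phaseValue / period) mod 360`.
#' Direction and offset are explicit because the alignment between an
#' external clock and the three-phase circle is dataset-specific.
#'
#' @param phaseValue Periodic phase values; vectorised.
#' @param period Period in the same units (e.g. 24 for hours of
#'   circadian time, `2*pi` for radians).
#' @param direction `+1` (default) or `-1`, the rotation sense.
#' @param offsetDeg Offset added in degrees (default 0).
#' @return Angles in degrees in `[0, 360)`.
#' @examples
#' externalPhaseToTheta(6, 24)  # 90
#' @export
externalPhaseToTheta <- function(phaseValue, period, direction = 1,
                                 offsetDeg = 0) {
  if (!(period > 0)) stop("period must be positive")
  if (!direction %in% c(-1, 1)) stop("direction must be +1 or -1")
  (offsetDeg + direction * 360 * phaseValue / period) %% 360
}

#' Category distribution of a gene set versus a background
#'
#' Bins the theta values of a gene set and of a background table into
#' the six categories and tests whether the set's distribution differs
#' from the background's, with both the G test and the exact multinomial
#' test. By default set members are removed from the background before
#' testing so the two samples are disjoint; when removal would empty the
#' background (the set covers everything) it is skipped.
#'
#' @param polar A [TriCompResult-class] (or table with `gene_id`,
#'   `theta`) holding the genes of interest.
#' @param geneSet Character vector of gene identifiers (one element of
#'   the list returned by [readGMT()]).
#' @param background Background polar table (defaults to `polar`).
#' @param removeSubset Remove set members from the background before
#'   testing (default `TRUE`).
#' @param ... Passed to [exactMultinomialP()] (e.g. `seed`).
#' @return A list with `observed` and `background` bin counts, `g_test`
#'   and `exact_test` (`htest` objects), and `n_set`, the number of set
#'   genes found with defined theta.
#' @export
geneSetThetaProfile <- function(polar, geneSet, background = polar,
                                removeSubset = TRUE, ...) {
  geneSet <- unique(as.character(geneSet))
  hit <- polar$gene_id %in% geneSet & !is.na(polar$theta)
  if (!any(hit)) {
    unmatched <- setdiff(geneSet, polar$gene_id)
    stop("no gene-set members with defined theta; unmatched ids: ",
         paste(utils::head(unmatched, 10), collapse = ", "),
         if (length(unmatched) > 10) ", ...")
  }
  sub_theta <- polar$theta[hit]
  bg_keep <- !is.na(background$theta)
  if (removeSubset) {
    remaining <- bg_keep & !(background$gene_id %in% geneSet)
    if (any(remaining)) bg_keep <- remaining
  }
  bg_theta <- background$theta[bg_keep]
  obs <- binTheta(sub_theta)
  bg <- binTheta(bg_theta)
  g <- gTestSubset(obs, bg)
  ex <- exactMultinomialP(obs, bg / sum(bg), ...)
  list(observed = obs, background = bg, g_test = g, exact_test = ex,
       n_set = sum(hit))
}
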
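test_that("theta binning counts per 60-degree sector", {
  expect_identical(binTheta(c(30, 90, 150, 210, 270, 330)),
                   stats::setNames(rep(1L, 6), paste0("cat", 1:6)))
  expect_identical(unname(binTheta(numeric(0))), rep(0L, 6))
  expect_identical(unname(binTheta(60)), c(0L, 1L, 0L, 0L, 0L, 0L))
  expect_error(binTheta(c(10, NA)), "filter")
})

test_that("G test matches the closed form and degenerates to p = 1", {
  null <- gTestSubset(c(4, 8, 12, 4, 8, 4), 10 * c(4, 8, 12, 4, 8, 4))
  expect_equal(unname(null$statistic), 0)
  expect_equal(null$p.value, 1)
  conc <- gTestSubset(c(10, 0, 0, 0, 0, 0), rep(50, 6))
  expect_equal(unname(conc$statistic), 20 * log(6), tolerance = 1e-12)
  # independent tail: numerically integrate the chi-square density
  tail <- stats::integrate(function(x) stats::dchisq(x, df = 5),
                           20 * log(6), Inf, rel.tol = 1e-10)$value
  expect_equal(conc$p.value, tail, tolerance = 1e-8)
  expect_error(gTestSubset(rep(0, 6), rep(10, 6)), "zero")
  expect_error(gTestSubset(rep(1, 6), rep(0, 6)), "background")
})

test_that("G test drops structurally empty bins and flags impossibles", {
  res <- gTestSubset(c(5, 5, 0, 0, 0, 0), c(20, 20, 0, 0, 0, 0))
  expect_equal(unname(res$parameter), 1)
  expect_equal(res$p.value, 1)
  expect_warning(out <- gTestSubset(c(5, 5, 1, 0, 0, 0),
                                    c(20, 20, 0, 0, 0, 0)),
                 "zero background")
  expect_equal(out$p.value, 0)
})

test_that("exact multinomial p matches brute-force enumeration", {
  probsets <- list(uniform = rep(1 / 6, 6),
                   skew1 = c(0.4, 0.2, 0.1, 0.1, 0.1, 0.1),
                   skew2 = c(0.05, 0.05, 0.1, 0.2, 0.3, 0.3))
  for (probs in probsets) {
    # n = 2 directly against the per-outcome brute force
    expect_equal(exactMultinomialP(c(1, 1, 0, 0, 0, 0), probs)$p.value,
                 oracle_multinomial_p(c(1, 1, 0, 0, 0, 0), probs),
                 tolerance = 1e-9)
    for (n in 1:4) {
      tab <- oracle_multinomial_table(n, probs)
      # every composition of n over 6 bins
      comps <- t(apply(utils::combn(n + 5, 5), 2, function(cut)
        diff(c(0, cut, n + 6)) - 1))
      for (i in seq_len(nrow(comps))) {
        obs <- comps[i, ]
        expect_equal(exactMultinomialP(obs, probs)$p.value,
                     oracle_multinomial_p_fast(obs, tab),
                     tolerance = 1e-9,
                     info = paste(c(obs, "|", round(probs, 2)),
                                  collapse = " "))
      }
    }
  }
})

test_that("exact multinomial handles degenerate probabilities", {
  expect_equal(exactMultinomialP(c(5, 0, 0, 0, 0, 0),
                                 c(1, 0, 0, 0, 0, 0))$p.value, 1)
  expect_equal(exactMultinomialP(c(4, 1, 0, 0, 0, 0),
                                 c(1, 0, 0, 0, 0, 0))$p.value, 0)
  expect_error(exactMultinomialP(c(1, 0, 0, 0, 0, 0), rep(0.2, 6)),
               "sum to 1")
})

test_that("Monte-Carlo branch approximates the exact p", {
  obs <- c(9, 3, 2, 1, 0, 0)     # n = 15
  exact <- exactMultinomialP(obs, rep(1 / 6, 6))$p.value
  mc <- exactMultinomialP(obs, rep(1 / 6, 6), exactMax = 5,
                          nMC = 2e5, seed = 9)
  expect_match(mc$method, "Monte Carlo")
  expect_lt(abs(mc$p.value - exact), 6 * mc$stderr + 1e-4)
  mc2 <- exactMultinomialP(obs, rep(1 / 6, 6), exactMax = 5,
                           nMC = 2e5, seed = 9)
  expect_identical(mc$p.value, mc2$p.value)
})

test_that("exact and G-test p-values agree in order of magnitude", {
  obs <- c(15, 8, 4, 3, 3, 3)
  bgp <- rep(1 / 6, 6)
  g <- gTestSubset(obs, 600 * bgp)
  ex <- exactMultinomialP(obs, bgp, exactMax = 40)
  expect_lt(abs(log10(g$p.value) - log10(ex$p.value)), 1)
})

test_that("cross-dataset comparison counts concordant genes", {
  tri <- archetypeMeans(c(10, 100, 200, 355), amplitude = 1,
                        baseline = 3)
  rownames(tri) <- paste0("g", 1:4)
  a <- triComp(tri)
  expect_equal(compareDatasets(a, a)$fraction_within, 1)
  rot <- triComp(data.frame(gene_id = a$gene_id,
                            d21 = -a$d21, d31 = -a$d31))
  expect_equal(compareDatasets(a, rot, deltaMax = 60)$fraction_within,
               0)
  hand_a <- S4Vectors::DataFrame(gene_id = c("g1", "g2", "g3"),
                                 theta = c(0, 100, 300))
  hand_b <- S4Vectors::DataFrame(gene_id = c("g1", "g2", "g3"),
                                 theta = c(10, 170, 359))
  cmp <- compareDatasets(hand_a, hand_b, deltaMax = 60)
  expect_equal(cmp$table$delta_theta, c(10, 70, 59))
  expect_equal(cmp$fraction_within, 2 / 3)
  # symmetry and order invariance
  cmp_rev <- compareDatasets(hand_b[c(3, 1, 2), ], hand_a)
  expect_equal(cmp_rev$fraction_within, cmp$fraction_within)
  expect_equal(cmp_rev$table$delta_theta, cmp$table$delta_theta)
  expect_error(compareDatasets(hand_a,
                               S4Vectors::DataFrame(gene_id = "q",
                                                    theta = 5)),
               "shared")
})

test_that("external periodic descriptors map linearly onto theta", {
  expect_equal(externalPhaseToTheta(6, 24), 90)
  expect_equal(externalPhaseToTheta(24, 24), 0)
  expect_equal(externalPhaseToTheta(pi, 2 * pi), 180)
  expect_equal(externalPhaseToTheta(6, 24, direction = -1,
                                    offsetDeg = 30), 300)
  expect_error(externalPhaseToTheta(1, 0), "period")
})

test_that("gene-set profiles are tested against the background", {
  set.seed(21)
  bg_theta <- runif(600, 0, 360)
  bg <- S4Vectors::DataFrame(gene_id = paste0("g", 1:600),
                             theta = bg_theta)
  # a set concentrated in category 5 (240-300 degrees)
  hot <- paste0("g", order(abs(((bg_theta - 270 + 180) %% 360) - 180))[1:15])
  prof <- geneSetThetaProfile(bg, hot)
  expect_lt(prof$g_test$p.value, 0.001)
  expect_lt(prof$exact_test$p.value, 0.001)
  expect_identical(sum(prof$observed), 15L)
  # subset removed from background by default
  expect_identical(sum(prof$background), 585L)
  full <- geneSetThetaProfile(bg, bg$gene_id, nMC = 1e4, seed = 2)
  expect_equal(full$g_test$p.value, 1)
  expect_error(geneSetThetaProfile(bg, c("nope1", "nope2")),
               "unmatched")
})

test_that("G-test type-I error is calibrated at the 5 percent level", {
  bg_probs <- c(0.25, 0.2, 0.1, 0.15, 0.2, 0.1)
  bg_counts <- round(bg_probs * 4000)
  set.seed(31)
  draws <- stats::rmultinom(4000, size = 50, prob = bg_probs)
  E <- 50 * bg_counts / sum(bg_counts)
  G <- 2 * colSums(draws * log(sweep(draws, 1, E, "/")), na.rm = TRUE)
  # same statistic via the package, spot-checked
  idx <- c(1, 2000, 4000)
  for (i in idx)
    expect_equal(unname(gTestSubset(draws[, i], bg_counts)$statistic),
                 G[i], tolerance = 1e-9)
  pvals <- stats::pchisq(G, df = 5, lower.tail = FALSE)
  rate <- mean(pvals < 0.05)
  expect_gte(rate, 0.04)
  expect_lte(rate, 0.06)
})
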
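test_that("log fold changes match the worked triples", {
  expect_equal(logFoldChanges(1, 2, 4), cbind(d21 = 1, d31 = 2))
  expect_equal(logFoldChanges(7, 7, 7), cbind(d21 = 0, d31 = 0))
  expect_equal(logFoldChanges(1, 10, 100),
               cbind(d21 = log2(10), d31 = log2(100)),
               tolerance = 1e-12)
  expect_error(logFoldChanges(0, 1, 2, geneId = "badgene"), "badgene")
  expect_error(logFoldChanges(1, -3, 2), "positive")
})

test_that("plane projection matches the pinned examples and the oracle", {
  expect_equal(triCompProject(1, 2),
               cbind(p = -1.5, q = -sqrt(3) / 2), tolerance = 1e-12)
  expect_equal(triCompProject(0, 0), cbind(p = 0, q = 0))
  # pure-G1 archetype (h, 0, 0) on the log2 scale, h = 1
  expect_equal(triCompProject(-1, -1),
               cbind(p = 0.5, q = sqrt(3) / 2), tolerance = 1e-12)
  for (tri in list(c(1, 2, 4), c(3, 0.5, 7), c(10, 10, 1))) {
    fc <- logFoldChanges(tri[1], tri[2], tri[3])
    expect_equal(drop(triCompProject(fc[, "d21"], fc[, "d31"])),
                 oracle_project(tri[1], tri[2], tri[3]),
                 tolerance = 1e-12)
  }
})

test_that("polar conversion uses the clockwise-from-up convention", {
  expect_equal(polarFromPlane(-1.5, -sqrt(3) / 2),
               cbind(r = sqrt(3), theta = 240), tolerance = 1e-12)
  expect_equal(polarFromPlane(0, 1), cbind(r = 1, theta = 0))
  expect_equal(polarFromPlane(1, 0), cbind(r = 1, theta = 90))
  expect_equal(polarFromPlane(0, -1), cbind(r = 1, theta = 180))
  expect_equal(polarFromPlane(-1, 0), cbind(r = 1, theta = 270))
  flat <- polarFromPlane(0, 0)
  expect_identical(flat[, "r"], c(r = 0))
  expect_true(is.na(flat[, "theta"]))
})

test_that("category bins are half-open 60-degree sectors", {
  expect_identical(assignCategory(c(240, 0, 359.99, 60, 30)),
                   c(5L, 1L, 6L, 2L, 1L))
  expect_identical(assignCategory(NA_real_), NA_integer_)
  expect_error(assignCategory(360), "\\[0, 360\\)")
  expect_error(assignCategory(-1), "\\[0, 360\\)")
})

test_that("circular difference wraps and is bounded by 180", {
  expect_equal(circularDifference(350, 10), 20)
  expect_equal(circularDifference(123.4, 123.4), 0)
  expect_equal(circularDifference(30, 240), 150)
  expect_equal(circularDifference(0, 180), 180)
  expect_error(circularDifference(NA, 10), "defined")
})

test_that("max fold change is the largest pairwise ratio", {
  expect_equal(maxFoldChange(1, 2, 4), 4)
  expect_equal(maxFoldChange(3, 3, 3), 1)
  expect_equal(maxFoldChange(3, 1.5, 2), 2)
  expect_error(maxFoldChange(1, 0, 2), "positive")
})

test_that("the full transform reproduces the worked examples", {
  res <- triComp(rbind(a = c(1, 2, 4), b = c(1, 10, 100),
                       c = c(2, 1, 1), d = c(5, 5, 5)))
  expect_s4_class(res, "TriCompResult")
  expect_equal(unname(theta(res)[c("a", "b")]), c(240, 240))
  expect_equal(unname(categories(res)[c("a", "b")]), c(5L, 5L))
  expect_equal(unname(radius(res)["a"]), sqrt(3), tolerance = 1e-12)
  expect_equal(unname(radius(res)["b"]),
               sqrt(log2(10)^2 + log2(100)^2 - log2(10) * log2(100)),
               tolerance = 1e-12)
  expect_equal(unname(theta(res)["c"]), 30)
  expect_equal(unname(radius(res)["c"]), 1, tolerance = 1e-12)
  expect_identical(unname(radius(res)["d"]), 0)
  expect_true(is.na(theta(res)["d"]))
  expect_true(is.na(categories(res)["d"]))
})

test_that("transform accepts precomputed fold-change tables verbatim", {
  tab <- data.frame(gene_id = c("x", "y"), d21 = c(1, 0),
                    d31 = c(2, 0))
  res <- triComp(tab)
  expect_equal(unname(theta(res)["x"]), 240)
  expect_true(is.na(theta(res)["y"]))
  res2 <- triComp(S4Vectors::DataFrame(tab))
  expect_equal(res$theta, res2$theta)
})

test_that("theta is invariant to overall scaling of the triple", {
  tri <- random_triples(2000, seed = 11)
  set.seed(12)
  sc <- 2^runif(2000, -8, 8)
  a <- triComp(tri)
  b <- triComp(tri * sc)
  expect_equal(a$theta, b$theta, tolerance = 1e-9)
  expect_equal(a$r, b$r, tolerance = 1e-9)
})

test_that("cyclic permutation rotates theta by 120 degrees", {
  grid <- seq(0.5, 359.5, by = 1)
  tri <- archetypeMeans(grid, amplitude = 1, baseline = 2)
  a <- triComp(tri)
  b <- triComp(tri[, c(3, 1, 2)])
  expect_equal(b$theta, (a$theta + 120) %% 360, tolerance = 1e-9)
  expect_equal(b$r, a$r, tolerance = 1e-9)
})

test_that("swapping groups 2 and 3 reflects theta about 30 degrees", {
  grid <- seq(0.5, 359.5, by = 1)
  tri <- archetypeMeans(grid, amplitude = 1, baseline = 2)
  a <- triComp(tri)
  b <- triComp(tri[, c(1, 3, 2)])
  expect_equal(b$theta, (60 - a$theta) %% 360, tolerance = 1e-9)
  expect_equal(b$r, a$r, tolerance = 1e-9)
})

test_that("r has the closed form sqrt(d21^2 + d31^2 - d21*d31)", {
  tri <- random_triples(1000, seed = 13)
  res <- triComp(tri)
  expect_equal(res$r,
               sqrt(res$d21^2 + res$d31^2 - res$d21 * res$d31),
               tolerance = 1e-12)
  expect_true(all((res$r == 0) ==
                    (tri[, 1] == tri[, 2] & tri[, 2] == tri[, 3])))
})

test_that("plane coordinates agree with the simplex-projection oracle", {
  tri <- random_triples(500, seed = 14)
  res <- triComp(tri)
  for (i in seq_len(nrow(tri))) {
    expect_equal(c(p = res$p[i], q = res$q[i]),
                 oracle_project(tri[i, 1], tri[i, 2], tri[i, 3]),
                 tolerance = 1e-10)
  }
})

test_that("theta agrees with an acos-based quadrant oracle", {
  set.seed(15)
  p <- runif(200, -3, 3)
  q <- runif(200, -3, 3)
  got <- polarFromPlane(p, q)[, "theta"]
  want <- vapply(seq_along(p), function(i) oracle_angle(p[i], q[i]),
                 numeric(1))
  expect_equal(got %% 360, want %% 360, tolerance = 1e-9)
})

test_that("the six archetypes land at the six category centers", {
  h <- 4; l <- 1
  arch <- rbind(c(h, l, l), c(h, h, l), c(l, h, l),
                c(l, h, h), c(l, l, h), c(h, l, h))
  res <- triComp(arch)
  expect_equal(unname(theta(res)), c(30, 90, 150, 210, 270, 330),
               tolerance = 1e-9)
  expect_identical(unname(categories(res)), 1:6)
})

test_that("TriCompResult validity catches corrupted objects", {
  res <- triComp(rbind(a = c(1, 2, 4)))
  make <- function(theta, r, category) {
    methods::new("TriCompResult", S4Vectors::DataFrame(
      gene_id = "a", d21 = 1, d31 = 2, p = 1, q = 1,
      r = r, theta = theta, category = category))
  }
  expect_error(make(theta = 400, r = sqrt(2), category = 1L), "theta")
  expect_error(make(theta = 90, r = -1, category = 2L))
  expect_error(make(theta = NA_real_, r = 1, category = NA_integer_),
               "NA exactly when")
  expect_s4_class(make(theta = 90, r = sqrt(2), category = 2L),
                  "TriCompResult")
  expect_output(show(res), "TriCompResult")
})
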
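test_that("CV statistics follow STD/MEAN with the population denominator", {
  c1 <- ClusterLabels(labels = rep(c(1L, 2L), each = 5))
  c2 <- ClusterLabels(labels = c(1L, 1L, 2L, 2L, 2L, 1L, 1L, 2L, 2L, 2L))
  # columns of this table are [2,2] and [3,3]: uniform -> CV 0
  cv <- cvStats(buildCrossTab(c1, c2), "columns")
  expect_equal(cv$cv, c(0, 0))

  # column counts [9,1]: population STD 4, mean 5, CV 0.8
  c1 <- ClusterLabels(labels = rep(c(1L, 2L), c(9, 1)))
  c2 <- ClusterLabels(labels = rep(1L, 10))
  cv <- cvStats(buildCrossTab(c1, c2), "columns")
  expect_equal(cv$mean, 5)
  expect_equal(cv$sd, 4)
  expect_equal(cv$cv, 0.8)
  # sample SD alternative is exposed but not the default
  expect_equal(cvStats(buildCrossTab(c1, c2), "columns", ddof = 1L)$sd,
               sd(c(9, 1)))

  # one-hot column among k=5 partner clusters: CV = sqrt(k-1) = 2
  c1 <- ClusterLabels(labels = c(rep(1L, 100), 2L, 3L, 4L, 5L))
  c2 <- ClusterLabels(labels = c(rep(1L, 100), 2L, 2L, 2L, 2L))
  cv <- cvStats(buildCrossTab(c1, c2), "columns")
  expect_equal(cv$cv[1], 2)

  # a single partner cluster: length-1 count vector, CV defined as 0
  one <- ClusterLabels(labels = rep(1L, 6))
  two <- ClusterLabels(labels = rep(c(1L, 2L), 3))
  expect_equal(cvStats(buildCrossTab(one, two), "columns")$cv, c(0, 0))
})

test_that("distribution-based pass relabels exactly the unmatched cells of firing columns", {
  fx <- handTraceFixture()
  # counts [[8,0],[2,10]]: col 1 CV 0.6, col 2 CV 1.0
  expect_equal(fx$cv$cv, c(0.6, 1.0))
  expect_equal(fx$mm@pairs$partner, c(1L, 2L))

  # threshold above every CV: identity
  res <- dbRecluster(fx$c1, fx$ct, fx$mm, fx$cv, cvTh = 1.5)
  expect_identical(labels(res$labels), labels(fx$c1))
  expect_equal(res$nChanged, 0L)

  # rule fires for both columns; only column 1 has unmatched cells (2 of them)
  res <- dbRecluster(fx$c1, fx$ct, fx$mm, fx$cv, cvTh = 0.5)
  expect_equal(res$nChanged, 2L)
  expect_equal(labels(res$labels), rep(c(1L, 2L), c(10, 10)))

  # firing for column 2 alone changes nothing: all its cells are matched
  res <- dbRecluster(fx$c1, fx$ct, fx$mm, fx$cv, cvTh = 0.8)
  expect_equal(res$nChanged, 0L)

  # the literal-equation rule direction is the complement
  res <- dbRecluster(fx$c1, fx$ct, fx$mm, fx$cv, cvTh = 0.8, cvRule = "lt")
  expect_equal(res$nChanged, 2L)
})

test_that("re-clustering never grows the label set and is deterministic", {
  set.seed(5)
  for (rep in 1:10) {
    n <- 150
    c1 <- ClusterLabels(labels = randomLabeling(n))
    c2 <- ClusterLabels(labels = randomLabeling(n))
    ct <- buildCrossTab(c1, c2)
    mm <- matchLabels(ct, c1, c2, "columns")
    cv <- cvStats(ct, "columns")
    res <- dbRecluster(c1, ct, mm, cv, cvTh = 0)   # fire everywhere
    expect_lte(nClusters(res$labels), nClusters(c1))
    res2 <- dbRecluster(c1, ct, mm, cv, cvTh = 0)
    expect_identical(labels(res$labels), labels(res2$labels))
    # matched cells kept their labels
    expect_identical(labels(res$labels)[mm@matchedMask],
                     labels(c1)[mm@matchedMask])
  }
})

test_that("COPOD scores rank a planted extreme point highest", {
  set.seed(21)
  x <- rbind(matrix(rnorm(100 * 3), 100), rep(10, 3))
  s <- copodScores(x)
  expect_equal(which.max(s), 101L)

  # identical rows: identical ranks, equal scores
  s <- copodScores(matrix(1, 20, 4))
  expect_true(all(s == s[1]))
})

test_that("COPOD agrees with an independent ECDF/skewness re-derivation", {
  set.seed(33)
  for (rep in 1:5) {
    x <- matrix(rnorm(80 * 5), 80)
    a <- copodScores(x)
    b <- copodOracle(x)
    expect_gt(cor(a, b, method = "spearman"), 0.99)
    expect_lt(max(abs(a - b)), 1e-10)
  }
})

test_that("COPOD scores are rank-based up to the skewness direction", {
  set.seed(8)
  x <- cbind(rnorm(60), rexp(60))
  # positive affine maps preserve ranks and skew signs: scores identical
  y <- sweep(sweep(x, 2L, c(3, 0.5), `*`), 2L, c(-7, 2), `+`)
  expect_equal(copodScores(x), copodScores(y), tolerance = 1e-12)
  # a nonlinear monotone transform that keeps the dimension right-skewed
  z <- x; z[, 2] <- sqrt(z[, 2])
  expect_gt(e1071::skewness(z[, 2]), 0)  # precondition of the property
  expect_equal(order(copodScores(x)), order(copodScores(z)))
})

test_that("outlier-based pass spares flagged outliers and moves inlying unmatched cells", {
  # subgroup of 20: 15 matched, 5 unmatched of which one planted far away
  set.seed(99)
  c1 <- ClusterLabels(labels = rep(c(1L, 2L), c(15, 5)))
  c2 <- ClusterLabels(labels = rep(1L, 20))
  feats <- matrix(rnorm(20 * 2, sd = 0.3), 20)
  feats[20, ] <- c(50, 50)                    # the planted outlier, unmatched
  ct <- buildCrossTab(c1, c2)
  mm <- matchLabels(ct, c1, c2, "columns")
  res <- obRecluster(c1, ct, mm, feats, contamination = 0.05)
  # round(0.05 * 20) = 1 flagged = the far point; it keeps label 2
  expect_equal(labels(res$labels), c(rep(1L, 19), 2L))
  expect_equal(res$nChanged, 4L)

  # matched cells keep their labels even under heavy flagging
  res <- obRecluster(c1, ct, mm, feats, contamination = 0.45)
  expect_true(all(labels(res$labels)[1:15] == 1L))

  # subgroups below the minimum size are skipped untouched
  tiny1 <- ClusterLabels(labels = c(1L, 2L))
  tiny2 <- ClusterLabels(labels = c(1L, 2L))
  ctT <- buildCrossTab(tiny1, tiny2)
  mmT <- matchLabels(ctT, tiny1, tiny2, "columns")
  resT <- obRecluster(tiny1, ctT, mmT, matrix(rnorm(4), 2),
                      contamination = 0.1, minSubgroup = 2L)
  expect_identical(labels(resT$labels), c(1L, 2L))
})

test_that("vanishing contamination reduces the outlier rule to fire-all relabeling", {
  for (s in 1:3) {
    fx <- syntheticFixture("imbalanced", seed = s)
    ct <- buildCrossTab(fx$method1, fx$method2)
    mm <- matchLabels(ct, fx$method1, fx$method2, "columns")
    ob <- obRecluster(fx$method1, ct, mm, fx$features, contamination = 0)
    db <- dbRecluster(fx$method1, ct, mm, cvStats(ct, "columns"), cvTh = 0)
    expect_identical(labels(ob$labels), labels(db$labels))
    expect_equal(ob$nChanged, db$nChanged)
  }
})
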
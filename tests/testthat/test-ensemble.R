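test_that("identical partitions converge immediately with no changes", {
  set.seed(1)
  lab <- randomLabeling(120)
  c1 <- ClusterLabels(labels = lab)
  c2 <- ClusterLabels(labels = lab + 10L)  # same partition, renamed
  res <- ctecPair(c1, c2, config = ensembleConfig("DB"))
  expect_equal(termination(res), "converged")
  expect_equal(nrow(traceTable(res)), 1L)
  expect_equal(sum(traceTable(res)$changed_col + traceTable(res)$changed_row),
               0L)
  expect_equal(ari(consensus(res), c1), 1)
})

test_that("a pure over-split is healed back to the partner's partition", {
  cells <- makeCells(syntheticScenario(nCells = 300, nClusters = 4,
                                       separation = 9, seed = 6))
  split1 <- perturbLabels(cells$truth, cells$features, split = 2L, seed = 60)
  expect_lt(ari(split1, cells$truth), 1)
  res <- ctecPair(split1, cells$truth, cells$features, ensembleConfig("DB"))
  expect_equal(ari(consensus(res), cells$truth), 1)
})

test_that("an all-one-cluster partner does not collapse separated blobs", {
  fx <- syntheticFixture("adversarial", seed = 1)
  res <- ctecPair(fx$method1, fx$method2, fx$features, ensembleConfig("DB"))
  # method 2 carries no information; the consensus keeps the dominant clusters
  expect_gte(nClusters(consensus(res)), 5L)
  expect_gt(ari(consensus(res), fx$truth), 0.8)
})

test_that("pair ensemble terminates with a declared reason and never grows clusters", {
  set.seed(14)
  for (rep in 1:25) {
    n <- sample(30:300, 1)
    c1 <- ClusterLabels(labels = randomLabeling(n))
    c2 <- ClusterLabels(labels = randomLabeling(n))
    res <- ctecPair(c1, c2, config = ensembleConfig("DB"))
    expect_true(termination(res) %in% c("converged", "cv_floor", "early_stop"))
    expect_lte(nClusters(consensus(res)), nClusters(c1))
  }
})

test_that("the annealed threshold strictly decreases across recorded rounds", {
  fx <- syntheticFixture("flagship", seed = 2)
  res <- ctecPair(fx$method1, fx$method2, fx$features, ensembleConfig("DB"))
  th <- traceTable(res)$cv_th
  expect_true(all(diff(th) < 0))
  expect_lte(nrow(traceTable(res)),
             (2 - 0) / 0.2 + 1)
})

test_that("iterative updating does at least as well as a single correction", {
  fx <- syntheticFixture("flagship", seed = 4)
  full <- ctecPair(fx$method1, fx$method2, fx$features, ensembleConfig("DB"))
  once <- ctecPair(fx$method1, fx$method2, fx$features,
                   ensembleConfig("DB", iterate = FALSE))
  expect_gte(ari(consensus(full), fx$truth), ari(consensus(once), fx$truth))
})

test_that("the OB strategy demands an embedding and runs to a fixed point", {
  fx <- syntheticFixture("imbalanced", seed = 2)
  expect_error(ctecPair(fx$method1, fx$method2, config = ensembleConfig("OB")),
               "feature")
  res <- ctecPair(fx$method1, fx$method2, fx$features, ensembleConfig("OB"))
  expect_true(termination(res) %in% c("converged", "iter_cap"))
  expect_gt(ari(consensus(res), fx$truth),
            ari(fx$method1, fx$truth))
})

test_that("pair ensemble is deterministic", {
  fx <- syntheticFixture("flagship", seed = 5)
  r1 <- ctecPair(fx$method1, fx$method2, fx$features, ensembleConfig("DB"))
  r2 <- ctecPair(fx$method1, fx$method2, fx$features, ensembleConfig("DB"))
  expect_identical(labels(consensus(r1)), labels(consensus(r2)))
  expect_identical(traceTable(r1), traceTable(r2))
})

test_that("multi-method scheduler is idempotent on identical inputs", {
  set.seed(9)
  cells <- makeCells(syntheticScenario(nCells = 200, nClusters = 3,
                                       separation = 8, seed = 9))
  ins <- list(a = cells$truth, b = cells$truth, c = cells$truth)
  res <- ctecMulti(ins, cells$features, ensembleConfig("DB"))
  expect_equal(ari(consensus(res), cells$truth), 1)
  # with two inputs, CH removal cannot drop below two and is skipped
  res2 <- ctecMulti(ins[1:2], cells$features,
                    ensembleConfig("DB", chRemoval = TRUE))
  expect_true(is.na(res2@history$removed))
  expect_equal(ari(consensus(res2), cells$truth), 1)
})

test_that("CH-based removal drops the corrupted input first", {
  fx <- syntheticFixture("flagship", seed = 1)
  set.seed(101)
  rnd <- ClusterLabels(cellIds(fx$truth),
                       sample.int(8L, length(labels(fx$truth)),
                                  replace = TRUE))
  res <- ctecMulti(list(m1 = fx$method1, m2 = fx$method2, bad = rnd),
                   fx$features, ensembleConfig("DB"))
  expect_equal(res@history$removed, "bad")
  expect_gt(ari(consensus(res), fx$truth), 0.7)
  # a single-cluster input has undefined CH and is treated as worst
  flat <- ClusterLabels(cellIds(fx$truth),
                        rep(1L, length(labels(fx$truth))))
  res2 <- ctecMulti(list(m1 = fx$method1, m2 = fx$method2, flat = flat),
                    fx$features, ensembleConfig("DB"))
  expect_equal(res2@history$removed, "flat")
})

test_that("scheduler merges the most dissimilar pair first", {
  fx <- syntheticFixture("flagship", seed = 3)
  set.seed(55)
  rnd <- ClusterLabels(cellIds(fx$truth),
                       sample.int(6L, length(labels(fx$truth)),
                                  replace = TRUE))
  res <- ctecMulti(list(m1 = fx$method1, m2 = fx$method2, bad = rnd),
                   fx$features, ensembleConfig("DB", chRemoval = FALSE))
  firstPair <- res@history$merges[[1]]$pair
  expect_true("bad" %in% firstPair)  # lowest pairwise ARI involves the noise
  expect_equal(length(res@history$merges), 2L)
})
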
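.withSeed <- function(seed, expr) {
  env <- globalenv()
  old <- if (exists(".Random.seed", envir = env, inherits = FALSE))
    get(".Random.seed", envir = env) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = env, inherits = FALSE))
        rm(".Random.seed", envir = env)
    } else assign(".Random.seed", old, envir = env)
  })
  set.seed(as.integer(seed))
  force(expr)
}

#' Scenario description for the synthetic benchmark generator
#'
#' Defines a population of cells as isotropic Gaussian clouds in a
#' low-dimensional embedding, plus two perturbed labelings that emulate the
#' complementary errors real clusterers make: over-splitting a cluster,
#' merging clusters, and random boundary noise.
#'
#' @param nCells total cells.
#' @param nClusters number of ground-truth clusters.
#' @param proportions cluster proportions (sum 1); supports heavy imbalance.
#' @param d embedding dimension.
#' @param separation minimum between-centroid distance in units of the
#'   within-cluster SD (which is 1).
#' @param perturb1,perturb2 lists with elements \code{split} (cluster ids to
#'   split in two), \code{merge} (list of id sets to merge) and
#'   \code{noiseRate} (fraction of cells given a uniformly random wrong
#'   label), describing simulated method 1 and method 2.
#' @param seed integer seed; all outputs are deterministic given it.
#' @return a list of class \code{SyntheticScenario}.
#' @examples
#' sc <- syntheticScenario(nCells = 90, nClusters = 3, seed = 7)
#' cells <- makeCells(sc)
#' nClusters(cells$truth)
#' @export
syntheticScenario <- function(nCells = 600L, nClusters = 5L,
                              proportions = rep(1 / nClusters, nClusters),
                              d = 10L, separation = 8,
                              perturb1 = list(split = integer(0),
                                              merge = list(), noiseRate = 0),
                              perturb2 = list(split = integer(0),
                                              merge = list(), noiseRate = 0),
                              seed = 1L) {
  stopifnot(nClusters <= nCells, abs(sum(proportions) - 1) < 1e-8,
            length(proportions) == nClusters)
  structure(list(nCells = as.integer(nCells),
                 nClusters = as.integer(nClusters),
                 proportions = proportions, d = as.integer(d),
                 separation = separation, perturb1 = perturb1,
                 perturb2 = perturb2, seed = as.integer(seed)),
            class = "SyntheticScenario")
}

#' Generate cells and ground-truth labels for a scenario
#'
#' Draws cluster sizes from a multinomial over the scenario proportions (every
#' cluster is guaranteed at least one cell), places centroids at random
#' directions rescaled so the closest pair sits \code{separation} apart, and
#' samples cells as unit-variance isotropic Gaussians around them.
#'
#' @param sc a \code{\link{syntheticScenario}}.
#' @return list with \code{features} (cells x d matrix, rownames = cell ids)
#'   and \code{truth} (\code{ClusterLabels}).
#' @export
makeCells <- function(sc) {
  stopifnot(inherits(sc, "SyntheticScenario"))
  .withSeed(sc$seed, {
    k <- sc$nClusters; d <- sc$d; n <- sc$nCells
    centroids <- matrix(rnorm(k * d), nrow = k)
    if (k > 1L) {
      dmin <- min(dist(centroids))
      if (dmin == 0) stop("degenerate centroids")
      centroids <- centroids * (sc$separation / dmin)
    }
    sizes <- as.vector(rmultinom(1L, n, sc$proportions))
    while (any(sizes == 0L)) {  # every cluster must have >= 1 member
      i <- which.max(sizes); j <- which(sizes == 0L)[1L]
      sizes[i] <- sizes[i] - 1L; sizes[j] <- 1L
    }
    g <- rep.int(seq_len(k), sizes)
    x <- centroids[g, , drop = FALSE] + matrix(rnorm(n * d), nrow = n)
    ids <- sprintf("cell%04d", seq_len(n))
    rownames(x) <- ids
    list(features = x, truth = ClusterLabels(ids, g))
  })
}

#' Perturb a labeling with controlled clustering errors
#'
#' Applies, in order: splits (each target cluster is cut in two by a random
#' hyperplane through its centroid, one side receiving a fresh label), merges
#' (each set collapses onto its smallest id), then label noise (a random
#' fraction of cells is reassigned to a uniformly chosen wrong label from the
#' current label set). Deterministic given the seed.
#'
#' @param truth a \code{ClusterLabels}.
#' @param features embedding matrix aligned with \code{truth} (used to place
#'   the split hyperplanes).
#' @param split integer vector of cluster ids to split.
#' @param merge list of integer vectors, disjoint sets of ids to merge.
#' @param noiseRate fraction in [0, 1) of cells to mislabel.
#' @param seed integer seed.
#' @return a perturbed \code{ClusterLabels}.
#' @export
perturbLabels <- function(truth, features, split = integer(0),
                          merge = list(), noiseRate = 0, seed = 1L) {
  stopifnot(is(truth, "ClusterLabels"), noiseRate >= 0, noiseRate < 1)
  x <- as.matrix(features)
  lab <- truth@labels
  if (!all(split %in% lab)) stop("split target not present in labeling")
  ids <- unlist(merge)
  if (anyDuplicated(ids)) stop("merge sets must be disjoint")
  if (length(ids) && !all(ids %in% lab)) stop("merge target not present")
  .withSeed(seed, {
    for (a in split) {
      idx <- which(lab == a)
      w <- rnorm(ncol(x)); w <- w / sqrt(sum(w^2))
      ctr <- colMeans(x[idx, , drop = FALSE])
      side <- as.vector(sweep(x[idx, , drop = FALSE], 2L, ctr) %*% w) > 0
      lab[idx[side]] <- max(lab) + 1L
    }
    for (s in merge) lab[lab %in% s] <- min(s)
    if (noiseRate > 0) {
      pool <- sort(unique(lab))
      nNoise <- floor(noiseRate * length(lab) + 0.5)
      hit <- sample.int(length(lab), nNoise)
      for (i in hit) {
        wrong <- setdiff(pool, lab[i])
        if (length(wrong)) lab[i] <- if (length(wrong) == 1L) wrong else
          sample(wrong, 1L)
      }
    }
    initialize(truth, labels = lab)
  })
}

#' Packaged benchmark scenarios
#'
#' Three ready-made fixtures used throughout the test-suite and the
#' reproduction script:
#' \describe{
#'   \item{flagship}{2000 cells, 5 clusters at proportions
#'     0.35/0.1/0.1/0.225/0.225, separation 8: method 1 = truth with the
#'     dominant cluster 1 over-split in two plus 5\% label noise; method 2 =
#'     truth with the two rare clusters 2 and 3 merged plus 5\% label noise.
#'     Over-splitting large populations and merging rare types are the
#'     complementary errors real clusterers make, the regime the pair
#'     ensemble is designed for.}
#'   \item{imbalanced}{600 cells, 3 clusters at proportions 0.9/0.05/0.05,
#'     the rare-cell-type regime; same complementary perturbations (split the
#'     dominant cluster, merge the two rare ones).}
#'   \item{adversarial}{300 cells, 5 balanced clusters: method 1 = truth with
#'     5\% noise, method 2 = a single all-cells cluster, probing whether the
#'     ensemble collapses.}
#' }
#'
#' @param scenario one of \code{"flagship"}, \code{"imbalanced"},
#'   \code{"adversarial"}.
#' @param seed integer seed.
#' @return list with \code{features}, \code{truth}, \code{method1},
#'   \code{method2} and the \code{scenario} object.
#' @examples
#' fx <- syntheticFixture("flagship", seed = 3)
#' ari(fx$method1, fx$truth)
#' @export
syntheticFixture <- function(scenario = c("flagship", "imbalanced",
                                          "adversarial"), seed = 1L) {
  scenario <- match.arg(scenario)
  seed <- as.integer(seed)
  sc <- switch(scenario,
    flagship = syntheticScenario(
      nCells = 2000L, nClusters = 5L,
      proportions = c(0.35, 0.1, 0.1, 0.225, 0.225), d = 10L,
      separation = 8,
      perturb1 = list(split = 1L, merge = list(), noiseRate = 0.05),
      perturb2 = list(split = integer(0), merge = list(2:3),
                      noiseRate = 0.05),
      seed = seed),
    imbalanced = syntheticScenario(
      nCells = 600L, nClusters = 3L, proportions = c(0.9, 0.05, 0.05),
      d = 10L, separation = 8,
      perturb1 = list(split = 1L, merge = list(), noiseRate = 0.05),
      perturb2 = list(split = integer(0), merge = list(2:3),
                      noiseRate = 0.05),
      seed = seed),
    adversarial = syntheticScenario(
      nCells = 300L, nClusters = 5L, d = 10L, separation = 8,
      perturb1 = list(split = integer(0), merge = list(), noiseRate = 0.05),
      perturb2 = list(split = integer(0), merge = list(1:5), noiseRate = 0),
      seed = seed))
  cells <- makeCells(sc)
  m1 <- perturbLabels(cells$truth, cells$features,
                      split = sc$perturb1$split, merge = sc$perturb1$merge,
                      noiseRate = sc$perturb1$noiseRate, seed = seed + 1001L)
  m2 <- perturbLabels(cells$truth, cells$features,
                      split = sc$perturb2$split, merge = sc$perturb2$merge,
                      noiseRate = sc$perturb2$noiseRate, seed = seed + 2002L)
  list(features = cells$features, truth = cells$truth, method1 = m1,
       method2 = m2, scenario = sc)
}
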
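.labelVector <- function(x) {
  if (is(x, "ClusterLabels")) x@labels else as.integer(x)
}

.contingency <- function(a, b) {
  a <- .labelVector(a); b <- .labelVector(b)
  if (length(a) != length(b)) stop("labelings differ in length")
  if (length(a) < 2L) stop("need at least 2 cells")
  table(a, b)
}

#' Adjusted Rand index
#'
#' Chance-corrected agreement between two partitions, computed from the
#' contingency table with pair counts n(n-1)/2 (exact in double precision for
#' any realistic cell count): the observed number of concordant pairs minus
#' its expectation under random label permutation, normalized by the maximum.
#' Symmetric; 1 for identical partitions (up to relabeling), about 0 for
#' independent ones, and can be negative.
#'
#' @param a,b \code{ClusterLabels} (or plain integer vectors) over the same
#'   cells in the same order.
#' @return a scalar in (-1, 1].
#' @examples
#' ari(c(0, 0, 1, 1), c(0, 1, 0, 1))  # -0.5
#' @export
ari <- function(a, b) {
  tab <- .contingency(a, b)
  comb2 <- function(x) x * (x - 1) / 2
  n <- sum(tab)
  sij <- sum(comb2(tab))
  sa <- sum(comb2(rowSums(tab)))
  sb <- sum(comb2(colSums(tab)))
  expected <- sa * sb / comb2(n)
  denom <- (sa + sb) / 2 - expected
  if (denom == 0) return(1)  # both partitions trivial in the same way
  (sij - expected) / denom
}

#' Normalized mutual information
#'
#' Mutual information between the two partitions normalized by the arithmetic
#' mean of their entropies: 2 * MI / (H(a) + H(b)), with the 0 log 0 = 0
#' convention and natural logarithms (the base cancels). Range [0, 1]; 1 for
#' identical partitions. When both partitions are the trivial single cluster
#' the value is 1 by continuity; when only one side is trivial it is 0.
#'
#' @inheritParams ari
#' @return a scalar in [0, 1].
#' @export
nmi <- function(a, b) {
  tab <- .contingency(a, b)
  n <- sum(tab)
  pa <- rowSums(tab) / n
  pb <- colSums(tab) / n
  ha <- -sum(pa * log(pa))
  hb <- -sum(pb * log(pb))
  if (ha + hb == 0) return(1)  # both single-cluster
  p <- tab / n
  nz <- p > 0
  mi <- sum(p[nz] * log(p[nz] / outer(pa, pb)[nz]))
  2 * mi / (ha + hb)
}

#' Calinski-Harabasz score
#'
#' Ratio of between- to within-cluster dispersion of an embedding,
#' (SSB / (k - 1)) / (SSW / (n - k)); larger values indicate better-separated,
#' more compact clusters. Used by \code{\link{ctecMulti}} to rank input
#' labelings without ground truth.
#'
#' @param features numeric matrix, cells x dimensions.
#' @param labels \code{ClusterLabels} or integer vector over the rows of
#'   \code{features}.
#' @return a positive scalar, or \code{NA} when undefined (fewer than 2
#'   clusters, or as many clusters as cells); callers that rank labelings
#'   treat \code{NA} as worst.
#' @export
chScore <- function(features, labels) {
  x <- as.matrix(features)
  g <- .labelVector(labels)
  if (nrow(x) != length(g)) stop("features not row-aligned with labels")
  k <- length(unique(g))
  n <- nrow(x)
  if (k < 2L || k >= n) return(NA_real_)
  grand <- colMeans(x)
  ssb <- 0; ssw <- 0
  for (lv in unique(g)) {
    xi <- x[g == lv, , drop = FALSE]
    mu <- colMeans(xi)
    ssb <- ssb + nrow(xi) * sum((mu - grand)^2)
    ssw <- ssw + sum(sweep(xi, 2L, mu)^2)
  }
  if (ssw == 0) return(Inf)
  (ssb / (k - 1)) / (ssw / (n - k))
}
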
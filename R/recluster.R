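#' Coefficient of variation of each scanned cluster's count vector
#'
#' For every label on the scanned axis, the mean, standard deviation and
#' coefficient of variation CV = STD/MEAN of its count vector across the
#' partner method's clusters. A one-hot column among k partner clusters has
#' CV = sqrt(k - 1) under the population SD; a uniform column has CV = 0.
#'
#' @param ct a \code{CrossTab}.
#' @param axis \code{"columns"} or \code{"rows"}.
#' @param ddof degrees-of-freedom correction for the SD: 0 = population
#'   (default), 1 = sample. With a single partner cluster the SD is 0.
#' @return data.frame with columns \code{scanned}, \code{mean}, \code{sd},
#'   \code{cv}.
#' @examples
#' ct <- buildCrossTab(ClusterLabels(labels = rep(0:1, each = 5)),
#'                     ClusterLabels(labels = c(rep(0, 9), 1)))
#' cvStats(ct, "columns")
#' @export
cvStats <- function(ct, axis = c("columns", "rows"), ddof = 0L) {
  axis <- match.arg(axis)
  stopifnot(is(ct, "CrossTab"), ddof %in% c(0L, 1L))
  m <- if (axis == "columns") ct@counts else t(ct@counts)
  scanned <- if (axis == "columns") ct@colLabels else ct@rowLabels
  k <- nrow(m)
  mu <- colMeans(m)
  if (k == 1L || (ddof == 1L && k < 2L)) {
    s <- rep(0, ncol(m))
  } else {
    s <- sqrt(colSums(sweep(m, 2L, mu)^2) / (k - ddof))
  }
  data.frame(scanned = scanned, mean = mu, sd = s, cv = s / mu,
             row.names = NULL)
}

.cvFires <- function(cv, cvTh, cvRule) {
  if (cvRule == "ge") cv >= cvTh - 1e-12 else cv < cvTh
}

#' Distribution-based re-clustering of one axis
#'
#' Applies the CV-threshold rule to one pass of the cross-tabulation: for each
#' scanned cluster whose count-vector CV satisfies the rule (default: CV >=
#' \code{cvTh}), every unmatched cell of that cluster is relabeled to the
#' cluster's dominant partner label. Matched cells are never altered, so the
#' partner method's label set can only shrink.
#'
#' @param cPartner the \code{ClusterLabels} being corrected (method 1 when
#'   scanning columns, method 2 when scanning rows).
#' @param ct the \code{CrossTab} the pass is based on.
#' @param mm \code{MatchMap} from \code{\link{matchLabels}} on the same table
#'   and axis.
#' @param cv \code{\link{cvStats}} output for the same table and axis.
#' @param cvTh CV threshold in force.
#' @param cvRule \code{"ge"} (default) fires when CV >= cvTh; \code{"lt"}
#'   fires when CV < cvTh.
#' @return list with \code{labels} (updated \code{ClusterLabels}) and
#'   \code{nChanged} (cells relabeled).
#' @export
dbRecluster <- function(cPartner, ct, mm, cv, cvTh, cvRule = c("ge", "lt")) {
  cvRule <- match.arg(cvRule)
  stopifnot(is(cPartner, "ClusterLabels"), is(mm, "MatchMap"), cvTh >= 0)
  fire <- .cvFires(cv$cv, cvTh, cvRule)
  firing <- cv$scanned[fire]
  sel <- !mm@matchedMask & mm@scannedCode %in% firing
  lab <- cPartner@labels
  changed <- sum(lab[sel] != mm@partnerDominant[sel])
  lab[sel] <- mm@partnerDominant[sel]
  list(labels = initialize(cPartner, labels = lab), nChanged = changed)
}

#' Copula-based outlier scores (COPOD)
#'
#' Parameter-free outlyingness scores: per feature dimension, the negative log
#' of the left- and right-tail empirical CDF probabilities, combined with a
#' skewness-directed tail choice, taking per-dimension the maximum of the
#' skewness-corrected tail and the mean of the two tails, and summing over
#' dimensions. Deterministic, rank-based (monotone transforms of a dimension
#' leave its contribution's ordering unchanged); higher scores are more
#' outlying.
#'
#' @param features numeric matrix, subgroup cells in rows, embedding
#'   dimensions in columns; at least 2 rows.
#' @return numeric vector of scores, one per row.
#' @examples
#' set.seed(1)
#' x <- rbind(matrix(rnorm(200), 100), c(10, 10))
#' which.max(copodScores(x))
#' @export
copodScores <- function(features) {
  x <- as.matrix(features)
  storage.mode(x) <- "double"
  n <- nrow(x)
  if (n < 2L) stop("COPOD needs at least 2 cells")
  ecdfTail <- function(m) {
    # P(X <= x) with the point itself included: max rank / n, per column
    apply(m, 2L, function(v) rank(v, ties.method = "max") / n)
  }
  ul <- -log(ecdfTail(x))
  ur <- -log(ecdfTail(-x))
  # population skewness sign per dimension (m3 / m2^1.5)
  ctr <- sweep(x, 2L, colMeans(x))
  m2 <- colMeans(ctr^2)
  m3 <- colMeans(ctr^3)
  sk <- sign(ifelse(m2 > 0, m3 / m2^1.5, 0))
  uskew <- sweep(ul, 2L, -sign(sk - 1), `*`) +
           sweep(ur, 2L,  sign(sk + 1), `*`)
  rowSums(pmax(uskew, (ul + ur) / 2))
}

#' Outlier-based re-clustering of one axis
#'
#' The complementary rule to \code{\link{dbRecluster}}: each scanned cluster
#' is treated as a subgroup, its cells scored with \code{\link{copodScores}}
#' on the embedding, and the top \code{contamination} fraction flagged as
#' outliers. Unmatched cells that are \emph{not} outliers join the dominant
#' partner label; flagged cells and matched cells keep their labels (matched
#' cells are never moved, outliers or not). Subgroups smaller than
#' \code{minSubgroup} are skipped untouched.
#'
#' @inheritParams dbRecluster
#' @param features numeric matrix of embedding coordinates, rows aligned with
#'   the cells of \code{cPartner}.
#' @param contamination fraction of each subgroup flagged, in [0, 0.5); the
#'   flag count is \code{round(contamination * subgroup size)}, ties in score
#'   broken toward the earlier cell.
#' @param minSubgroup smallest subgroup scored (default 2).
#' @return list with \code{labels} and \code{nChanged} as in
#'   \code{\link{dbRecluster}}.
#' @export
obRecluster <- function(cPartner, ct, mm, features, contamination = 0.1,
                        minSubgroup = 2L) {
  stopifnot(is(cPartner, "ClusterLabels"), is(mm, "MatchMap"),
            contamination >= 0, contamination < 0.5)
  x <- as.matrix(features)
  if (nrow(x) != length(cPartner@labels))
    stop("features not row-aligned with cells")
  lab <- cPartner@labels
  changed <- 0L
  for (m in mm@pairs$scanned) {
    idx <- which(mm@scannedCode == m)
    s <- length(idx)
    if (s < max(2L, minSubgroup)) next
    scores <- copodScores(x[idx, , drop = FALSE])
    nOut <- floor(contamination * s + 0.5)
    isOut <- logical(s)
    if (nOut > 0L)
      isOut[order(-scores, seq_len(s))[seq_len(nOut)]] <- TRUE
    sel <- idx[!mm@matchedMask[idx] & !isOut]
    dom <- mm@pairs$partner[mm@pairs$scanned == m]
    changed <- changed + sum(lab[sel] != dom)
    lab[sel] <- dom
  }
  list(labels = initialize(cPartner, labels = lab), nChanged = changed)
}
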
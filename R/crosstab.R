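#' Build the cross-tabulation of two labelings
#'
#' Counts, for every pair of cluster codes, the cells assigned that code by
#' method 1 (rows) and method 2 (columns). Cells are paired by position after
#' verifying that the two objects carry identical cell-id sequences; use
#' \code{\link{alignLabels}} first if the files were ordered differently.
#'
#' @param c1,c2 \code{ClusterLabels} over the same cells in the same order.
#' @return a \code{\link{CrossTab}} whose entries sum to the number of cells;
#'   row sums are method-1 cluster sizes and column sums method-2 sizes.
#' @examples
#' ct <- buildCrossTab(ClusterLabels(labels = c(0, 0, 1, 1, 2, 2)),
#'                     ClusterLabels(labels = c(0, 0, 0, 1, 1, 1)))
#' counts(ct)
#' @export
buildCrossTab <- function(c1, c2) {
  stopifnot(is(c1, "ClusterLabels"), is(c2, "ClusterLabels"))
  if (length(c1@labels) == 0L || length(c2@labels) == 0L)
    stop("empty labeling")
  if (length(c1@cellIds) != length(c2@cellIds) ||
      !identical(c1@cellIds, c2@cellIds))
    stop("cell identities differ between the two labelings; ",
         "align them by cell_id first (see alignLabels)")
  rl <- sort(unique(c1@labels))
  cl <- sort(unique(c2@labels))
  tab <- table(factor(c1@labels, levels = rl),
               factor(c2@labels, levels = cl))
  cnt <- matrix(as.integer(tab), nrow = length(rl),
                dimnames = list(as.character(rl), as.character(cl)))
  new("CrossTab", counts = cnt, rowLabels = rl, colLabels = cl)
}

#' Match cluster labels across the two methods
#'
#' Scans one axis of the cross-tabulation and pairs each scanned label with
#' its dominant partner: the label on the other axis holding the largest count
#' in that column (or row). Ties break toward the smaller label. Cells whose
#' two labels form such a pair are "matched"; the remaining cells of each
#' scanned cluster are "unmatched" and are the only candidates for
#' re-clustering.
#'
#' @param ct a \code{CrossTab} built from \code{c1} and \code{c2}.
#' @param c1,c2 the \code{ClusterLabels} the table was built from (needed to
#'   compute the per-cell matched mask).
#' @param axis \code{"columns"} to scan method-2 clusters (dominant partners
#'   are method-1 labels) or \code{"rows"} for the symmetric pass.
#' @return a \code{\link{MatchMap}}.
#' @examples
#' c1 <- ClusterLabels(labels = c(0, 0, 1, 1, 2, 2))
#' c2 <- ClusterLabels(labels = c(0, 0, 0, 1, 1, 1))
#' matchLabels(buildCrossTab(c1, c2), c1, c2, axis = "columns")
#' @export
matchLabels <- function(ct, c1, c2, axis = c("columns", "rows")) {
  axis <- match.arg(axis)
  stopifnot(is(ct, "CrossTab"))
  cnt <- ct@counts
  if (nrow(cnt) < 1L || ncol(cnt) < 1L) stop("degenerate cross-tabulation")
  if (axis == "columns") {
    scannedLab <- ct@colLabels; partnerLab <- ct@rowLabels
    dom <- partnerLab[apply(cnt, 2L, which.max)]  # which.max: smallest index on ties
    scannedCode <- c2@labels; partnerCode <- c1@labels
  } else {
    scannedLab <- ct@rowLabels; partnerLab <- ct@colLabels
    dom <- partnerLab[apply(cnt, 1L, which.max)]
    scannedCode <- c1@labels; partnerCode <- c2@labels
  }
  pairs <- data.frame(scanned = scannedLab, partner = dom)
  perCellDom <- dom[match(scannedCode, scannedLab)]
  new("MatchMap", axis = axis, pairs = pairs,
      matchedMask = partnerCode == perCellDom,
      scannedCode = scannedCode, partnerDominant = perCellDom)
}

#' Serialize a cross-tabulation to CSV
#'
#' Writes the count matrix with method-1 labels as the index column and
#' method-2 labels as the header, for inspection outside R.
#'
#' @param ct a \code{CrossTab}.
#' @param path output file.
#' @return \code{path}, invisibly.
#' @export
writeCrossTab <- function(ct, path) {
  stopifnot(is(ct, "CrossTab"))
  df <- data.frame(label1 = ct@rowLabels, ct@counts, check.names = FALSE)
  colnames(df) <- c("label1", as.character(ct@colLabels))
  write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
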
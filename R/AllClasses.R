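#' @import methods
#' @importFrom stats prcomp rmultinom rnorm runif sd quantile
#' @importFrom utils read.csv write.csv packageVersion
NULL

#' ClusterLabels: one hard cluster assignment over a set of cells
#'
#' Container for the cluster labeling produced by a single method: an ordered
#' vector of cell identifiers and one integer cluster code per cell. Codes need
#' not be contiguous; an optional \code{levels} vector keeps the original
#' (e.g. cell-type string) name of each code for round-tripping label files.
#'
#' @slot cellIds character vector of unique cell identifiers.
#' @slot labels integer vector, one cluster code per cell.
#' @slot levels named character vector mapping code (name) to the original
#'   label string; may be empty when labels were numeric to begin with.
#'
#' @examples
#' cl <- ClusterLabels(paste0("cell", 1:4), c(1L, 1L, 2L, 2L))
#' nClusters(cl)
#' @export
setClass("ClusterLabels",
  representation(cellIds = "character", labels = "integer",
                 levels = "character"),
  prototype(levels = character(0)))

setValidity("ClusterLabels", function(object) {
  msg <- NULL
  if (length(object@cellIds) != length(object@labels))
    msg <- c(msg, "cellIds and labels must have equal length")
  if (length(object@labels) == 0L)
    msg <- c(msg, "empty labeling")
  if (anyNA(object@labels) || anyNA(object@cellIds))
    msg <- c(msg, "NA in labels or cellIds")
  if (anyDuplicated(object@cellIds))
    msg <- c(msg, sprintf("duplicate cell_id: '%s'",
                          object@cellIds[anyDuplicated(object@cellIds)]))
  if (is.null(msg)) TRUE else msg
})

#' @rdname ClusterLabels-class
#' @param cellIds character vector of cell identifiers; generated as
#'   \code{cell1..celln} when omitted.
#' @param labels integer (or coercible) vector of cluster codes.
#' @param levels optional named character vector of original label names.
#' @return a \code{ClusterLabels} object.
#' @export
ClusterLabels <- function(cellIds, labels, levels = character(0)) {
  if (missing(cellIds) || is.null(cellIds))
    cellIds <- paste0("cell", seq_along(labels))
  new("ClusterLabels", cellIds = as.character(cellIds),
      labels = as.integer(labels), levels = levels)
}

#' CrossTab: the 2D cross-tabulation of two labelings
#'
#' An R x C contingency table of cell counts: entry \code{[r, c]} is the number
#' of cells carrying row-method (method 1) label \code{rowLabels[r]} and
#' column-method (method 2) label \code{colLabels[c]}. Labels are kept sorted
#' ascending so serialization is stable.
#'
#' @slot counts non-negative integer matrix summing to the number of cells.
#' @slot rowLabels integer codes of method 1, ascending.
#' @slot colLabels integer codes of method 2, ascending.
#' @export
setClass("CrossTab",
  representation(counts = "matrix", rowLabels = "integer",
                 colLabels = "integer"))

setValidity("CrossTab", function(object) {
  msg <- NULL
  if (nrow(object@counts) != length(object@rowLabels) ||
      ncol(object@counts) != length(object@colLabels))
    msg <- c(msg, "counts dimensions do not match label vectors")
  if (any(object@counts < 0) || any(object@counts != round(object@counts)))
    msg <- c(msg, "counts must be non-negative integers")
  if (is.unsorted(object@rowLabels, strictly = TRUE) ||
      is.unsorted(object@colLabels, strictly = TRUE))
    msg <- c(msg, "row/col labels must be strictly ascending")
  if (is.null(msg)) TRUE else msg
})

#' MatchMap: label correspondence and the matched/unmatched cell split
#'
#' For each label on the scanned axis, the dominant partner label on the other
#' axis (argmax of its count vector; ties broken toward the smaller label), and
#' the induced per-cell partition into matched cells (the cell's two labels
#' form a dominant pair) and unmatched cells.
#'
#' @slot axis \code{"columns"} (scan method-2 clusters) or \code{"rows"}.
#' @slot pairs data.frame with columns \code{scanned}, \code{partner}.
#' @slot matchedMask logical per cell; TRUE iff the cell is matched.
#' @slot scannedCode integer per cell: its label on the scanned axis.
#' @slot partnerDominant integer per cell: the dominant partner label of the
#'   cell's scanned cluster.
#' @export
setClass("MatchMap",
  representation(axis = "character", pairs = "data.frame",
                 matchedMask = "logical", scannedCode = "integer",
                 partnerDominant = "integer"))

setValidity("MatchMap", function(object) {
  msg <- NULL
  if (!object@axis %in% c("columns", "rows"))
    msg <- c(msg, "axis must be 'columns' or 'rows'")
  if (anyDuplicated(object@pairs$scanned))
    msg <- c(msg, "more than one dominant partner for a scanned label")
  n <- length(object@matchedMask)
  if (length(object@scannedCode) != n || length(object@partnerDominant) != n)
    msg <- c(msg, "per-cell vectors must have equal length")
  if (is.null(msg)) TRUE else msg
})

#' EnsembleConfig: tuning knobs of the cross-tabulation ensemble
#'
#' @slot strategy \code{"DB"} (distribution-based, CV threshold) or
#'   \code{"OB"} (outlier-based, COPOD on the embedding).
#' @slot cvInit initial CV threshold of the annealed schedule (default 2).
#' @slot cvStep decrement between rounds (default 0.2).
#' @slot cvFloor value at which the schedule terminates (default 0; the
#'   schedule stops when the threshold reaches the floor, so no round is run
#'   at the floor itself).
#' @slot cvRule \code{"ge"}: a column is corrected when CV >= threshold
#'   (default, consistent with the descending schedule); \code{"lt"} flips the
#'   comparison.
#' @slot contamination fraction of each subgroup flagged as outliers by the
#'   OB rule (default 0.1); flagged cells keep their labels.
#' @slot minSubgroup smallest subgroup the OB rule will score (default 2).
#' @slot maxOuterIter hard cap on outer rounds (default 50).
#' @slot iterate when FALSE, stop after the first round that changes a label
#'   (the non-iterative ablation).
#' @slot stdDdof degrees-of-freedom correction for the CV's standard
#'   deviation: 0 (population, default) or 1 (sample).
#' @slot chRemoval drop the worst input by Calinski-Harabasz score before the
#'   multi-method merge loop (default TRUE).
#' @slot anchor which member of a merged pair plays method 1 inside the pair
#'   ensemble: \code{"ch"} (higher CH score, default) or \code{"first"}.
#' @slot seed integer seed for the randomized helpers (synthetic data); the
#'   ensemble itself is deterministic.
#' @export
setClass("EnsembleConfig",
  representation(strategy = "character", cvInit = "numeric",
                 cvStep = "numeric", cvFloor = "numeric", cvRule = "character",
                 contamination = "numeric", minSubgroup = "integer",
                 maxOuterIter = "integer", iterate = "logical",
                 stdDdof = "integer", chRemoval = "logical",
                 anchor = "character", seed = "integer"))

setValidity("EnsembleConfig", function(object) {
  msg <- NULL
  if (!object@strategy %in% c("DB", "OB"))
    msg <- c(msg, "strategy must be 'DB' or 'OB'")
  if (!object@cvRule %in% c("ge", "lt"))
    msg <- c(msg, "cvRule must be 'ge' or 'lt'")
  if (object@cvInit < object@cvFloor)
    msg <- c(msg, "cvInit must be >= cvFloor")
  if (object@cvStep <= 0) msg <- c(msg, "cvStep must be positive")
  if (object@contamination < 0 || object@contamination >= 0.5)
    msg <- c(msg, "contamination must lie in [0, 0.5)")
  if (object@maxOuterIter < 1L) msg <- c(msg, "maxOuterIter must be >= 1")
  if (!object@anchor %in% c("ch", "first"))
    msg <- c(msg, "anchor must be 'ch' or 'first'")
  if (is.null(msg)) TRUE else msg
})

#' @rdname EnsembleConfig-class
#' @param strategy,cvInit,cvStep,cvFloor,cvRule,contamination,minSubgroup
#'   see the class slots.
#' @param maxOuterIter,iterate,stdDdof,chRemoval,anchor,seed see the class
#'   slots.
#' @return an \code{EnsembleConfig}.
#' @examples
#' ensembleConfig(strategy = "OB", contamination = 0.05)
#' @export
ensembleConfig <- function(strategy = c("DB", "OB"), cvInit = 2, cvStep = 0.2,
                           cvFloor = 0, cvRule = c("ge", "lt"),
                           contamination = 0.1, minSubgroup = 2L,
                           maxOuterIter = 50L, iterate = TRUE, stdDdof = 0L,
                           chRemoval = TRUE, anchor = c("ch", "first"),
                           seed = 1L) {
  new("EnsembleConfig", strategy = match.arg(strategy), cvInit = cvInit,
      cvStep = cvStep, cvFloor = cvFloor, cvRule = match.arg(cvRule),
      contamination = contamination, minSubgroup = as.integer(minSubgroup),
      maxOuterIter = as.integer(maxOuterIter), iterate = iterate,
      stdDdof = as.integer(stdDdof), chRemoval = chRemoval,
      anchor = match.arg(anchor), seed = as.integer(seed))
}

#' CTECResult: consensus labeling plus the iteration trace
#'
#' @slot ensemble the consensus \code{ClusterLabels} (the converged method-1
#'   labeling).
#' @slot trace data.frame with one row per outer round: threshold in force,
#'   labels changed in the column and row passes, cluster counts of the two
#'   updated labelings.
#' @slot termination one of \code{"converged"}, \code{"cv_floor"},
#'   \code{"early_stop"}, \code{"iter_cap"}, \code{"single_pass"}.
#' @slot config the \code{EnsembleConfig} used.
#' @slot history list with scheduler details when produced by
#'   \code{\link{ctecMulti}} (CH scores, removed input, merge order).
#' @export
setClass("CTECResult",
  representation(ensemble = "ClusterLabels", trace = "data.frame",
                 termination = "character", config = "EnsembleConfig",
                 history = "list"),
  prototype(history = list()))
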
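#' @importFrom BiocGenerics counts
NULL

#' @export
setGeneric("cellIds", function(x) standardGeneric("cellIds"))

#' @export
setGeneric("nClusters", function(x) standardGeneric("nClusters"))

#' @export
setGeneric("consensus", function(x) standardGeneric("consensus"))

#' @export
setGeneric("termination", function(x) standardGeneric("termination"))

#' @export
setGeneric("traceTable", function(x) standardGeneric("traceTable"))

#' Accessors
#'
#' \code{cellIds} returns the ordered cell identifiers; \code{labels} the
#' integer cluster codes; \code{nClusters} the number of distinct codes;
#' \code{counts} the contingency matrix of a \code{CrossTab};
#' \code{consensus}, \code{traceTable} and \code{termination} unpack a
#' \code{CTECResult}.
#'
#' @param x a \code{ClusterLabels}, \code{CrossTab} or \code{CTECResult}.
#' @param object a \code{ClusterLabels} (for \code{labels}).
#' @param ... ignored.
#' @return the slot value described above.
#' @name accessors
#' @aliases cellIds nClusters consensus termination traceTable
#' @examples
#' cl <- ClusterLabels(labels = c(1, 1, 2))
#' labels(cl)
#' nClusters(cl)
NULL

#' @rdname accessors
#' @export
setMethod("cellIds", "ClusterLabels", function(x) x@cellIds)

#' @rdname accessors
#' @export
setMethod("labels", "ClusterLabels", function(object, ...) object@labels)

#' @rdname accessors
#' @export
setMethod("nClusters", "ClusterLabels",
          function(x) length(unique(x@labels)))

#' @rdname accessors
#' @export
setMethod("counts", "CrossTab", function(object) object@counts)

#' @rdname accessors
#' @export
setMethod("consensus", "CTECResult", function(x) x@ensemble)

#' @rdname accessors
#' @export
setMethod("termination", "CTECResult", function(x) x@termination)

#' @rdname accessors
#' @export
setMethod("traceTable", "CTECResult", function(x) x@trace)

setMethod("show", "ClusterLabels", function(object) {
  k <- length(unique(object@labels))
  cat(sprintf("ClusterLabels: %d cells, %d clusters\n",
              length(object@labels), k))
  tab <- sort(table(object@labels), decreasing = TRUE)
  cat("  sizes:", paste(utils::head(tab, 8), collapse = " "),
      if (length(tab) > 8) "..." else "", "\n")
})

setMethod("show", "CrossTab", function(object) {
  cat(sprintf("CrossTab: %d x %d, %d cells\n", nrow(object@counts),
              ncol(object@counts), sum(object@counts)))
  print(object@counts)
})

setMethod("show", "MatchMap", function(object) {
  cat(sprintf("MatchMap (%s): %d pairs, %d/%d cells matched\n", object@axis,
              nrow(object@pairs), sum(object@matchedMask),
              length(object@matchedMask)))
})

setMethod("show", "EnsembleConfig", function(object) {
  cat(sprintf(
    "EnsembleConfig: strategy=%s cvInit=%g cvStep=%g cvRule=%s contamination=%g\n",
    object@strategy, object@cvInit, object@cvStep, object@cvRule,
    object@contamination))
})

setMethod("show", "CTECResult", function(object) {
  cat(sprintf("CTECResult: %d cells, %d clusters, %d rounds, termination=%s\n",
              length(object@ensemble@labels),
              length(unique(object@ensemble@labels)),
              nrow(object@trace), object@termination))
})
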
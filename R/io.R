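.sepFor <- function(path) if (grepl("\\.tsv$", path, ignore.case = TRUE))
  "\t" else ","

#' Read a per-cell label table
#'
#' Loads a headered CSV/TSV with columns \code{cell_id} and \code{label}.
#' Arbitrary (string) labels are mapped to stable integer codes in sorted
#' order of first appearance of the sorted unique values; the mapping is kept
#' in the object's \code{levels} slot so outputs can restore the original
#' names.
#'
#' @param path CSV (comma) or TSV (tab) file with \code{cell_id,label}.
#' @return a \code{\link{ClusterLabels}}.
#' @export
readLabels <- function(path) {
  df <- read.csv(path, sep = .sepFor(path), stringsAsFactors = FALSE)
  if (nrow(df) == 0L) stop("empty label file: ", path)
  if (!all(c("cell_id", "label") %in% colnames(df)))
    stop("label file must have columns 'cell_id' and 'label': ", path)
  dup <- df$cell_id[duplicated(df$cell_id)]
  if (length(dup))
    stop("duplicate cell_id '", dup[1L], "' in ", path)
  lev <- sort(unique(as.character(df$label)))
  codes <- match(as.character(df$label), lev)
  ClusterLabels(df$cell_id, codes,
                levels = stats::setNames(lev, seq_along(lev)))
}

#' Reorder a labeling to a reference cell-id sequence
#'
#' @param x a \code{ClusterLabels}.
#' @param refIds character vector of cell ids (e.g. \code{cellIds} of another
#'   labeling, or rownames of a feature matrix).
#' @return \code{x} reordered to \code{refIds}; a warning is emitted when the
#'   order actually changes, and an error when the id sets differ.
#' @export
alignLabels <- function(x, refIds) {
  stopifnot(is(x, "ClusterLabels"))
  if (identical(x@cellIds, refIds)) return(x)
  if (!setequal(x@cellIds, refIds) || length(refIds) != length(x@cellIds))
    stop("cell id sets differ; cannot align")
  warning("reordering cells by cell_id to match the reference")
  idx <- match(refIds, x@cellIds)
  initialize(x, cellIds = x@cellIds[idx], labels = x@labels[idx])
}

#' Write a labeling, preserving the input schema
#'
#' Emits \code{cell_id,label} (original label names when known) and, when
#' \code{ensemble} is supplied, an extra \code{ctec_label} column with the
#' consensus codes.
#'
#' @param x a \code{ClusterLabels}.
#' @param path output CSV/TSV path.
#' @param ensemble optional second \code{ClusterLabels} over the same cells.
#' @return \code{path}, invisibly.
#' @export
writeLabels <- function(x, path, ensemble = NULL) {
  stopifnot(is(x, "ClusterLabels"))
  lab <- if (length(x@levels)) x@levels[as.character(x@labels)] else x@labels
  df <- data.frame(cell_id = x@cellIds, label = lab)
  if (!is.null(ensemble)) {
    stopifnot(identical(ensemble@cellIds, x@cellIds))
    df$ctec_label <- ensemble@labels
  }
  sep <- .sepFor(path)
  utils::write.table(df, path, sep = sep, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read a cells-x-dimensions feature matrix
#'
#' Supported inputs: a dense CSV/TSV whose first column is \code{cell_id}
#' (remaining columns numeric), or a MatrixMarket expression triplet (genes in
#' rows, cells in columns, as written by common single-cell pipelines) with
#' barcode and gene sidecar files, which is transposed and passed through the
#' log1p + PCA convenience path via \code{\link{expressionToPCA}}.
#'
#' @param path the CSV/TSV or \code{.mtx} file.
#' @param kind \code{"csv"} (also TSV) or \code{"mtx"}; guessed from the
#'   extension by default.
#' @param barcodes,genes sidecar paths for \code{kind = "mtx"}; defaults are
#'   \code{barcodes.tsv} and \code{genes.tsv} next to the matrix.
#' @param dim target PCA dimension for the expression path (default 50,
#'   capped at the matrix rank).
#' @param pca for \code{kind = "mtx"}: run the log1p + PCA convenience path
#'   (default TRUE); set FALSE to get the dense cells x genes matrix as read.
#' @return numeric matrix with cell ids as rownames.
#' @export
readFeatures <- function(path, kind = NULL, barcodes = NULL, genes = NULL,
                         dim = 50L, pca = TRUE) {
  if (is.null(kind))
    kind <- if (grepl("\\.mtx$", path, ignore.case = TRUE)) "mtx" else "csv"
  if (kind == "csv") {
    df <- read.csv(path, sep = .sepFor(path), stringsAsFactors = FALSE)
    idCol <- if ("cell_id" %in% colnames(df)) "cell_id" else colnames(df)[1L]
    x <- as.matrix(df[setdiff(colnames(df), idCol)])
    if (!is.numeric(x)) stop("non-numeric feature columns in ", path)
    rownames(x) <- as.character(df[[idCol]])
    return(x)
  }
  if (kind != "mtx") stop("unsupported feature input kind: ", kind)
  m <- Matrix::readMM(path)
  dirn <- dirname(path)
  if (is.null(barcodes)) barcodes <- file.path(dirn, "barcodes.tsv")
  if (is.null(genes)) genes <- file.path(dirn, "genes.tsv")
  bc <- readLines(barcodes)
  if (length(bc) != ncol(m))
    stop("barcode count does not match matrix columns")
  expr <- t(as.matrix(m))  # cells x genes
  rownames(expr) <- bc
  if (!pca) return(expr)
  expressionToPCA(expr, dim = dim)
}

#' Log-transform an expression matrix and project onto PCA coordinates
#'
#' Convenience path for raw counts: log1p, column centering, then the leading
#' principal components. The requested dimension is capped at the matrix rank;
#' a warning reports the cap. The decomposition is deterministic (exact SVD,
#' no randomized solver).
#'
#' @param expr cells x genes numeric matrix.
#' @param dim number of components (default 50).
#' @param log1p apply \code{log1p} first (default TRUE).
#' @return cells x dim matrix of PCA coordinates, rownames preserved.
#' @export
expressionToPCA <- function(expr, dim = 50L, log1p = TRUE) {
  x <- as.matrix(expr)
  if (log1p) x <- log1p(x)
  maxRank <- min(nrow(x) - 1L, ncol(x))
  if (dim > maxRank) {
    warning("requested ", dim, " components but rank allows at most ",
            maxRank, "; capping")
    dim <- maxRank
  }
  p <- prcomp(x, center = TRUE, scale. = FALSE, rank. = dim)
  out <- p$x
  rownames(out) <- rownames(x)
  out
}

#' Write a feature matrix as dense CSV
#'
#' @param x cells x dimensions matrix with cell ids as rownames.
#' @param path output CSV path.
#' @return \code{path}, invisibly.
#' @export
writeFeatures <- function(x, path) {
  df <- data.frame(cell_id = rownames(x), as.data.frame(x),
                   check.names = FALSE)
  write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Run manifest for reproducibility
#'
#' Snapshot of a run: input paths with md5 checksums, the configuration, the
#' package version and the termination trace, as written next to every CLI
#' output.
#'
#' @param inputs named character vector of input file paths.
#' @param config an \code{EnsembleConfig} (or NULL).
#' @param result a \code{CTECResult} (or NULL).
#' @param timing named numeric vector of stage timings in seconds.
#' @return a list ready for \code{jsonlite::write_json}.
#' @export
runManifest <- function(inputs = character(0), config = NULL, result = NULL,
                        timing = numeric(0)) {
  cfg <- if (is.null(config)) NULL else {
    sl <- getSlots("EnsembleConfig")
    stats::setNames(lapply(names(sl), function(s) slot(config, s)), names(sl))
  }
  list(package = "CTEC",
       version = as.character(packageVersion("CTEC")),
       inputs = as.list(inputs),
       checksums = as.list(tools::md5sum(inputs[file.exists(inputs)])),
       config = cfg,
       termination = if (is.null(result)) NULL else termination(result),
       timing = as.list(timing))
}
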
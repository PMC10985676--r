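#' Ensemble two clusterings by iterative cross-tabulation rectification
#'
#' The core two-method loop. Each outer round (i) builds the cross-tabulation
#' of the current method-1 and method-2 labelings, (ii) corrects method 1 from
#' the column-wise pass, (iii) rebuilds the table and corrects method 2 from
#' the row-wise pass. Under the distribution-based strategy the CV threshold
#' starts at \code{cvInit} and is annealed down by \code{cvStep} between
#' rounds until it reaches \code{cvFloor}, progressively admitting more
#' clusters for correction; the loop stops early when two consecutive
#' thresholds change no labels after updates have begun. Under the
#' outlier-based strategy there is no threshold and the loop runs to a label
#' fixed point. A round in which every cell is matched on both axes is a
#' provable fixed point and terminates the loop as converged. The consensus
#' returned is the final method-1 labeling.
#'
#' @param c1,c2 \code{ClusterLabels} over the same cells in the same order;
#'   method 1 is the convergence anchor and is corrected first.
#' @param features numeric matrix (cells x dimensions, e.g. PCA coordinates),
#'   row-aligned with the cells; required for strategy \code{"OB"}, unused by
#'   \code{"DB"}.
#' @param config an \code{\link{ensembleConfig}}.
#' @return a \code{\link{CTECResult}}; \code{consensus(x)} is the ensemble
#'   labeling, \code{traceTable(x)} the per-round record and
#'   \code{termination(x)} the stop reason.
#' @examples
#' c1 <- ClusterLabels(labels = rep(1:3, each = 20))
#' res <- ctecPair(c1, c1, config = ensembleConfig("DB"))
#' termination(res)
#' @export
ctecPair <- function(c1, c2, features = NULL, config = ensembleConfig()) {
  stopifnot(is(c1, "ClusterLabels"), is(c2, "ClusterLabels"),
            is(config, "EnsembleConfig"))
  validObject(config)
  if (!identical(c1@cellIds, c2@cellIds))
    stop("cell identities differ between the two labelings")
  db <- config@strategy == "DB"
  if (!db) {
    if (is.null(features)) stop("strategy 'OB' requires a feature matrix")
    features <- as.matrix(features)
    if (nrow(features) != length(c1@labels))
      stop("features not row-aligned with cells")
  }
  cvTh <- config@cvInit
  prevChanged <- NA_integer_
  everChanged <- FALSE
  term <- "iter_cap"
  rows <- vector("list", config@maxOuterIter)

  onePass <- function(cPartner, cScanned, axis) {
    if (axis == "columns") ct <- buildCrossTab(cPartner, cScanned)
    else ct <- buildCrossTab(cScanned, cPartner)
    mm <- if (axis == "columns") matchLabels(ct, cPartner, cScanned, "columns")
          else matchLabels(ct, cScanned, cPartner, "rows")
    upd <- if (db)
      dbRecluster(cPartner, ct, mm, cvStats(ct, axis, config@stdDdof),
                  cvTh, config@cvRule)
    else
      obRecluster(cPartner, ct, mm, features, config@contamination,
                  config@minSubgroup)
    upd$allMatched <- all(mm@matchedMask)
    upd
  }

  for (it in seq_len(config@maxOuterIter)) {
    colPass <- onePass(c1, c2, "columns")   # update method 1 -> C1'
    c1 <- colPass$labels
    rowPass <- onePass(c2, c1, "rows")      # update method 2 -> C2'
    c2 <- rowPass$labels
    total <- colPass$nChanged + rowPass$nChanged
    rows[[it]] <- data.frame(round = it, cv_th = if (db) cvTh else NA_real_,
                             changed_col = colPass$nChanged,
                             changed_row = rowPass$nChanged,
                             k1 = length(unique(c1@labels)),
                             k2 = length(unique(c2@labels)))
    if (colPass$allMatched && rowPass$allMatched) { term <- "converged"; break }
    if (!db && total == 0L) { term <- "converged"; break }
    if (!config@iterate && total > 0L) { term <- "single_pass"; break }
    if (db && everChanged && total == 0L &&
        !is.na(prevChanged) && prevChanged == 0L) { term <- "early_stop"; break }
    if (total > 0L) everChanged <- TRUE
    prevChanged <- total
    if (db) {
      cvTh <- cvTh - config@cvStep
      if (cvTh <= config@cvFloor + 1e-9) { term <- "cv_floor"; break }
    }
  }
  new("CTECResult", ensemble = c1,
      trace = do.call(rbind, rows[!vapply(rows, is.null, logical(1))]),
      termination = term, config = config)
}

.chOrMinusInf <- function(features, cl) {
  v <- chScore(features, cl)
  if (is.na(v)) -Inf else v
}

#' Progressive ensemble of more than two clusterings
#'
#' The multi-method scheduler: (i) score every input labeling with the
#' Calinski-Harabasz index on the embedding and drop the worst one (skipped
#' when only two inputs remain or \code{chRemoval} is off; an input with a
#' single cluster has an undefined score and is treated as worst); (ii) while
#' more than one labeling remains, compute all pairwise adjusted Rand indices,
#' pick the most dissimilar pair (lowest ARI; ties toward the earliest pair in
#' input order), ensemble it with \code{\link{ctecPair}} -- the member with
#' the higher CH score playing method 1 -- and put the merged result back in
#' the queue. The last survivor is the consensus.
#'
#' @param results list of \code{ClusterLabels}, all over the same cells.
#' @param features numeric matrix of embedding coordinates (needed for the CH
#'   scores, and by the OB strategy).
#' @param config an \code{\link{ensembleConfig}}; \code{chRemoval} and
#'   \code{anchor} control the scheduler.
#' @return a \code{\link{CTECResult}} whose \code{history} records the CH
#'   scores, any removed input and the merge order.
#' @export
ctecMulti <- function(results, features, config = ensembleConfig()) {
  stopifnot(is.list(results), length(results) >= 2L,
            all(vapply(results, is, logical(1), "ClusterLabels")))
  features <- as.matrix(features)
  names(results) <- if (is.null(names(results)))
    paste0("input", seq_along(results)) else names(results)
  ch <- vapply(results, function(r) .chOrMinusInf(features, r), numeric(1))
  history <- list(ch_scores = ch, removed = NA_character_, merges = list())
  if (config@chRemoval && length(results) > 2L) {
    worst <- which.min(ch)
    history$removed <- names(results)[worst]
    results <- results[-worst]
    ch <- ch[-worst]
  }
  lastRes <- NULL
  while (length(results) > 1L) {
    nIn <- length(results)
    best <- c(1L, 2L); bestAri <- Inf
    for (i in seq_len(nIn - 1L)) for (j in seq.int(i + 1L, nIn)) {
      a <- ari(results[[i]], results[[j]])
      if (a < bestAri) { bestAri <- a; best <- c(i, j) }
    }
    i <- best[1L]; j <- best[2L]
    anchorFirst <- config@anchor != "ch" || ch[i] >= ch[j]
    a1 <- if (anchorFirst) results[[i]] else results[[j]]
    a2 <- if (anchorFirst) results[[j]] else results[[i]]
    lastRes <- ctecPair(a1, a2, features, config)
    merged <- consensus(lastRes)
    mergedName <- paste0(names(results)[i], "+", names(results)[j])
    history$merges <- c(history$merges, list(list(
      pair = names(results)[best], ari = bestAri,
      anchor = names(results)[if (anchorFirst) i else j],
      termination = termination(lastRes))))
    keep <- setdiff(seq_len(nIn), best)
    results <- c(results[keep], stats::setNames(list(merged), mergedName))
    ch <- c(ch[keep], stats::setNames(.chOrMinusInf(features, merged),
                                      mergedName))
  }
  new("CTECResult", ensemble = results[[1L]], trace = traceTable(lastRes),
      termination = termination(lastRes), config = config,
      history = history)
}
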
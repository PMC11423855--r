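#' Top-k retrieval accuracy over a labeled database
#'
#' Uses every database entry in turn as a query against the remaining
#' entries and measures how many of its `k` nearest neighbours share its
#' group label. The per-query score is the hit count divided by
#' `min(k, group_size - 1)` — the number of same-group entries that could
#' possibly be retrieved — and the returned accuracy is the mean over
#' queries. Queries whose group has no other member are excluded (they have
#' nothing to retrieve). The metric depends only on the distance ranking,
#' so it is invariant to any monotone transform of the distances.
#'
#' @param db a [descriptor_db].
#' @param labels named character vector (names = structure ids) or a data
#'   frame with columns `structure_id` and `group`; every db id must be
#'   labeled.
#' @param k neighbourhood size (>= 1).
#' @return mean per-query accuracy in `[0, 1]`.
#' @export
topk_accuracy <- function(db, labels, k = 10L) {
  stopifnot(inherits(db, "descriptor_db"))
  if (k < 1L) stop("k must be >= 1")
  if (is.data.frame(labels))
    labels <- stats::setNames(as.character(labels$group), labels$structure_id)
  miss <- setdiff(db$ids, names(labels))
  if (length(miss))
    stop("unlabeled database ids: ", paste(utils::head(miss, 5L), collapse = ", "))
  lab <- labels[db$ids]
  gsize <- table(lab)
  dmat <- as.matrix(stats::dist(db$vectors))
  scores <- numeric(0L)
  for (i in seq_along(db$ids)) {
    avail <- as.integer(gsize[[lab[i]]]) - 1L
    if (avail < 1L) next
    d <- dmat[i, -i]
    ids <- db$ids[-i]
    kk <- min(k, length(d))
    sel <- order(d, ids, method = "radix")[seq_len(kk)]
    hits <- sum(lab[match(ids[sel], db$ids)] == lab[i])
    scores <- c(scores, hits / min(k, avail))
  }
  if (!length(scores))
    stop("no query has a same-group partner; accuracy undefined")
  mean(scores)
}

#' ROC and precision-recall curves for scored structure pairs
#'
#' Standard threshold-sweep evaluation of a binary similar/dissimilar
#' labeling against a distance score (smaller distance = more similar; the
#' score is negated internally so thresholding runs from most to least
#' similar). Tied scores move as one block. The ROC area is computed by the
#' trapezoid rule (equal to the Mann-Whitney pairwise-comparison statistic
#' with ties counted 1/2) and average precision by the step sum
#' `sum (R_i - R_{i-1}) P_i`.
#'
#' @param pairs data frame with a `score` column (distance) and a `positive`
#'   logical column; id columns are allowed and ignored. Both classes must
#'   be present.
#' @return list with `roc` (data frame `fpr`, `tpr`), `auc`, `pr` (data
#'   frame `recall`, `precision`), `ap`.
#' @export
roc_pr <- function(pairs) {
  stopifnot(is.data.frame(pairs), all(c("score", "positive") %in% names(pairs)))
  y <- as.logical(pairs$positive)
  s <- -as.numeric(pairs$score)          # larger = more similar
  if (!any(y) || all(y))
    stop("need at least one positive and one negative pair")
  if (!all(is.finite(s))) stop("non-finite scores")
  ord <- order(s, decreasing = TRUE)
  y <- y[ord]; s <- s[ord]
  # collapse tied scores into single thresholds
  last_of_block <- c(diff(s) != 0, TRUE)
  tp <- cumsum(y)[last_of_block]
  fp <- cumsum(!y)[last_of_block]
  P <- sum(y); Ng <- sum(!y)
  tpr <- c(0, tp / P); fpr <- c(0, fp / Ng)
  auc <- sum(diff(fpr) * (utils::head(tpr, -1L) + utils::tail(tpr, -1L)) / 2)
  prec <- tp / (tp + fp)
  rec <- tp / P
  ap <- sum(diff(c(0, rec)) * prec)
  list(roc = data.frame(fpr = fpr, tpr = tpr), auc = auc,
       pr = data.frame(recall = rec, precision = prec), ap = ap)
}
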
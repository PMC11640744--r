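#' The 60-configuration kNN parameter grid
#'
#' k in 1..10, distance in {cityblock, euclidean, cosine}, weighting in
#' {inverse, equal}: 10 x 3 x 2 = 60 configurations, in a fixed enumeration
#' order (k fastest, then distance, then weighting).
#'
#' @return Data frame with columns `k`, `distance`, `weighting` (60 rows).
#' @export
knn_grid <- function() {
  g <- expand.grid(k = 1:10,
                   distance = c("cityblock", "euclidean", "cosine"),
                   weighting = c("inverse", "equal"),
                   stringsAsFactors = FALSE)
  g[order(g$weighting, g$distance, g$k), ][, c("k", "distance", "weighting")]
}

# Pairwise distances between rows of `a` (queries) and rows of `b`
# (references). Cosine distance of a zero vector is defined as 1.
pair_distances <- function(a, b, distance) {
  switch(distance,
    euclidean = {
      d2 <- outer(rowSums(a ^ 2), rowSums(b ^ 2), `+`) - 2 * tcrossprod(a, b)
      sqrt(pmax(d2, 0))
    },
    cityblock = {
      out <- matrix(0, nrow(a), nrow(b))
      for (i in seq_len(nrow(a)))
        out[i, ] <- colSums(abs(t(b) - a[i, ]))
      out
    },
    cosine = {
      na <- sqrt(rowSums(a ^ 2)); nb <- sqrt(rowSums(b ^ 2))
      s <- tcrossprod(a, b) / (outer(na, nb))
      s[!is.finite(s)] <- 0  # zero vectors: undefined cosine -> distance 1
      1 - s
    },
    stop("unknown distance: ", distance))
}

# Predict labels for query points given sorted neighbor labels/distances.
# `ord_lab` / `ord_d`: ntr x nq matrices, neighbors sorted nearest-first per
# column. Ties in class votes/scores fall back to the nearest neighbor's
# class, then to the lower label.
predict_from_sorted <- function(ord_lab, ord_d, k, weighting, classes,
                                delta = 1e-12) {
  is1 <- ord_lab[seq_len(k), , drop = FALSE] == classes[1L]
  if (weighting == "equal") {
    s1 <- colSums(is1)
    s2 <- k - s1
  } else {
    wts <- 1 / pmax(ord_d[seq_len(k), , drop = FALSE], delta)
    s1 <- colSums(wts * is1)
    s2 <- colSums(wts) - s1
  }
  out <- ifelse(s1 > s2, classes[1L],
                ifelse(s2 > s1, classes[2L], ord_lab[1L, ]))
  as.vector(out)
}

#' k-nearest-neighbour prediction
#'
#' Distances: `cityblock` (L1), `euclidean` (L2) or `cosine` (1 - cosine
#' similarity; zero vectors get distance 1). `equal` weighting takes the
#' majority vote among the k nearest training points; `inverse` scores each
#' class by the sum of 1/max(d, 1e-12) over its neighbours. Vote/score ties
#' resolve to the single nearest neighbour's class, then the lower label;
#' equidistant neighbours rank by training-row order.
#'
#' @param train_features,test_features Numeric matrices with matching
#'   columns.
#' @param train_labels Label vector for the training rows (two classes).
#' @param k Neighbourhood size (1..nrow(train_features)).
#' @param distance `"cityblock"`, `"euclidean"` or `"cosine"`.
#' @param weighting `"inverse"` or `"equal"`.
#' @return Predicted label vector, one per test row.
#' @export
knn_predict <- function(train_features, train_labels, test_features,
                        k = 1L, distance = "cityblock", weighting = "equal") {
  train_features <- as.matrix(train_features)
  test_features <- as.matrix(test_features)
  if (nrow(test_features) == 0L) stop("empty test set")
  if (k > nrow(train_features)) stop("k exceeds training-set size")
  classes <- sort(unique(train_labels))
  if (length(classes) < 2L) stop("training labels contain a single class")
  D <- pair_distances(test_features, train_features, distance)
  ord <- apply(D, 1L, order)                      # ntr x nq, stable
  if (is.null(dim(ord))) ord <- matrix(ord, ncol = nrow(D))
  ord_lab <- matrix(train_labels[ord], nrow = nrow(ord))
  ord_d <- matrix(D[cbind(rep(seq_len(nrow(D)), each = nrow(ord)),
                          as.vector(ord))], nrow = nrow(ord))
  predict_from_sorted(ord_lab, ord_d, k, weighting, classes)
}

new_outcome <- function(predictions, labels, provenance) {
  structure(list(predictions = predictions,
                 accuracy = mean(predictions == labels),
                 provenance = provenance),
            class = "knn_outcome")
}

#' @export
print.knn_outcome <- function(x, ...) {
  prov <- x$provenance
  desc <- switch(prov$type,
                 parameter = sprintf("k=%d %s/%s", prov$k, prov$distance,
                                     prov$weighting),
                 voted = sprintf("voted rank %d", prov$rank),
                 fused = "fused", prov$type)
  cat(sprintf("<knn_outcome %s> accuracy %.4f over %d segments\n",
              desc, x$accuracy, length(x$predictions)))
  invisible(x)
}

#' Out-of-fold outcomes for all 60 kNN configurations
#'
#' For each configuration of [knn_grid()], out-of-fold predictions are
#' assembled across all folds into one full-length vector (one prediction
#' per segment, produced while its fold was held out) and scored against the
#' true labels. Per fold, neighbour orderings are computed once per distance
#' metric and reused across all k and weightings.
#'
#' @param features Numeric matrix, segments x features.
#' @param labels True class labels (length = segment count, two classes).
#' @param folds A `fold_plan` from [make_folds()].
#' @return List of 60 `knn_outcome`s, in grid order.
#' @export
parameter_outcomes <- function(features, labels, folds) {
  features <- as.matrix(features)
  n <- nrow(features)
  stopifnot(length(labels) == n, length(folds$assignments) == n)
  classes <- sort(unique(labels))
  grid <- knn_grid()
  preds <- matrix(labels[1L], nrow = n, ncol = nrow(grid))
  metrics <- unique(grid$distance)
  for (f in seq_len(folds$n_folds)) {
    test <- which(folds$assignments == f)
    train <- which(folds$assignments != f)
    if (length(test) == 0L) next
    tl <- labels[train]
    if (length(unique(tl)) < 2L)
      stop("training part of fold ", f, " lacks a class")
    if (length(train) < max(grid$k))
      stop("training part of fold ", f, " has ", length(train),
           " segments, fewer than the largest k (", max(grid$k),
           ") of the parameter grid")
    for (m in metrics) {
      D <- pair_distances(features[test, , drop = FALSE],
                          features[train, , drop = FALSE], m)
      ord <- apply(D, 1L, order)
      if (is.null(dim(ord))) ord <- matrix(ord, ncol = length(test))
      ord_lab <- matrix(tl[ord], nrow = nrow(ord))
      ord_d <- matrix(D[cbind(rep(seq_len(nrow(D)), each = nrow(ord)),
                              as.vector(ord))], nrow = nrow(ord))
      rows <- which(grid$distance == m)
      for (g in rows) {
        preds[test, g] <- predict_from_sorted(ord_lab, ord_d, grid$k[g],
                                              grid$weighting[g], classes)
      }
    }
  }
  lapply(seq_len(nrow(grid)), function(g) {
    new_outcome(preds[, g], labels,
                list(type = "parameter", k = grid$k[g],
                     distance = grid$distance[g],
                     weighting = grid$weighting[g]))
  })
}

#' Iterative majority voting
#'
#' Sorts the m input outcomes by accuracy (descending, ties keep input
#' order) and, for r = 1..m-2, takes the elementwise mode over the top r+2
#' prediction vectors; mode ties resolve to the lower class label. With m
#' inputs this yields m-2 voted outcomes (58 from the 60 parameter-based
#' outcomes, 13 from the 15 per-feature-vector outcomes).
#'
#' @param outcomes List of at least three `knn_outcome`s.
#' @param labels True class labels.
#' @return List of m-2 voted `knn_outcome`s, in increasing r.
#' @export
imv <- function(outcomes, labels) {
  m <- length(outcomes)
  if (m < 3L) stop("iterative majority voting needs at least 3 outcomes")
  acc <- vapply(outcomes, `[[`, 0, "accuracy")
  ord <- order(-acc)  # stable: ties keep original order
  P <- vapply(outcomes[ord], `[[`, numeric(length(labels)), "predictions")
  classes <- sort(unique(labels))
  votes1 <- (P == classes[1L])
  c1 <- rowSums(votes1[, 1:2, drop = FALSE])
  out <- vector("list", m - 2L)
  for (r in seq_len(m - 2L)) {
    c1 <- c1 + votes1[, r + 2L]
    voted <- ifelse(2 * c1 >= r + 2L, classes[1L], classes[2L])  # tie -> lower
    out[[r]] <- new_outcome(voted, labels, list(type = "voted", rank = r))
  }
  out
}

#' Select the most accurate outcome
#'
#' @param outcomes Non-empty list of `knn_outcome`s.
#' @param labels Unused (accuracy is already stored); kept for symmetry.
#' @return The outcome with maximal accuracy; ties go to the earliest.
#' @export
greedy_best <- function(outcomes, labels = NULL) {
  if (length(outcomes) == 0L) stop("empty outcome list")
  outcomes[[which.max(vapply(outcomes, `[[`, 0, "accuracy"))]]
}

#' tkNN: iterative/ensemble kNN for one feature matrix
#'
#' Runs the 60-configuration grid ([parameter_outcomes()]), derives 58 voted
#' outcomes ([imv()]) and greedily selects the most accurate of the 118
#' candidates. The greedy choice uses accuracy against the true labels of
#' all segments — the pipeline's self-organization mechanism, which makes
#' reported per-stage accuracies optimistic (see the package vignette).
#'
#' @inheritParams parameter_outcomes
#' @param return_candidates If `TRUE`, attach all 118 candidates as
#'   attribute `candidates`.
#' @return The best `knn_outcome`.
#' @export
tknn <- function(features, labels, folds, return_candidates = FALSE) {
  po <- parameter_outcomes(features, labels, folds)
  cand <- c(po, imv(po, labels))
  best <- greedy_best(cand)
  if (return_candidates) attr(best, "candidates") <- cand
  best
}

#' Fuse the 15 per-feature-vector outcomes
#'
#' Applies [imv()] to the 15 tkNN outcomes (13 voted candidates) and
#' greedily selects the best voted outcome — the final decision of the
#' pipeline is always a voted outcome.
#'
#' @param outcomes List of per-feature-vector `knn_outcome`s (>= 3).
#' @param labels True class labels.
#' @return The fused `knn_outcome` (provenance records the winning vote
#'   rank).
#' @export
fuse <- function(outcomes, labels) {
  voted <- imv(outcomes, labels)
  best <- greedy_best(voted)
  best$provenance <- list(type = "fused", rank = best$provenance$rank)
  best
}
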
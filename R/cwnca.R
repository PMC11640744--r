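#' Neighborhood component analysis feature weights
#'
#' Diagonal-metric feature-weighting NCA: each feature j carries a weight
#' w_j, the metric between samples is the weighted city-block distance
#' d_ij = sum_j w_j^2 |x_ij - x_i'j|, and the objective is the expected
#' leave-one-out correct-classification probability under a softmax over
#' exp(-d/sigma) reference-point probabilities, minus an L2 penalty
#' lambda * sum(w^2). Weights are fit by fixed-iteration gradient ascent
#' from the all-ones vector; negative weights are clipped to zero on output.
#' Features are z-scored internally; zero-variance columns get weight 0.
#'
#' @param features Numeric matrix, samples x features.
#' @param labels Class label vector (two or more classes, >= 2 samples each).
#' @param sigma Kernel width of the softmax (default 1).
#' @param lambda L2 regularization; default `1/n` (n = sample count).
#' @param iters Gradient-ascent iterations (default 100).
#' @param lr Step size (default 0.1).
#' @param seed Kept for interface stability; the fixed-start ascent is
#'   deterministic and draws no random numbers.
#' @return Nonnegative weight vector, one entry per feature column.
#' @export
nca_weights <- function(features, labels, sigma = 1, lambda = NULL,
                        iters = 100L, lr = 0.1, seed = 1L) {
  if (!is.matrix(features)) features <- as.matrix(features)
  n <- nrow(features)
  if (n < 2L || ncol(features) == 0L) stop("empty or degenerate feature matrix")
  if (length(labels) != n) stop("labels length must match row count")
  if (length(unique(labels)) < 2L) stop("labels contain a single class")
  if (min(table(labels)) < 2L) stop("each class needs at least 2 samples")
  if (is.null(lambda)) lambda <- 1 / n
  sds <- apply(features, 2L, stats::sd)
  keep <- which(sds > 0)
  X <- scale(features[, keep, drop = FALSE])
  same <- outer(labels, labels, `==`)
  diag(same) <- FALSE
  w <- .nca_fit_cpp(X, same, sigma, lambda, as.integer(iters), lr)
  out <- numeric(ncol(features))
  out[keep] <- pmax(w, 0)
  out
}

# Pure-R reference path (same mathematics, no compiled code); retained as the
# independent check of the compiled fit and for gradient verification.
nca_weights_ref <- function(features, labels, sigma = 1, lambda = NULL,
                            iters = 100L, lr = 0.1) {
  prep <- nca_prepare(features, labels, sigma = sigma, lambda = lambda)
  w <- rep(1, prep$p)
  for (it in seq_len(iters)) {
    w <- w + lr * nca_gradient(w, prep)
  }
  out <- numeric(ncol(features))
  out[prep$keep] <- pmax(w, 0)
  out
}

# Precompute the pairwise absolute-difference matrix (n^2 x p, pair (i,j) at
# row (j-1)*n + i) and bookkeeping shared by the objective and gradient.
nca_prepare <- function(features, labels, sigma = 1, lambda = NULL,
                        standardize = TRUE) {
  if (!is.matrix(features)) features <- as.matrix(features)
  n <- nrow(features)
  if (n < 2L || ncol(features) == 0L) stop("empty or degenerate feature matrix")
  if (length(labels) != n) stop("labels length must match row count")
  if (length(unique(labels)) < 2L) stop("labels contain a single class")
  if (min(table(labels)) < 2L) stop("each class needs at least 2 samples")
  if (is.null(lambda)) lambda <- 1 / n
  sds <- apply(features, 2L, stats::sd)
  keep <- which(sds > 0)
  X <- features[, keep, drop = FALSE]
  if (standardize)
    X <- scale(X, center = TRUE, scale = TRUE)
  p <- length(keep)
  A <- matrix(0, nrow = n * n, ncol = p)
  for (r in seq_len(p)) {
    x <- X[, r]
    A[, r] <- abs(rep(x, times = n) - rep(x, each = n))  # |x_i - x_j|, i fastest
  }
  same <- outer(labels, labels, `==`)
  diag(same) <- FALSE
  list(A = A, same = same, n = n, p = p, sigma = sigma, lambda = lambda,
       keep = keep)
}

# Softmax leave-one-out assignment probabilities P[i, j] for weights w.
nca_probs <- function(w, prep) {
  d <- prep$A %*% (w ^ 2)
  K <- matrix(exp(-d / prep$sigma), prep$n, prep$n)
  diag(K) <- 0
  P <- K / (rowSums(K) + 1e-300)
  P
}

# Regularized expected LOO accuracy: sum_i p_i - lambda * sum(w^2).
nca_objective <- function(w, prep) {
  P <- nca_probs(w, prep)
  sum(P[prep$same]) - prep$lambda * sum(w ^ 2)
}

# Analytic gradient of nca_objective with respect to w.
nca_gradient <- function(w, prep) {
  P <- nca_probs(w, prep)
  pi_i <- rowSums(P * prep$same)
  C <- P * (pi_i - prep$same)  # column-major recycling puts pi_i[i] in row i
  g <- crossprod(prep$A, as.vector(C))
  as.vector((2 * w / prep$sigma) * g - 2 * prep$lambda * w)
}

#' Cumulative-weight feature selection
#'
#' Sorts features by descending weight (ties keep the lower index first),
#' normalizes the weights to sum to one, and selects the smallest prefix
#' whose cumulative normalized weight reaches `threshold`.
#'
#' @param weights Nonnegative weight vector.
#' @param threshold Cumulative-weight threshold in (0, 1] (default 0.99).
#' @return A `selection_result`: list with `weights`, `order` (descending
#'   weight), `nf`, `selected_indices` (first `nf` of `order`) and
#'   `threshold`.
#' @export
cumulative_select <- function(weights, threshold = 0.99) {
  if (any(weights < 0)) stop("weights must be nonnegative")
  if (threshold <= 0 || threshold > 1) stop("threshold must be in (0, 1]")
  ord <- order(-weights)  # stable: ties keep lower index first
  total <- sum(weights)
  if (total == 0) {
    warning("all feature weights are zero; selecting a single feature")
    nf <- 1L
  } else {
    cum <- cumsum(weights[ord]) / total
    nf <- which(cum >= threshold - 1e-12)[1L]
    if (is.na(nf)) nf <- length(weights)
  }
  structure(list(weights = weights, order = ord, nf = as.integer(nf),
                 selected_indices = ord[seq_len(nf)],
                 threshold = threshold),
            class = "selection_result")
}

#' @export
print.selection_result <- function(x, ...) {
  cat(sprintf("<selection_result> %d of %d features (threshold %.3g)\n",
              x$nf, length(x$weights), x$threshold))
  invisible(x)
}

#' Apply a feature selection to a feature matrix
#'
#' Subsets/reorders columns to the selected indices in descending-weight
#' order — the order that also defines the DLob string downstream.
#'
#' @param features Numeric matrix, samples x features.
#' @param sel A `selection_result` from [cumulative_select()].
#' @return Matrix with `sel$nf` columns.
#' @export
apply_selection <- function(features, sel) {
  stopifnot(inherits(sel, "selection_result"))
  if (max(sel$selected_indices) > ncol(features))
    stop("selected index out of range for feature matrix with ",
         ncol(features), " columns")
  features[, sel$selected_indices, drop = FALSE]
}

#' CWNCA: weight, rank and select in one call
#'
#' @inheritParams nca_weights
#' @inheritParams cumulative_select
#' @return A `selection_result`.
#' @export
cwnca <- function(features, labels, threshold = 0.99, sigma = 1,
                  lambda = NULL, iters = 100L, lr = 0.1, seed = 1L) {
  w <- nca_weights(features, labels, sigma = sigma, lambda = lambda,
                   iters = iters, lr = lr, seed = seed)
  cumulative_select(w, threshold)
}
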
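test_that("kNN prediction honours metrics, weighting and tie rules", {
  # zero distance wins under every metric
  tr <- matrix(c(1, 2, 5, 6, 9, 9), 3, 2, byrow = TRUE)
  lab <- c(1L, 2L, 2L)
  for (d in c("cityblock", "euclidean", "cosine"))
    expect_equal(knn_predict(tr, lab, tr[1, , drop = FALSE], k = 1,
                             distance = d), 1L)
  # resubstitution with k = 1 is perfect
  set.seed(71)
  X <- matrix(rnorm(40), 20, 2)
  y <- rep(c(1L, 2L), 10)
  expect_equal(knn_predict(X, y, X, k = 1, distance = "euclidean",
                           weighting = "equal"), y)
  # inverse weighting: train {0 -> 1, 10 -> 2}, test 4: 1/4 > 1/6
  expect_equal(knn_predict(matrix(c(0, 10), 2, 1), c(1L, 2L),
                           matrix(4, 1, 1), k = 2, weighting = "inverse"), 1L)
  # equal-vote tie falls back to the nearest neighbour's class
  expect_equal(knn_predict(matrix(c(0, 3), 2, 1), c(2L, 1L),
                           matrix(1, 1, 1), k = 2, weighting = "equal"), 2L)
  expect_error(knn_predict(X, y, X, k = 21), "exceeds")
  expect_error(knn_predict(X, rep(1L, 20), X, k = 1), "single class")
})

test_that("cosine distance treats zero vectors as maximally distant-but-defined", {
  tr <- rbind(c(1, 0), c(0, 1))
  D <- soxfe:::pair_distances(matrix(0, 1, 2), tr, "cosine")
  expect_equal(as.vector(D), c(1, 1))
  D2 <- soxfe:::pair_distances(rbind(c(2, 0)), tr, "cosine")
  expect_equal(as.vector(D2), c(0, 1))
})

test_that("the parameter grid enumerates exactly 60 configurations", {
  g <- knn_grid()
  expect_equal(nrow(g), 60L)
  expect_equal(sort(unique(g$k)), 1:10)
  expect_setequal(unique(g$distance), c("cityblock", "euclidean", "cosine"))
  expect_setequal(unique(g$weighting), c("inverse", "equal"))
  expect_false(any(duplicated(g)))
})

test_that("out-of-fold outcomes cover all segments and separate easy data", {
  set.seed(83)
  n <- 40
  y <- rep(c(0L, 1L), each = n / 2)
  # clusters separated in both norm and direction so that all three
  # metrics (including cosine) split them perfectly
  X <- rbind(cbind(rnorm(n / 2, 8, 0.3), rnorm(n / 2, 0, 0.3)),
             cbind(rnorm(n / 2, 0, 0.3), rnorm(n / 2, 8, 0.3)))
  man <- data.frame(segment_id = paste0("s", 1:n),
                    record_id = paste0("r", 1:n))
  folds <- make_folds(man, "kfold", 5, seed = 2)
  outs <- parameter_outcomes(X, y, folds)
  expect_length(outs, 60L)
  accs <- vapply(outs, `[[`, 0, "accuracy")
  expect_true(all(accs == 1))  # perfectly separated clusters
  expect_true(all(vapply(outs, function(o) length(o$predictions), 0L) == n))
  # a fold lacking a class is an error
  bad_folds <- folds
  bad_folds$assignments[y == 1L] <- 1L
  bad_folds$assignments[y == 0L] <- 2L
  expect_error(parameter_outcomes(X, y, bad_folds), "lacks a class")
})

test_that("iterative majority voting matches a brute-force per-position tally", {
  set.seed(97)
  n <- 1000
  labels <- sample(c(3L, 7L), n, replace = TRUE)
  voters <- lapply(1:7, function(i) {
    structure(list(predictions = sample(c(3L, 7L), n, replace = TRUE),
                   accuracy = runif(1), provenance = list(type = "parameter")),
              class = "knn_outcome")
  })
  voted <- imv(voters, labels)
  expect_length(voted, 5L)  # m - 2
  acc <- vapply(voters, `[[`, 0, "accuracy")
  ord <- order(-acc)
  P <- sapply(voters[ord], `[[`, "predictions")
  for (r in 1:5)
    expect_identical(voted[[r]]$predictions,
                     ref_mode_vote(P[, 1:(r + 2), drop = FALSE]))
  # three identical vectors vote to themselves
  same <- voters[c(1, 1, 1)]
  expect_identical(imv(same, labels)[[1]]$predictions,
                   same[[1]]$predictions)
  expect_error(imv(voters[1:2], labels), "at least 3")
})

test_that("voted-outcome bookkeeping: 60 inputs give 58, 15 give 13", {
  set.seed(101)
  labels <- rep(c(0L, 1L), 20)
  mk <- function(m) lapply(1:m, function(i) {
    structure(list(predictions = sample(c(0L, 1L), 40, replace = TRUE),
                   accuracy = runif(1), provenance = list(type = "parameter")),
              class = "knn_outcome")
  })
  expect_length(imv(mk(60), labels), 58L)
  expect_length(imv(mk(15), labels), 13L)
})

test_that("greedy selection takes the first maximum", {
  mk <- function(acc) structure(list(predictions = 1L, accuracy = acc,
                                     provenance = list(type = "parameter")),
                                class = "knn_outcome")
  outs <- list(mk(0.7), mk(0.9), mk(0.9))
  expect_identical(greedy_best(outs), outs[[2]])
  expect_identical(greedy_best(outs[1]), outs[[1]])
  expect_error(greedy_best(list()), "empty")
})

test_that("tkNN beats every single configuration and fusion votes over 13", {
  set.seed(103)
  n <- 30
  y <- rep(c(0L, 1L), each = n / 2)
  X <- cbind(y * 2 + rnorm(n, 0, 0.8), rnorm(n))
  man <- data.frame(segment_id = paste0("s", 1:n),
                    record_id = paste0("r", 1:n))
  folds <- make_folds(man, "kfold", 5, seed = 9)
  best <- tknn(X, y, folds, return_candidates = TRUE)
  cand <- attr(best, "candidates")
  expect_length(cand, 118L)  # 60 parameter-based + 58 voted
  par_accs <- vapply(cand[1:60], `[[`, 0, "accuracy")
  expect_gte(best$accuracy, max(par_accs))
  # determinism given folds
  best2 <- tknn(X, y, folds)
  expect_identical(best$predictions, best2$predictions)

  # fusion: identical inputs fuse to themselves; result is a voted outcome
  fifteen <- replicate(15, best, simplify = FALSE)
  fused <- fuse(fifteen, y)
  expect_identical(fused$predictions, best$predictions)
  expect_equal(fused$provenance$type, "fused")
  voted <- imv(fifteen, y)
  expect_length(voted, 13L)
  expect_gte(fused$accuracy, min(vapply(voted, `[[`, 0, "accuracy")))
})
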
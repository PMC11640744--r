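test_that("analytic NCA gradient matches central finite differences", {
  set.seed(17)
  X <- matrix(rnorm(20 * 3), 20, 3)
  y <- rep(c(0, 1), 10)
  prep <- soxfe:::nca_prepare(X, y)
  for (trial in 1:3) {
    w <- runif(3, 0.3, 2)
    g <- soxfe:::nca_gradient(w, prep)
    h <- 1e-5
    fd <- vapply(1:3, function(r) {
      wp <- w; wm <- w
      wp[r] <- w[r] + h; wm[r] <- w[r] - h
      (soxfe:::nca_objective(wp, prep) - soxfe:::nca_objective(wm, prep)) / (2 * h)
    }, 0)
    expect_lt(max(abs(g - fd) / pmax(abs(fd), 1e-8)), 1e-4)
  }
})

test_that("compiled NCA fit agrees with the pure-R reference path", {
  set.seed(29)
  X <- matrix(rnorm(24 * 5), 24, 5)
  X[, 2] <- rep(c(0, 1), 12) + rnorm(24, 0, 0.2)
  y <- rep(c(0, 1), 12)
  expect_equal(nca_weights(X, y, iters = 50),
               soxfe:::nca_weights_ref(X, y, iters = 50), tolerance = 1e-10)
})

test_that("informative features outweigh noise, agreeing with a brute-force grid", {
  set.seed(41)
  n <- 40
  y <- rep(c(0, 1), n / 2)
  X <- cbind(y + rnorm(n, 0, 0.05), rnorm(n))
  w <- nca_weights(X, y)
  expect_gt(w[1], w[2])
  # independent oracle: exhaustive grid over (w1, w2) of the regularized
  # LOO objective on the same standardized data
  Xs <- scale(X)
  grid <- seq(0, 3, by = 0.1)
  best <- c(-Inf, NA, NA)
  for (w1 in grid) for (w2 in grid) {
    val <- ref_nca_objective(c(w1, w2), Xs, y)
    if (val > best[1]) best <- c(val, w1, w2)
  }
  expect_gt(best[2], best[3])  # the grid optimum also favours the signal
  # and the fitted objective is close to the grid optimum
  prep <- soxfe:::nca_prepare(X, y)
  expect_gt(soxfe:::nca_objective(w, prep), best[1] - 0.5)
})

test_that("duplicate columns receive equal weights and zero-variance columns get zero", {
  set.seed(53)
  x <- rep(c(0, 1), 15) + rnorm(30, 0, 0.3)
  X <- cbind(x, x, rnorm(30), 5)
  y <- rep(c(0, 1), 15)
  w <- nca_weights(X, y, iters = 60)
  expect_lt(abs(w[1] - w[2]), 1e-6)
  expect_equal(w[4], 0)
  expect_error(nca_weights(X, rep(0, 30)), "single class")
  expect_error(nca_weights(X[0, , drop = FALSE], integer(0)), "degenerate")
})

test_that("cumulative-weight cut selects the smallest sufficient prefix", {
  s <- cumulative_select(c(0.5, 0.3, 0.15, 0.05), 0.9)
  expect_equal(s$nf, 3L)
  expect_equal(s$selected_indices, c(1L, 2L, 3L))
  expect_equal(cumulative_select(c(0.5, 0.3, 0.15, 0.05), 0.99)$nf, 4L)
  # equal weights: 3/4 < 0.99 <= 1 so all four are needed
  expect_equal(cumulative_select(rep(1, 4), 0.99)$nf, 4L)
  # ties sort by lower index first
  s <- cumulative_select(c(0.2, 0.5, 0.2, 0.1), 0.6)
  expect_equal(s$selected_indices[1:2], c(2L, 1L))
  # all-zero weights fall back to a single feature with a warning
  expect_warning(s0 <- cumulative_select(c(0, 0, 0), 0.99), "zero")
  expect_equal(s0$nf, 1L)
  expect_error(cumulative_select(c(-1, 2), 0.9), "nonnegative")
})

test_that("selection is monotone in threshold and invariant to weight scaling", {
  set.seed(61)
  for (i in 1:20) {
    w <- runif(sample(3:30, 1))
    ths <- sort(runif(3, 0.1, 1))
    nfs <- vapply(ths, function(t) cumulative_select(w, t)$nf, 0L)
    expect_true(all(diff(nfs) >= 0))
    s1 <- cumulative_select(w, 0.9)
    s2 <- cumulative_select(w * 7.3, 0.9)
    expect_identical(s1$selected_indices, s2$selected_indices)
  }
})

test_that("selected columns come out in descending-weight order", {
  X <- matrix(seq_len(60), 10, 6)
  sel <- structure(list(weights = c(1, 4, 2, 9, 0, 0), order = c(4L, 2L, 3L, 1L, 5L, 6L),
                        nf = 2L, selected_indices = c(4L, 1L), threshold = 0.5),
                   class = "selection_result")
  got <- apply_selection(X, sel)
  expect_identical(unname(got), unname(X[, c(4, 1)]))
  sel$selected_indices <- c(4L, 7L)
  expect_error(apply_selection(X, sel), "out of range")
})

test_that("signal-carrying features are recovered across seeded replicates", {
  hits <- 0L
  for (seed in 1:10) {
    set.seed(seed)
    n <- 40
    y <- rep(c(0, 1), n / 2)
    X <- cbind(y + rnorm(n, 0, 0.1), -y + rnorm(n, 0, 0.1),
               matrix(rnorm(n * 6), n))
    sel <- cwnca(X, y, threshold = 0.5)
    if (all(c(1L, 2L) %in% sel$selected_indices)) hits <- hits + 1L
  }
  expect_gte(hits, 9L)
})
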
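# Independent reference implementations used as oracles. Deliberately naive:
# explicit loops, no shared code with the package internals.

# Lowest-index argmax/argmin by linear scan with strict comparison.
ref_argmax <- function(v) {
  best <- 1L
  for (i in seq_along(v)) if (v[i] > v[best]) best <- i
  best
}
ref_argmin <- function(v) {
  best <- 1L
  for (i in seq_along(v)) if (v[i] < v[best]) best <- i
  best
}

# One-timepoint-at-a-time ChMinMaxPat: identities, tables, maps, bundle.
ref_chminmaxpat <- function(data, distance_mode = "absolute",
                            epsilon = 1e-10) {
  nc <- ncol(data); L <- nrow(data)
  pairs <- list(c(1, 2), c(1, 3), c(1, 4), c(2, 3), c(2, 4), c(3, 4))
  tt <- lapply(1:6, function(k) matrix(0L, nc, nc))
  maps <- lapply(1:6, function(k) integer(L))
  for (i in seq_len(L)) {
    vec <- data[i, ]
    d <- vec - sum(vec) / nc
    if (distance_mode == "absolute") d <- abs(d)
    id <- c(ref_argmax(vec), ref_argmin(vec), ref_argmax(d), ref_argmin(d))
    for (k in 1:6) {
      a <- id[pairs[[k]][1]]; b <- id[pairs[[k]][2]]
      tt[[k]][a, b] <- tt[[k]][a, b] + 1L
      maps[[k]][i] <- (a - 1L) * nc + (b - 1L)
    }
  }
  fv <- vector("list", 15)
  for (k in 1:6) {
    norm <- matrix(0, nc, nc)
    for (a in seq_len(nc)) {
      s <- 0
      for (b in seq_len(nc)) s <- s + tt[[k]][a, b]
      for (b in seq_len(nc)) norm[a, b] <- tt[[k]][a, b] / (s + epsilon)
    }
    v <- numeric(nc * nc)
    for (a in seq_len(nc)) for (b in seq_len(nc))
      v[(a - 1) * nc + b] <- norm[a, b]           # row-major
    fv[[k]] <- v
  }
  fv[[7]] <- c(fv[[1]], fv[[2]], fv[[3]], fv[[4]], fv[[5]], fv[[6]])
  for (k in 1:6) {
    h <- integer(nc * nc)
    for (i in seq_len(L)) {
      bin <- maps[[k]][i] + 1L
      h[bin] <- h[bin] + 1L
    }
    fv[[7 + k]] <- h
  }
  fv[[14]] <- c(fv[[8]], fv[[9]], fv[[10]], fv[[11]], fv[[12]], fv[[13]])
  fv[[15]] <- c(fv[[7]], fv[[14]])
  names(fv) <- paste0("fv", 1:15)
  list(tables = tt, maps = maps, fv = fv)
}

# Direct evaluation of the regularized expected-LOO-accuracy objective of
# diagonal-metric NCA, by explicit loops over sample pairs.
ref_nca_objective <- function(w, X, y, sigma = 1, lambda = 1 / nrow(X)) {
  n <- nrow(X); p <- ncol(X)
  total <- 0
  for (i in seq_len(n)) {
    kern <- numeric(n)
    for (j in seq_len(n)) {
      if (j == i) next
      d <- 0
      for (r in seq_len(p)) d <- d + w[r]^2 * abs(X[i, r] - X[j, r])
      kern[j] <- exp(-d / sigma)
    }
    denom <- sum(kern)
    if (denom > 0) {
      for (j in seq_len(n))
        if (j != i && y[j] == y[i]) total <- total + kern[j] / denom
    }
  }
  total - lambda * sum(w^2)
}

# Per-position majority vote with ties to the lower label.
ref_mode_vote <- function(mat) {
  apply(mat, 1, function(row) {
    tab <- table(row)
    winners <- names(tab)[tab == max(tab)]
    as.integer(min(as.integer(winners)))
  })
}

# Random manifest data frame (no files on disk).
random_manifest <- function(n_records = 6, max_segments = 4, seed = 1) {
  set.seed(seed)
  rows <- list()
  for (r in seq_len(n_records)) {
    lab <- if (r <= ceiling(n_records / 2)) 0L else 1L
    for (s in seq_len(sample(max_segments, 1))) {
      rows[[length(rows) + 1]] <- data.frame(
        segment_path = sprintf("r%02d_s%02d.csv", r, s),
        segment_id = sprintf("r%02d_s%02d", r, s),
        record_id = sprintf("r%02d", r),
        subject_id = sprintf("sub%02d", r),
        class_label = lab, stringsAsFactors = FALSE)
    }
  }
  do.call(rbind, rows)
}

# Small synthetic config for fast property tests.
small_synth_config <- function(seed = 1, dominance_scale = 1,
                               n_records_per_class = 6,
                               segments_per_record = 2) {
  synth_config(n_records_per_class = n_records_per_class,
               segments_per_record = segments_per_record,
               dominance_scale = dominance_scale, seed = seed)
}
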
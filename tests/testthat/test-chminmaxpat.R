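test_that("extreme-channel identities follow the stated tie and mode rules", {
  # absolute mode: dist = |vec - mean|, ties to the lowest channel
  expect_equal(unname(extract_identities(c(5, 1, 2, 4), "absolute")),
               c(1L, 2L, 1L, 3L))
  # signed mode collapses id3/id4 onto id1/id2
  expect_equal(unname(extract_identities(c(5, 1, 2, 4), "signed")),
               c(1L, 2L, 1L, 2L))
  # all-tie input
  expect_equal(unname(extract_identities(c(3, 3, 3), "absolute")),
               c(1L, 1L, 1L, 1L))
  expect_error(extract_identities(5), "at least 2")
  expect_error(extract_identities(c(1, NA)), "non-finite")
})

test_that("identities are invariant to a constant shift across channels", {
  set.seed(11)
  for (i in 1:50) {
    vec <- rnorm(14)
    shift <- runif(1, -100, 100)
    for (mode in c("absolute", "signed"))
      expect_identical(extract_identities(vec, mode),
                       extract_identities(vec + shift, mode))
  }
})

test_that("accumulation books one transition and one map value per pair per timepoint", {
  # one timepoint, identities (1,2,1,2) under signed mode
  acc <- accumulate(matrix(c(5, 1, 2, 4), 1, 4), "signed")
  expect_equal(acc$tables[[1]][1, 2], 1)  # (id1,id2)
  expect_equal(acc$tables[[2]][1, 1], 1)  # (id1,id3)
  expect_equal(acc$tables[[3]][1, 2], 1)  # (id1,id4)
  expect_equal(acc$tables[[4]][2, 1], 1)  # (id2,id3)
  expect_equal(acc$tables[[5]][2, 2], 1)  # (id2,id4)
  expect_equal(acc$tables[[6]][1, 2], 1)  # (id3,id4)
  expect_true(all(vapply(acc$tables, sum, 0) == 1))
  expect_equal(acc$maps[[1]], 1L)         # (1-1)*4 + (2-1)

  # map encoding at the corners of a 14-channel montage
  expect_equal(accumulate(matrix(14:1, 1, 14), "signed")$maps[[1]], 13L)
  expect_equal(accumulate(matrix(1:14, 1, 14), "signed")$maps[[1]], 182L)
})

test_that("row normalization divides by row sums and keeps zero rows zero", {
  tt <- matrix(0, 4, 4); tt[1, ] <- c(2, 0, 0, 2)
  norm <- normalize_tables(list(tt))[[1]]
  expect_equal(norm[1, ], c(0.5, 0, 0, 0.5), tolerance = 1e-9)
  expect_true(all(norm[2:4, ] == 0))
  # every row sum in {0} u [1 - 1e-6, 1]
  acc <- accumulate(matrix(rnorm(200), 50, 4))
  rs <- unlist(lapply(normalize_tables(acc)$tables, rowSums))
  expect_true(all(rs == 0 | (rs >= 1 - 1e-6 & rs <= 1)))
})

test_that("bundles have the documented lengths, concatenations and count sums", {
  seg <- matrix(rnorm(1920 * 14), 1920, 14)
  b <- chminmaxpat(seg)
  expect_length(b, 15)
  expect_true(all(lengths(b[c(1:6, 8:13)]) == 196))
  expect_true(all(lengths(b[c(7, 14)]) == 1176))
  expect_length(b$fv15, 2352)
  expect_identical(b$fv7, c(b$fv1, b$fv2, b$fv3, b$fv4, b$fv5, b$fv6))
  expect_identical(b$fv14, c(b$fv8, b$fv9, b$fv10, b$fv11, b$fv12, b$fv13))
  expect_identical(b$fv15, c(b$fv7, b$fv14))
  # histograms conserve timepoint counts and are nonnegative
  b100 <- chminmaxpat(matrix(rnorm(100 * 5), 100, 5))
  expect_true(all(vapply(b100[8:13], sum, 0) == 100))
  expect_true(all(unlist(b100[8:13]) >= 0))
  # pre-normalization tables conserve counts too
  acc <- accumulate(matrix(rnorm(100 * 5), 100, 5))
  expect_true(all(vapply(acc$tables, sum, 0) == 100))
})

test_that("vectorized extractor matches the naive per-timepoint reference exactly", {
  set.seed(23)
  for (mode in c("absolute", "signed")) {
    data <- matrix(rnorm(50 * 5), 50, 5)
    ref <- ref_chminmaxpat(data, mode)
    acc <- accumulate(data, mode)
    for (k in 1:6) {
      expect_identical(unname(acc$tables[[k]]), ref$tables[[k]])
      expect_identical(as.integer(acc$maps[[k]]), as.integer(ref$maps[[k]]))
    }
    got <- chminmaxpat(data, mode)
    for (h in 1:15) expect_identical(unname(got[[h]]), unname(ref$fv[[h]]))
  }
})

test_that("signed mode degenerates: fv1 = fv3 = fv6 and fv5 is diagonal-only", {
  set.seed(31)
  for (i in 1:5) {
    nc <- sample(3:14, 1)
    b <- chminmaxpat(matrix(rnorm(200 * nc), 200, nc), "signed")
    expect_identical(b$fv1, b$fv3)
    expect_identical(b$fv1, b$fv6)
    m5 <- matrix(b$fv5, nc, nc, byrow = TRUE)
    expect_true(all(m5[row(m5) != col(m5)] == 0))
  }
})

test_that("feature matrices stack in manifest order, deterministically", {
  cfg <- small_synth_config(seed = 4, n_records_per_class = 2,
                            segments_per_record = 2)
  segs <- simulate_segments(cfg)
  fs <- extract_features(segs)
  expect_equal(dim(fs$fv15), c(8L, 2352L))
  expect_equal(dim(fs$fv1), c(8L, 196L))
  expect_identical(rownames(fs$fv1), vapply(segs, `[[`, "", "segment_id"))
  # permuting segments permutes rows identically
  perm <- c(3, 1, 4, 2, 8, 5, 6, 7)
  fs_p <- extract_features(segs[perm])
  expect_identical(unname(fs_p$fv15), unname(fs$fv15[perm, ]))
  # duplicate segment content gives identical feature rows
  fs_d <- extract_features(list(segs[[1]], segs[[1]]))
  expect_identical(fs_d$fv15[1, ], fs_d$fv15[2, ])
})
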
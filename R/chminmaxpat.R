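#' Per-timepoint extreme-channel identities
#'
#' At one timepoint the ChMinMaxPat extractor records four channel
#' identities: `id1` = argmax of the channel vector, `id2` = argmin, and
#' `id3`/`id4` = argmax/argmin of the vector's deviation from its own mean.
#' In `"absolute"` mode the deviation is `|vec - mean(vec)|`; in `"signed"`
#' mode it is `vec - mean(vec)`, in which case `id3 = id1` and `id4 = id2`
#' identically (argmax/argmin are invariant to subtracting a constant) — the
#' signed variant is retained as a flag but collapses two of the transition
#' tables onto the others. All argmax/argmin ties resolve to the lowest
#' channel index.
#'
#' @param vec Numeric vector of channel values at one timepoint (length >= 2).
#' @param distance_mode `"absolute"` (default) or `"signed"`.
#' @return Named integer vector `c(id1, id2, id3, id4)`, values in `1..nc`.
#' @export
extract_identities <- function(vec, distance_mode = c("absolute", "signed")) {
  distance_mode <- match.arg(distance_mode)
  if (length(vec) < 2L) stop("need at least 2 channels")
  if (any(!is.finite(vec))) stop("non-finite channel value")
  d <- vec - mean(vec)
  if (distance_mode == "absolute") d <- abs(d)
  c(id1 = which.max(vec), id2 = which.min(vec),
    id3 = which.max(d), id4 = which.min(d))
}

# L x 4 identity matrix for a whole segment, vectorized over timepoints.
# max.col(ties.method = "first") matches the lowest-index tie rule.
identity_matrix <- function(data, distance_mode = "absolute") {
  if (ncol(data) < 2L) stop("need at least 2 channels")
  if (any(!is.finite(data))) {
    bad <- which(rowSums(!is.finite(data)) > 0L)[1L]
    stop("non-finite channel value at timepoint ", bad)
  }
  d <- data - rowMeans(data)
  if (distance_mode == "absolute") d <- abs(d)
  cbind(id1 = max.col(data, ties.method = "first"),
        id2 = max.col(-data, ties.method = "first"),
        id3 = max.col(d, ties.method = "first"),
        id4 = max.col(-d, ties.method = "first"))
}

# The six ordered identity pairs feeding the six transition tables / maps.
identity_pairs <- cbind(first  = c(1L, 1L, 1L, 2L, 2L, 3L),
                        second = c(2L, 3L, 4L, 3L, 4L, 4L))

#' Accumulate transition tables and map signals over a segment
#'
#' For each timepoint the six ordered identity pairs
#' (id1,id2), (id1,id3), (id1,id4), (id2,id3), (id2,id4), (id3,id4)
#' increment one cell of the corresponding nc x nc transition table
#' (`tt[first, second]`) and append one value to the corresponding map
#' signal, encoded `(first - 1) * nc + (second - 1)` in `0..nc^2 - 1`.
#'
#' @param segment An [eeg_segment()] or a bare numeric matrix
#'   (samples x channels).
#' @param distance_mode `"absolute"` (default) or `"signed"`.
#' @return List with `tables` (six nc x nc count matrices), `maps` (six
#'   integer vectors of length L), `nc` and `L`.
#' @export
accumulate <- function(segment, distance_mode = c("absolute", "signed")) {
  distance_mode <- match.arg(distance_mode)
  data <- if (inherits(segment, "eeg_segment")) segment$data else segment
  if (!is.matrix(data)) stop("segment data must be a matrix")
  nc <- ncol(data)
  ids <- identity_matrix(data, distance_mode)
  tables <- vector("list", 6L)
  maps <- vector("list", 6L)
  for (k in 1:6) {
    f <- unname(ids[, identity_pairs[k, "first"]])
    s <- unname(ids[, identity_pairs[k, "second"]])
    # cell [f, s] in column-major storage is (s - 1) * nc + f
    tables[[k]] <- matrix(tabulate((s - 1L) * nc + f, nbins = nc * nc),
                          nrow = nc, ncol = nc)
    maps[[k]] <- (f - 1L) * nc + (s - 1L)
  }
  list(tables = tables, maps = maps, nc = nc, L = nrow(data))
}

#' Row-normalize transition tables
#'
#' Each row is divided by its sum plus a small epsilon, so populated rows sum
#' to (essentially) one and all-zero rows stay all-zero.
#'
#' @param acc Result of [accumulate()], or a list of matrices.
#' @param epsilon Zero-row guard added to each row sum (default 1e-10).
#' @return The input with `tables` replaced by their row-normalized versions.
#' @export
normalize_tables <- function(acc, epsilon = 1e-10) {
  tables <- if (is.list(acc) && !is.null(acc$tables)) acc$tables else acc
  norm <- lapply(tables, function(tt) tt / (rowSums(tt) + epsilon))
  if (is.list(acc) && !is.null(acc$tables)) {
    acc$tables <- norm
    acc$epsilon <- epsilon
    acc
  } else norm
}

#' Build the 15 ChMinMaxPat feature vectors for one segment
#'
#' `fv1..fv6` are the row-major flattenings of the six row-normalized
#' transition tables (length nc^2 each); `fv7` is their concatenation
#' (6 nc^2); `fv8..fv13` are the raw-count histograms of the six map signals
#' over bins `0..nc^2 - 1` (length nc^2, each summing to L); `fv14`
#' concatenates the histograms (6 nc^2); `fv15 = c(fv7, fv14)` (12 nc^2).
#' Row-major flattening makes position `g` of a table-derived vector encode
#' the channel pair `first = floor((g - 1) / nc) + 1`,
#' `second = (g - 1) %% nc + 1` — the same encoding as the map bins, which is
#' what the DLob decoder inverts.
#'
#' @param acc Result of [accumulate()].
#' @param epsilon Row-normalization guard (see [normalize_tables()]).
#' @return A named list `fv1..fv15` of class `feature_bundle`, with
#'   attributes `nc` and `L`.
#' @export
build_bundle <- function(acc, epsilon = 1e-10) {
  norm <- normalize_tables(acc, epsilon)
  nc <- acc$nc
  fv <- vector("list", 15L)
  for (k in 1:6) fv[[k]] <- as.vector(t(norm$tables[[k]]))  # row-major
  fv[[7L]] <- unlist(fv[1:6], use.names = FALSE)
  for (k in 1:6) {
    mp <- acc$maps[[k]]
    if (any(mp < 0L | mp >= nc * nc)) stop("map value out of range 0..nc^2-1")
    fv[[7L + k]] <- tabulate(mp + 1L, nbins = nc * nc)
  }
  fv[[14L]] <- unlist(fv[8:13], use.names = FALSE)
  fv[[15L]] <- c(fv[[7L]], fv[[14L]])
  names(fv) <- paste0("fv", 1:15)
  structure(fv, class = "feature_bundle", nc = nc, L = acc$L)
}

#' Extract ChMinMaxPat features for one segment
#'
#' Convenience wrapper: [accumulate()] then [build_bundle()].
#'
#' @inheritParams accumulate
#' @inheritParams build_bundle
#' @return A `feature_bundle` (see [build_bundle()]).
#' @export
chminmaxpat <- function(segment, distance_mode = c("absolute", "signed"),
                        epsilon = 1e-10) {
  distance_mode <- match.arg(distance_mode)
  build_bundle(accumulate(segment, distance_mode), epsilon)
}

#' Extract features for every segment of a dataset
#'
#' Runs the extractor on each segment in manifest order and stacks the
#' results into 15 feature matrices (rows = segments).
#'
#' @param manifest A validated manifest, or a list of [eeg_segment()]s.
#' @param distance_mode `"absolute"` (default) or `"signed"`.
#' @param epsilon Row-normalization guard.
#' @param fs Sampling rate recorded on loaded segments (manifest input only).
#' @return A `feature_set`: list of 15 numeric matrices named `fv1..fv15`
#'   with `segment_id` rownames, plus attributes `nc`, `distance_mode`,
#'   `epsilon`, `segment_ids`, `labels` (integer class labels in row order)
#'   and `record_ids`.
#' @export
extract_features <- function(manifest, distance_mode = c("absolute", "signed"),
                             epsilon = 1e-10, fs = 128) {
  distance_mode <- match.arg(distance_mode)
  segs <- if (is.data.frame(manifest)) load_segments(manifest, fs = fs)
          else manifest
  bundles <- lapply(segs, function(s) {
    tryCatch(chminmaxpat(s, distance_mode, epsilon),
             error = function(e) stop("segment '", s$segment_id, "': ",
                                      conditionMessage(e), call. = FALSE))
  })
  ids <- vapply(segs, function(s) s$segment_id, "")
  labels <- vapply(segs, function(s) s$class_label, 0L)
  recs <- vapply(segs, function(s) s$record_id, "")
  fs_list <- lapply(1:15, function(h) {
    m <- do.call(rbind, lapply(bundles, `[[`, h))
    rownames(m) <- ids
    m
  })
  names(fs_list) <- paste0("fv", 1:15)
  structure(fs_list, class = "feature_set",
            nc = attr(bundles[[1L]], "nc"), distance_mode = distance_mode,
            epsilon = epsilon, segment_ids = ids, labels = labels,
            record_ids = recs)
}

#' Write a feature set to CSV files
#'
#' One file per feature vector (`fv01.csv .. fv15.csv`, segment_id first
#' column) plus a JSON sidecar recording nc, distance_mode and epsilon.
#'
#' @param features A `feature_set` from [extract_features()].
#' @param out_dir Output directory.
#' @return `out_dir`, invisibly.
#' @export
write_features <- function(features, out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  for (h in 1:15) {
    df <- data.frame(segment_id = attr(features, "segment_ids"),
                     features[[h]], check.names = FALSE)
    data.table::fwrite(df, file.path(out_dir, sprintf("fv%02d.csv", h)))
  }
  jsonlite::write_json(
    list(nc = attr(features, "nc"),
         distance_mode = attr(features, "distance_mode"),
         epsilon = attr(features, "epsilon")),
    file.path(out_dir, "features.json"), auto_unbox = TRUE)
  invisible(out_dir)
}
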
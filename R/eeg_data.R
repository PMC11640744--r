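#' Construct an EEG segment
#'
#' An `eeg_segment` is the unit of feature extraction: one fixed-length
#' multichannel window (rows = samples, columns = channels) together with the
#' metadata needed for grouped cross-validation (record and subject identity)
#' and supervision (class label).
#'
#' @param data Numeric matrix, L samples x nc channels. No missing values.
#' @param segment_id,record_id,subject_id Character scalars identifying the
#'   segment, the continuous recording it was cut from, and the subject.
#' @param class_label Integer class label (two classes per dataset; any two
#'   distinct integer codes such as 0/1 or 1/2).
#' @param fs Sampling rate in Hz.
#' @param channel_names Character vector of channel names, one per column of
#'   `data`, in montage order (the order the lobe look-up table refers to).
#'   Defaults to the column names of `data`, or `ch1..chnc`.
#' @return An object of class `eeg_segment`.
#' @export
eeg_segment <- function(data, segment_id, record_id, subject_id, class_label,
                        fs, channel_names = NULL) {
  if (!is.matrix(data) || !is.numeric(data))
    stop("`data` must be a numeric matrix (samples x channels)")
  if (nrow(data) < 1L || ncol(data) < 1L)
    stop("`data` must have at least one row and one column")
  if (anyNA(data) || any(!is.finite(data)))
    stop("`data` contains missing or non-finite values")
  if (is.null(channel_names)) {
    channel_names <- colnames(data)
    if (is.null(channel_names)) channel_names <- paste0("ch", seq_len(ncol(data)))
  }
  if (length(channel_names) != ncol(data))
    stop("`channel_names` length (", length(channel_names),
         ") does not match channel count (", ncol(data), ")")
  structure(
    list(segment_id = as.character(segment_id),
         record_id = as.character(record_id),
         subject_id = as.character(subject_id),
         class_label = as.integer(class_label),
         data = data, fs = fs,
         channel_names = as.character(channel_names)),
    class = "eeg_segment")
}

#' @export
print.eeg_segment <- function(x, ...) {
  cat(sprintf("<eeg_segment %s> record=%s subject=%s class=%d  %d samples x %d channels @ %g Hz\n",
              x$segment_id, x$record_id, x$subject_id, x$class_label,
              nrow(x$data), ncol(x$data), x$fs))
  invisible(x)
}

manifest_columns <- c("segment_path", "segment_id", "record_id",
                      "subject_id", "class_label")

#' Read and validate a dataset manifest
#'
#' The manifest is a CSV with one row per segment and columns
#' `segment_path,segment_id,record_id,subject_id,class_label`. Segment paths
#' are resolved relative to the manifest's directory. A valid manifest has
#' exactly two class labels and every record belongs to exactly one class and
#' one subject.
#'
#' @param path Path to the manifest CSV.
#' @return A `data.frame` with the five manifest columns (character except
#'   `class_label`, integer), rows in file order, plus attributes `dir` (the
#'   manifest directory) and `class_labels` (the two labels, sorted).
#' @export
read_manifest <- function(path) {
  if (!file.exists(path)) stop("manifest file not found: ", path)
  df <- utils::read.csv(path, stringsAsFactors = FALSE, colClasses = "character")
  validate_manifest(df, dir = dirname(normalizePath(path)))
}

#' Validate a manifest data frame
#'
#' @param df Data frame with the manifest columns.
#' @param dir Directory against which relative `segment_path`s resolve.
#' @return The validated manifest (see [read_manifest()]).
#' @export
validate_manifest <- function(df, dir = ".") {
  missing_cols <- setdiff(manifest_columns, names(df))
  if (length(missing_cols))
    stop("manifest is missing column(s): ", paste(missing_cols, collapse = ", "))
  if (nrow(df) == 0L) stop("manifest contains no segments")
  df <- df[manifest_columns]
  for (col in setdiff(manifest_columns, "class_label"))
    df[[col]] <- as.character(df[[col]])
  lab <- suppressWarnings(as.integer(df$class_label))
  if (anyNA(lab))
    stop("non-integer class_label in manifest row ",
         which(is.na(lab))[1L])
  df$class_label <- lab
  labels <- sort(unique(lab))
  if (length(labels) != 2L)
    stop("manifest must contain exactly two class labels, found: ",
         paste(labels, collapse = ", "))
  if (anyDuplicated(df$segment_id))
    stop("duplicate segment_id in manifest: ",
         df$segment_id[anyDuplicated(df$segment_id)])
  # each record maps to one class and one subject
  for (field in c("class_label", "subject_id")) {
    tab <- unique(df[c("record_id", field)])
    dup <- tab$record_id[duplicated(tab$record_id)]
    if (length(dup))
      stop("record '", dup[1L], "' maps to more than one ", field,
           " (first offending manifest row ",
           which(df$record_id == dup[1L])[1L], ")")
  }
  attr(df, "dir") <- dir
  attr(df, "class_labels") <- labels
  df
}

#' Load one EEG segment from a CSV file
#'
#' Segment files are numeric CSV, rows = samples, columns = channels, with a
#' header row of channel names.
#'
#' @param path Path to the segment CSV (resolved against `dir` if relative).
#' @param manifest_row One-row slice of a manifest supplying metadata, or
#'   `NULL` for anonymous loading.
#' @param nc Expected channel count, or `NULL` to infer from the file.
#' @param fs Sampling rate in Hz recorded on the segment.
#' @param dir Base directory for relative paths.
#' @return An [eeg_segment()].
#' @export
load_segment <- function(path, manifest_row = NULL, nc = NULL, fs = 128,
                         dir = ".") {
  full <- if (file.exists(path)) path else file.path(dir, path)
  if (!file.exists(full)) stop("segment file not found: ", path)
  dt <- data.table::fread(full, header = TRUE, sep = ",", data.table = FALSE)
  bad <- which(!vapply(dt, is.numeric, logical(1L)))
  if (length(bad)) {
    col <- bad[1L]
    row <- which(is.na(suppressWarnings(as.numeric(dt[[col]]))))[1L]
    stop("non-numeric value in segment '", path, "' at row ",
         if (is.na(row)) "?" else row, ", column ", names(dt)[col])
  }
  m <- as.matrix(dt)
  if (anyNA(m)) {
    idx <- which(is.na(m), arr.ind = TRUE)[1L, ]
    stop("missing value in segment '", path, "' at row ", idx[1L],
         ", column ", colnames(m)[idx[2L]])
  }
  if (!is.null(nc) && ncol(m) != nc)
    stop("segment '", path, "' has ", ncol(m),
         " channels, expected ", nc)
  if (is.null(manifest_row)) {
    id <- sub("\\.[^.]*$", "", basename(full))
    eeg_segment(m, id, id, id, 0L, fs)
  } else {
    eeg_segment(m, manifest_row$segment_id, manifest_row$record_id,
                manifest_row$subject_id, manifest_row$class_label, fs)
  }
}

#' Write one EEG segment to CSV
#'
#' Full-precision output: [load_segment()] on the written file reproduces the
#' matrix bit-exactly.
#'
#' @param segment An [eeg_segment()] or a bare numeric matrix.
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_segment <- function(segment, path) {
  m <- if (inherits(segment, "eeg_segment")) segment$data else segment
  cn <- if (inherits(segment, "eeg_segment")) segment$channel_names
        else colnames(m)
  if (is.null(cn)) cn <- paste0("ch", seq_len(ncol(m)))
  # 17 significant digits: the written text round-trips doubles bit-exactly
  df <- as.data.frame(apply(m, 2L, function(x) sprintf("%.17g", x)))
  names(df) <- cn
  data.table::fwrite(df, path, quote = FALSE)
  invisible(path)
}

#' Load all segments listed in a manifest
#'
#' @param manifest A validated manifest (see [read_manifest()]).
#' @param fs Sampling rate to record on each segment.
#' @param nc Expected channel count, or `NULL`.
#' @return List of [eeg_segment()]s, in manifest row order.
#' @export
load_segments <- function(manifest, fs = 128, nc = NULL) {
  dir <- attr(manifest, "dir") %||% "."
  lapply(seq_len(nrow(manifest)), function(i) {
    row <- manifest[i, , drop = FALSE]
    tryCatch(load_segment(row$segment_path, row, nc = nc, fs = fs, dir = dir),
             error = function(e) stop("segment '", row$segment_id, "': ",
                                      conditionMessage(e), call. = FALSE))
  })
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Assign segments to cross-validation folds
#'
#' Two schemes: `kfold` shuffles segments with `seed` and splits into
#' `n_folds` near-equal parts (no stratification); `loro`
#' (leave-one-record-out) gives every record its own fold, so all segments of
#' a record are held out together. When each record belongs to a distinct
#' subject, `loro` coincides with leave-one-subject-out.
#'
#' @param manifest A validated manifest.
#' @param scheme `"kfold"` or `"loro"`.
#' @param n_folds Number of folds (k-fold only; ignored for loro).
#' @param seed Integer seed controlling the k-fold shuffle.
#' @return A `fold_plan`: list with `scheme`, `assignments` (integer fold
#'   index named by segment_id, in manifest order) and `n_folds`.
#' @export
make_folds <- function(manifest, scheme = c("kfold", "loro"), n_folds = 10L,
                       seed = 1L) {
  scheme <- match.arg(scheme)
  n <- nrow(manifest)
  ids <- manifest$segment_id
  if (scheme == "kfold") {
    if (n_folds > n) stop("n_folds (", n_folds, ") exceeds segment count (", n, ")")
    if (n_folds < 2L) stop("n_folds must be at least 2")
    perm <- with_seed(seed, sample.int(n))
    assign_idx <- integer(n)
    # near-equal parts: fold sizes differ by at most one
    sizes <- rep(n %/% n_folds, n_folds) + (seq_len(n_folds) <= n %% n_folds)
    assign_idx[perm] <- rep(seq_len(n_folds), times = sizes)
    assignments <- stats::setNames(assign_idx, ids)
  } else {
    recs <- unique(manifest$record_id)
    if (length(recs) < 2L) stop("loro requires at least two records")
    n_folds <- length(recs)
    assignments <- stats::setNames(match(manifest$record_id, recs), ids)
  }
  structure(list(scheme = scheme, assignments = assignments,
                 n_folds = as.integer(n_folds)),
            class = "fold_plan")
}

#' @export
print.fold_plan <- function(x, ...) {
  cat(sprintf("<fold_plan> scheme=%s, %d folds, %d segments\n",
              x$scheme, x$n_folds, length(x$assignments)))
  invisible(x)
}

#' Write a manifest to CSV
#'
#' @param manifest Manifest data frame.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_manifest <- function(manifest, path) {
  utils::write.csv(as.data.frame(manifest)[manifest_columns], path,
                   row.names = FALSE, quote = FALSE)
  invisible(path)
}
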
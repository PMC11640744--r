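#' Configuration for the synthetic EEG generator
#'
#' The generator produces class-structured multichannel EEG-like data whose
#' learnable signal lives exactly where the ChMinMaxPat extractor looks: in
#' the identity of the channel that is extreme at each timepoint. Each sample
#' is i.i.d. Gaussian baseline noise plus a class-dependent per-channel
#' amplitude boost (drawn once per segment, per channel, around the class's
#' dominance weight), plus a per-record scalar offset applied to every
#' channel. The scalar record offset induces record-level amplitude
#' correlation in the raw signal while leaving extreme-channel identities
#' untouched (they are invariant to a constant shift across channels).
#'
#' Default dominance: one class boosts the first half of the montage
#' (frontal-leaning channels), the other the second half (posterior-leaning),
#' by `dominance_scale` microvolt-scale units.
#'
#' @param nc Number of channels (default 14, a standard consumer montage).
#' @param fs Sampling rate in Hz (default 128).
#' @param segment_seconds Window length in seconds (default 15); `fs *
#'   segment_seconds` must be an integer.
#' @param n_records_per_class Records per class (default 20).
#' @param segments_per_record Segments per record (default 4).
#' @param dominance_map Named list mapping each class label (as character) to
#'   a length-`nc` numeric vector of per-channel boost means.
#' @param dominance_scale Multiplier applied to the default dominance
#'   profiles (ignored when `dominance_map` is supplied); 0 removes the class
#'   signal entirely.
#' @param noise_sd Baseline noise standard deviation (default 10).
#' @param boost_sd Standard deviation of the per-segment channel boosts
#'   around their dominance means (default 1).
#' @param record_offset_sd Standard deviation of the per-record scalar
#'   offset (default 5).
#' @param class_labels Integer pair of class labels (default `c(0L, 1L)`).
#' @param seed Integer seed; the output tree is fully determined by it.
#' @return A list of class `synth_config`.
#' @export
synth_config <- function(nc = 14L, fs = 128, segment_seconds = 15,
                         n_records_per_class = 20L, segments_per_record = 4L,
                         dominance_map = NULL, dominance_scale = 1,
                         noise_sd = 10, boost_sd = 1, record_offset_sd = 5,
                         class_labels = c(0L, 1L), seed = 1L) {
  nc <- as.integer(nc)
  if (nc < 2L) stop("nc must be at least 2")
  if (n_records_per_class < 1L || segments_per_record < 1L)
    stop("need at least one record per class and one segment per record")
  L <- fs * segment_seconds
  if (abs(L - round(L)) > 1e-9)
    stop("fs * segment_seconds must be an integer number of samples")
  if (noise_sd <= 0 || boost_sd <= 0) stop("noise_sd and boost_sd must be positive")
  class_labels <- sort(as.integer(class_labels))
  if (length(class_labels) != 2L || anyDuplicated(class_labels))
    stop("class_labels must be two distinct integers")
  if (is.null(dominance_map)) {
    half <- nc %/% 2L
    a <- c(rep(3, half), rep(0, nc - half)) * dominance_scale
    b <- c(rep(0, nc - half), rep(3, half)) * dominance_scale
    dominance_map <- stats::setNames(list(a, b), as.character(class_labels))
  }
  if (!all(as.character(class_labels) %in% names(dominance_map)))
    stop("dominance_map must have an entry for both class labels")
  if (!all(vapply(dominance_map, length, 0L) == nc))
    stop("each dominance_map entry must have length nc = ", nc)
  structure(list(nc = nc, fs = fs, segment_seconds = segment_seconds,
                 L = as.integer(round(L)),
                 n_records_per_class = as.integer(n_records_per_class),
                 segments_per_record = as.integer(segments_per_record),
                 dominance_map = dominance_map, noise_sd = noise_sd,
                 boost_sd = boost_sd, record_offset_sd = record_offset_sd,
                 class_labels = class_labels, seed = as.integer(seed)),
            class = "synth_config")
}

#' Generate a synthetic EEG dataset on disk
#'
#' Writes one CSV per segment plus `manifest.csv` into `out_dir` and returns
#' the validated manifest. Byte-identical for identical configs (including
#' seed).
#'
#' @param cfg A [synth_config()].
#' @param out_dir Output directory (created if needed).
#' @return The validated manifest, as from [read_manifest()].
#' @export
generate_dataset <- function(cfg, out_dir) {
  stopifnot(inherits(cfg, "synth_config"))
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  segs <- simulate_segments(cfg)
  rows <- lapply(segs, function(s) {
    fn <- paste0(s$segment_id, ".csv")
    write_segment(s, file.path(out_dir, fn))
    data.frame(segment_path = fn, segment_id = s$segment_id,
               record_id = s$record_id, subject_id = s$subject_id,
               class_label = s$class_label, stringsAsFactors = FALSE)
  })
  manifest <- do.call(rbind, rows)
  write_manifest(manifest, file.path(out_dir, "manifest.csv"))
  read_manifest(file.path(out_dir, "manifest.csv"))
}

#' Simulate synthetic EEG segments in memory
#'
#' Same generative model as [generate_dataset()] without touching disk.
#' One subject per record (so leave-one-record-out is also
#' leave-one-subject-out on this fixture).
#'
#' @param cfg A [synth_config()].
#' @return List of [eeg_segment()]s.
#' @export
simulate_segments <- function(cfg) {
  stopifnot(inherits(cfg, "synth_config"))
  with_seed(cfg$seed, {
    segs <- list()
    rec_no <- 0L
    for (cls in cfg$class_labels) {
      dom <- cfg$dominance_map[[as.character(cls)]]
      for (r in seq_len(cfg$n_records_per_class)) {
        rec_no <- rec_no + 1L
        rec_id <- sprintf("rec%03d", rec_no)
        offset <- stats::rnorm(1L, 0, cfg$record_offset_sd)  # scalar, all channels
        for (s in seq_len(cfg$segments_per_record)) {
          boost <- stats::rnorm(cfg$nc, mean = dom, sd = cfg$boost_sd)
          noise <- matrix(stats::rnorm(cfg$L * cfg$nc, 0, cfg$noise_sd),
                          nrow = cfg$L, ncol = cfg$nc)
          m <- sweep(noise, 2L, boost, `+`) + offset
          colnames(m) <- paste0("ch", seq_len(cfg$nc))
          seg_id <- sprintf("%s_s%02d", rec_id, s)
          segs[[seg_id]] <- eeg_segment(m, seg_id, rec_id,
                                        subject_id = sprintf("sub%03d", rec_no),
                                        class_label = cls, fs = cfg$fs)
        }
      }
    }
    segs
  })
}

#' Permute class labels at the record level
#'
#' Negative-control fixture: reassigns class labels among records with a
#' seeded permutation, preserving per-class record counts and keeping every
#' record single-class.
#'
#' @param manifest A validated manifest.
#' @param seed Integer seed.
#' @return A manifest with permuted labels (same attributes).
#' @export
shuffle_labels <- function(manifest, seed = 1L) {
  recs <- unique(manifest[c("record_id", "class_label")])
  if (length(unique(recs$class_label)) < 2L)
    stop("cannot shuffle labels of a single-class manifest")
  perm <- with_seed(seed, sample.int(nrow(recs)))
  new_lab <- stats::setNames(recs$class_label[perm], recs$record_id)
  out <- manifest
  out$class_label <- as.integer(new_lab[manifest$record_id])
  attr(out, "dir") <- attr(manifest, "dir")
  attr(out, "class_labels") <- attr(manifest, "class_labels")
  out
}
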
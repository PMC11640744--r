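#' Binary classification performance metrics
#'
#' Accuracy, sensitivity, specificity and their geometric mean from the
#' confusion matrix of a two-class prediction. A degenerate denominator (no
#' positive or no negative ground-truth samples) yields `NA` for the
#' affected metric, flagged in `undefined`, never silently 0.
#'
#' @param true_labels,predicted_labels Equal-length label vectors over the
#'   same two classes.
#' @param positive_class The label counted as positive (condition) class.
#' @return A `metrics_report`: list with `tp`, `fn`, `tn`, `fp`, `acc`,
#'   `sen`, `spe`, `gm`, `confusion` (2 x 2, rows = truth), `positive_class`
#'   and `undefined` (character vector of metrics with degenerate
#'   denominators).
#' @export
compute_metrics <- function(true_labels, predicted_labels, positive_class) {
  if (length(true_labels) != length(predicted_labels))
    stop("label vectors differ in length")
  classes <- sort(unique(c(true_labels, predicted_labels)))
  if (length(classes) > 2L)
    stop("more than two classes present: ", paste(classes, collapse = ", "))
  if (!positive_class %in% classes && length(classes) == 2L)
    stop("positive_class ", positive_class, " not among labels")
  pos <- true_labels == positive_class
  ppos <- predicted_labels == positive_class
  tp <- sum(pos & ppos); fn <- sum(pos & !ppos)
  tn <- sum(!pos & !ppos); fp <- sum(!pos & ppos)
  undefined <- character()
  acc <- (tp + tn) / (tp + fn + tn + fp)
  sen <- if (tp + fn > 0) tp / (tp + fn) else { undefined <- c(undefined, "sen"); NA_real_ }
  spe <- if (fp + tn > 0) tn / (fp + tn) else { undefined <- c(undefined, "spe"); NA_real_ }
  gm <- if (is.na(sen) || is.na(spe)) { undefined <- unique(c(undefined, "gm")); NA_real_ }
        else sqrt(sen * spe)
  confusion <- matrix(c(tp, fn, fp, tn), 2L, 2L, byrow = TRUE,
                      dimnames = list(truth = c("positive", "negative"),
                                      predicted = c("positive", "negative")))
  structure(list(tp = tp, fn = fn, tn = tn, fp = fp, acc = acc, sen = sen,
                 spe = spe, gm = gm, confusion = confusion,
                 positive_class = positive_class, undefined = undefined),
            class = "metrics_report")
}

#' @export
print.metrics_report <- function(x, ...) {
  cat(sprintf("<metrics_report> acc %.4f  sen %.4f  spe %.4f  gm %.4f (positive class %s)\n",
              x$acc, x$sen, x$spe, x$gm, x$positive_class))
  invisible(x)
}

#' Pipeline run configuration
#'
#' Bundles every tunable of the pipeline. The defaults reproduce the
#' method's reference settings: absolute distance mode, epsilon 1e-10,
#' cumulative-weight threshold 0.99, the 60-configuration kNN grid, 10-fold
#' CV, and the standard 14-channel lobe table.
#'
#' @param distance_mode `"absolute"` or `"signed"`.
#' @param epsilon Transition-table row-normalization guard.
#' @param threshold Cumulative-weight selection threshold.
#' @param cv `"kfold"` or `"loro"`.
#' @param n_folds Folds for k-fold CV.
#' @param seed Integer seed (fold shuffling).
#' @param lut Channel-to-lobe table, or `NULL` for the 14-channel default.
#' @param positive_class Positive label for metrics, or `NULL` to default to
#'   the higher of the two labels (the condition class in the usual
#'   control-first coding).
#' @param fs Sampling rate recorded on loaded segments.
#' @param nca Named list of NCA hyperparameters passed to [nca_weights()]
#'   (`sigma`, `lambda`, `iters`, `lr`).
#' @param out_dir Output directory for artifacts, or `NULL` for in-memory
#'   results only.
#' @return A list of class `run_config`.
#' @export
run_config <- function(distance_mode = "absolute", epsilon = 1e-10,
                       threshold = 0.99, cv = "kfold", n_folds = 10L,
                       seed = 1L, lut = NULL, positive_class = NULL,
                       fs = 128, nca = list(), out_dir = NULL) {
  stopifnot(distance_mode %in% c("absolute", "signed"),
            cv %in% c("kfold", "loro"))
  structure(list(distance_mode = distance_mode, epsilon = epsilon,
                 threshold = threshold, cv = cv, n_folds = as.integer(n_folds),
                 seed = as.integer(seed), lut = lut,
                 positive_class = positive_class, fs = fs,
                 nca = nca, out_dir = out_dir),
            class = "run_config")
}

#' Run the full pipeline on a dataset
#'
#' Extract (15 feature matrices) -> select (cumulative-weight NCA per
#' feature vector) -> classify (tkNN per selected feature vector, out-of-fold
#' under the configured CV scheme) -> fuse (IMV over the 15 outcomes, greedy
#' over the 13 voted candidates) -> explain (DLob report per selection).
#' Fully deterministic given the config seed.
#'
#' @param cfg A [run_config()].
#' @param manifest A validated manifest (see [read_manifest()]), or a list
#'   of [eeg_segment()]s.
#' @return List with `folds`, `selections` (15), `fv_outcomes` (15),
#'   `fused`, `metrics`, `dlob`, `labels`, `segment_ids` and `config`.
#'   With `cfg$out_dir` set, also writes feature CSVs, per-fv outcome CSVs,
#'   the fused outcome, metrics JSON, selection JSONs, DLob reports and a
#'   machine-readable run log.
#' @export
run_pipeline <- function(cfg, manifest) {
  stopifnot(inherits(cfg, "run_config"))
  stage <- "extract"
  result <- tryCatch({
    features <- extract_features(manifest, cfg$distance_mode, cfg$epsilon,
                                 fs = cfg$fs)
    labels <- attr(features, "labels")
    ids <- attr(features, "segment_ids")
    nc <- attr(features, "nc")
    lut <- cfg$lut %||% default_lut(nc)
    man <- if (is.data.frame(manifest)) manifest else
      data.frame(segment_id = ids,
                 record_id = attr(features, "record_ids"),
                 class_label = labels, stringsAsFactors = FALSE)
    folds <- make_folds(man, cfg$cv, cfg$n_folds, cfg$seed)

    stage <- "select"
    nca_args <- cfg$nca
    selections <- lapply(1:15, function(h) {
      w <- do.call(nca_weights, c(list(features[[h]], labels), nca_args))
      cumulative_select(w, cfg$threshold)
    })

    stage <- "classify"
    fv_outcomes <- lapply(1:15, function(h) {
      tknn(apply_selection(features[[h]], selections[[h]]), labels, folds)
    })

    stage <- "fuse"
    fused <- fuse(fv_outcomes, labels)
    pos <- cfg$positive_class %||% max(labels)
    metrics <- compute_metrics(labels, fused$predictions, pos)

    stage <- "explain"
    dlob <- dlob_reports(selections, nc, lut)

    list(folds = folds, selections = selections, fv_outcomes = fv_outcomes,
         fused = fused, metrics = metrics, dlob = dlob, labels = labels,
         segment_ids = ids, features = features, config = cfg)
  }, error = function(e) {
    stop("pipeline failed in stage '", stage, "': ", conditionMessage(e),
         call. = FALSE)
  })
  if (!is.null(cfg$out_dir)) write_results(result, cfg$out_dir)
  result$features <- NULL  # keep the returned object light
  result
}

write_results <- function(result, out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  write_features(result$features, file.path(out_dir, "features"))
  dir.create(file.path(out_dir, "outcomes"), showWarnings = FALSE)
  for (h in 1:15) {
    oc <- result$fv_outcomes[[h]]
    utils::write.csv(data.frame(segment_id = result$segment_ids,
                                true = result$labels,
                                predicted = oc$predictions),
                     file.path(out_dir, "outcomes",
                               sprintf("outcome_fv%02d.csv", h)),
                     row.names = FALSE)
    sel <- result$selections[[h]]
    jsonlite::write_json(
      list(nf = sel$nf, threshold = sel$threshold,
           selected_indices = sel$selected_indices,
           weights_of_selected = sel$weights[sel$selected_indices]),
      file.path(out_dir, "outcomes", sprintf("selection_fv%02d.json", h)),
      auto_unbox = TRUE, digits = NA)
  }
  utils::write.csv(data.frame(segment_id = result$segment_ids,
                              true = result$labels,
                              predicted = result$fused$predictions),
                   file.path(out_dir, "fused_outcome.csv"), row.names = FALSE)
  m <- result$metrics
  jsonlite::write_json(
    list(tp = m$tp, fn = m$fn, tn = m$tn, fp = m$fp, acc = m$acc,
         sen = m$sen, spe = m$spe, gm = m$gm,
         positive_class = m$positive_class, undefined = m$undefined),
    file.path(out_dir, "metrics.json"), auto_unbox = TRUE, digits = NA)
  write_dlob(result$dlob, file.path(out_dir, "dlob"))
  cfg <- result$config
  jsonlite::write_json(
    list(distance_mode = cfg$distance_mode, epsilon = cfg$epsilon,
         threshold = cfg$threshold, cv = cfg$cv, n_folds = cfg$n_folds,
         seed = cfg$seed,
         fused_provenance = result$fused$provenance,
         fv_provenance = lapply(result$fv_outcomes, `[[`, "provenance"),
         fv_accuracies = vapply(result$fv_outcomes, `[[`, 0, "accuracy"),
         r_version = as.character(getRversion()),
         package_version = as.character(utils::packageVersion("soxfe"))),
    file.path(out_dir, "run_log.json"), auto_unbox = TRUE, digits = NA)
  invisible(out_dir)
}
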
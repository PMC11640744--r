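#' The Directed Lobish alphabet
#'
#' Eight symbols naming brain lobe x hemisphere: FL, TL, PL, OL (left
#' frontal, temporal, parietal, occipital) and OR, PR, TR, FR (right
#' occipital, parietal, temporal, frontal). This fixed order indexes
#' histogram and transition-matrix rows/columns throughout.
#'
#' @export
dlob_alphabet <- c("FL", "TL", "PL", "OL", "OR", "PR", "TR", "FR")

#' Default channel-to-lobe look-up table
#'
#' For the standard 14-channel consumer montage (AF3, F7, F3, FC5, T7, P7,
#' O1, O2, P8, T8, FC6, F4, F8, AF4 in 10/20 placement): channels 1-4 are
#' left-frontal, 5 left-temporal, 6 left-parietal, 7 left-occipital, 8
#' right-occipital, 9 right-parietal, 10 right-temporal and 11-14
#' right-frontal.
#'
#' @param nc Channel count; only 14 has a standard table.
#' @return Character vector of length `nc` over [dlob_alphabet].
#' @export
default_lut <- function(nc = 14L) {
  if (nc != 14L)
    stop("no default lobe table for nc = ", nc,
         "; supply a look-up table explicitly")
  c("FL", "FL", "FL", "FL", "TL", "PL", "OL", "OR", "PR", "TR",
    "FR", "FR", "FR", "FR")
}

check_lut <- function(lut, nc) {
  if (length(lut) != nc)
    stop("look-up table length (", length(lut), ") does not match nc (", nc, ")")
  bad <- setdiff(unique(lut), dlob_alphabet)
  if (length(bad))
    stop("look-up table contains non-alphabet symbol(s): ",
         paste(bad, collapse = ", "))
  invisible(lut)
}

#' Decode a selected feature index into a channel pair
#'
#' Every ChMinMaxPat feature position encodes an ordered channel pair: bin
#' (or row-major table cell) `g` within one of the twelve nc^2-blocks of the
#' general feature vector encodes `(first - 1) * nc + (second - 1)`. Decoding
#' inverts that: `mul = floor((value - 1) / nc^2)`, `rem = value - nc^2 *
#' mul`, `first = floor((rem - 1) / nc) + 1`, `second = (rem - 1) %% nc + 1`,
#' `table = mul + 1`.
#'
#' @param value 1-based feature index (vectorized), at most `12 * nc^2`.
#' @param nc Channel count.
#' @return Data frame with integer columns `first`, `second` (channels in
#'   `1..nc`) and `table` (`1..12`).
#' @export
decode_index <- function(value, nc) {
  value <- as.integer(value)
  if (any(value < 1L) || any(value > 12L * nc * nc))
    stop("feature index out of range 1..", 12L * nc * nc)
  mul <- (value - 1L) %/% (nc * nc)
  rem <- value - nc * nc * mul
  data.frame(first = (rem - 1L) %/% nc + 1L,
             second = (rem - 1L) %% nc + 1L,
             table = mul + 1L)
}

#' Build the DLob string for one feature selection
#'
#' For each selected feature index, in descending-weight order, the decoded
#' channel pair contributes two symbols: `LUT[first]` then `LUT[second]`.
#'
#' @param sel A `selection_result` (or a plain vector of selected indices in
#'   final order).
#' @param nc Channel count.
#' @param lut Channel-to-lobe look-up table (default [default_lut()]).
#' @return Character vector of symbols, length `2 * nf`.
#' @export
build_string <- function(sel, nc, lut = default_lut(nc)) {
  check_lut(lut, nc)
  idx <- if (inherits(sel, "selection_result")) sel$selected_indices else sel
  dec <- decode_index(idx, nc)
  as.vector(rbind(lut[dec$first], lut[dec$second]))
}

#' Shannon entropy of a DLob string
#'
#' Base-2 entropy of the 8-symbol histogram; zero-count symbols contribute
#' nothing. Bounded by log2(8) = 3 bits.
#'
#' @param string Character vector of symbols from [dlob_alphabet].
#' @return Entropy in bits.
#' @export
string_entropy <- function(string) {
  if (length(string) == 0L) stop("empty symbol string")
  h <- symbol_histogram(string)
  p <- h / sum(h)
  p <- p[p > 0]
  -sum(p * log2(p))
}

symbol_histogram <- function(string) {
  bad <- setdiff(unique(string), dlob_alphabet)
  if (length(bad))
    stop("symbol(s) outside the DLob alphabet: ", paste(bad, collapse = ", "))
  tab <- table(factor(string, levels = dlob_alphabet))
  stats::setNames(as.integer(tab), dlob_alphabet)
}

#' Directed symbol-transition (connectome) matrix
#'
#' Counts consecutive ordered symbol pairs over the whole string. Rows are
#' "from", columns "to", both in [dlob_alphabet] order; a length-n string
#' yields n-1 transitions (a length-1 string gives the zero matrix).
#'
#' @param string Character vector of symbols from [dlob_alphabet].
#' @return 8 x 8 integer matrix with dimnames from [dlob_alphabet].
#' @export
transition_matrix <- function(string) {
  symbol_histogram(string)  # validates alphabet
  tm <- matrix(0L, 8L, 8L, dimnames = list(dlob_alphabet, dlob_alphabet))
  n <- length(string)
  if (n >= 2L) {
    from <- match(string[-n], dlob_alphabet)
    to <- match(string[-1L], dlob_alphabet)
    for (i in seq_len(n - 1L)) tm[from[i], to[i]] <- tm[from[i], to[i]] + 1L
  }
  tm
}

#' DLob report for one feature selection
#'
#' @inheritParams build_string
#' @return A `dlob_report`: list with `string`, `histogram` (8 counts,
#'   summing to 2*nf), `entropy` (bits) and `transitions` (8 x 8, summing to
#'   2*nf - 1).
#' @export
dlob_report <- function(sel, nc, lut = default_lut(nc)) {
  s <- build_string(sel, nc, lut)
  structure(list(string = s, histogram = symbol_histogram(s),
                 entropy = string_entropy(s),
                 transitions = transition_matrix(s)),
            class = "dlob_report")
}

#' @export
print.dlob_report <- function(x, ...) {
  cat(sprintf("<dlob_report> %d symbols, entropy %.4f bits\n",
              length(x$string), x$entropy))
  cat("  ", paste(x$string[seq_len(min(20L, length(x$string)))],
                  collapse = " "),
      if (length(x$string) > 20L) "...", "\n")
  invisible(x)
}

#' DLob reports for all 15 feature-vector selections
#'
#' One report per selection plus the pooled symbol-frequency table (overall
#' lobe-usage histogram across the 15 strings) and the vector of per-string
#' entropies.
#'
#' @param selections List of 15 `selection_result`s (one per feature
#'   vector).
#' @param nc Channel count.
#' @param lut Channel-to-lobe look-up table.
#' @return List with `reports` (15 `dlob_report`s), `entropies` (length 15)
#'   and `pooled` (8 counts).
#' @export
dlob_reports <- function(selections, nc, lut = default_lut(nc)) {
  reports <- lapply(selections, dlob_report, nc = nc, lut = lut)
  pooled <- Reduce(`+`, lapply(reports, `[[`, "histogram"))
  list(reports = reports,
       entropies = vapply(reports, `[[`, 0, "entropy"),
       pooled = pooled)
}

#' Write DLob reports to disk
#'
#' Strings as plain text (one line per feature vector), entropies and pooled
#' frequencies as CSV, and one 8 x 8 transition-matrix CSV per feature
#' vector.
#'
#' @param dlob Result of [dlob_reports()].
#' @param out_dir Output directory.
#' @return `out_dir`, invisibly.
#' @export
write_dlob <- function(dlob, out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  writeLines(vapply(dlob$reports, function(r) paste(r$string, collapse = " "),
                    ""),
             file.path(out_dir, "dlob_strings.txt"))
  utils::write.csv(data.frame(fv = seq_along(dlob$entropies),
                              entropy_bits = dlob$entropies),
                   file.path(out_dir, "dlob_entropies.csv"), row.names = FALSE)
  utils::write.csv(data.frame(symbol = names(dlob$pooled),
                              count = as.integer(dlob$pooled)),
                   file.path(out_dir, "dlob_pooled_frequencies.csv"),
                   row.names = FALSE)
  for (h in seq_along(dlob$reports))
    utils::write.csv(dlob$reports[[h]]$transitions,
                     file.path(out_dir, sprintf("dlob_transitions_fv%02d.csv", h)))
  invisible(out_dir)
}
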
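# Benchmark statistics for caller output against a truth table: accuracy and
# true-positive rate from confusion counts, MAPE / SMAPE of supporting-read
# recovery, and a read-support threshold sweep over the standard cutoff grid.

#' Accuracy and true-positive rate from confusion counts
#'
#' accuracy = (TP + TN) / (TP + TN + FP + FN); tpr = TP / (TP + FN).
#'
#' @param tp,tn,fp,fn Non-negative counts.
#' @return A fraction.
#' @export
#' @examples
#' fusion_accuracy(tp = 5, tn = 3, fp = 1, fn = 1)
fusion_accuracy <- function(tp, tn = 0, fp = 0, fn = 0) {
  stopifnot(tp >= 0, tn >= 0, fp >= 0, fn >= 0)
  denom <- tp + tn + fp + fn
  if (denom == 0) {
    stop("accuracy is undefined for all-zero counts", call. = FALSE)
  }
  (tp + tn) / denom
}

#' @rdname fusion_accuracy
#' @export
fusion_tpr <- function(tp, fn) {
  stopifnot(tp >= 0, fn >= 0)
  if (tp + fn == 0) {
    stop("TPR is undefined with no positives", call. = FALSE)
  }
  tp / (tp + fn)
}

#' MAPE and SMAPE of supporting-read recovery
#'
#' For fusions with known supporting-read counts A (actual, > 0) and detected
#' counts F (forecast, >= 0): MAPE = mean(|A - F| / A) and
#' SMAPE = mean(|A - F| / (A + F)) with 0/0 -> 0. This SMAPE denominator
#' keeps the statistic in [0, 1] and equals exactly 1 for a caller that
#' detects nothing (F = 0 everywhere), matching its use alongside MAPE = 1.
#'
#' @param actual Known supporting reads per fusion (> 0).
#' @param forecast Detected supporting reads per fusion (>= 0).
#' @return A fraction.
#' @export
#' @examples
#' fusion_mape(actual = 10, forecast = 5)
fusion_mape <- function(actual, forecast) {
  check_series(actual, forecast)
  mean(abs(actual - forecast) / actual)
}

#' @rdname fusion_mape
#' @export
fusion_smape <- function(actual, forecast) {
  check_series(actual, forecast)
  denom <- actual + forecast
  term <- ifelse(denom == 0, 0, abs(actual - forecast) / denom)
  mean(term)
}

check_series <- function(actual, forecast) {
  if (length(actual) == 0) {
    stop("empty series", call. = FALSE)
  }
  stopifnot(length(actual) == length(forecast))
  if (any(actual <= 0)) {
    stop("every actual supporting-read count must be positive", call. = FALSE)
  }
  if (any(forecast < 0)) {
    stop("forecast counts must be non-negative", call. = FALSE)
  }
  invisible(TRUE)
}

#' Match calls against a truth table
#'
#' A call matches a truth fusion iff the unordered gene pair matches and both
#' breakpoints agree within `window` bases (sides may be swapped).
#'
#' @param calls Calls tibble (gene5, gene3, chrom5, pos5, chrom3, pos3,
#'   supporting_reads).
#' @param truth Truth tibble (same breakpoint columns plus fusion_id).
#' @param window Breakpoint agreement window (bases).
#' @return The truth tibble with `detected` (logical), `matched_call` (call
#'   row index or NA) and `detected_reads` (supporting reads of the matched
#'   call, 0 when undetected).
#' @export
match_truth <- function(calls, truth, window = 10L) {
  truth$detected <- FALSE
  truth$matched_call <- NA_integer_
  truth$detected_reads <- 0
  if (nrow(calls) == 0 || nrow(truth) == 0) {
    return(truth)
  }
  for (i in seq_len(nrow(truth))) {
    tt <- truth[i, ]
    straight <- !is.na(calls$gene5) & !is.na(calls$gene3) &
      calls$gene5 == tt$gene5 & calls$gene3 == tt$gene3 &
      calls$chrom5 == tt$chrom5 & abs(calls$pos5 - tt$pos5) <= window &
      calls$chrom3 == tt$chrom3 & abs(calls$pos3 - tt$pos3) <= window
    swapped <- !is.na(calls$gene5) & !is.na(calls$gene3) &
      calls$gene5 == tt$gene3 & calls$gene3 == tt$gene5 &
      calls$chrom5 == tt$chrom3 & abs(calls$pos5 - tt$pos3) <= window &
      calls$chrom3 == tt$chrom5 & abs(calls$pos3 - tt$pos5) <= window
    hit <- which(straight | swapped)
    if (length(hit) > 0) {
      truth$detected[i] <- TRUE
      truth$matched_call[i] <- hit[1]
      truth$detected_reads[i] <- calls$supporting_reads[hit[1]]
    }
  }
  truth
}

#' Accuracy / TPR across read-support cutoffs
#'
#' For each cutoff c a call counts as positive iff its supporting reads are
#' >= c. Counts are computed per sample and aggregated: TP/FN over truth
#' fusions, FP over unmatched calls, and TN as truth-negative samples with no
#' surviving call. The default grid is 1, 2, 3, 4, 5, 10, 20, ..., 100.
#'
#' @param calls Calls tibble with a `sample` column.
#' @param truth Truth tibble with a `sample` column (zero rows of a sample
#'   mark it truth-negative; list such samples in `samples`).
#' @param cutoffs Ascending integer cutoffs.
#' @param samples Character vector of all sample names (defaults to those
#'   present in `calls`/`truth`).
#' @param window Breakpoint matching window.
#' @return A tibble of class `fusion_sweep`: cutoff, tp, tn, fp, fn,
#'   accuracy, tpr.
#' @export
threshold_sweep <- function(calls, truth,
                            cutoffs = c(1:5, seq(10, 100, by = 10)),
                            samples = NULL, window = 10L) {
  stopifnot(!is.unsorted(cutoffs))
  if (!"sample" %in% names(calls)) calls$sample <- "sample1"
  if (!"sample" %in% names(truth)) truth$sample <- "sample1"
  samples <- samples %||% sort(unique(c(calls$sample, truth$sample)))
  out <- vector("list", length(cutoffs))
  for (ci in seq_along(cutoffs)) {
    cc <- cutoffs[ci]
    tp <- fp <- fn <- tn <- 0L
    for (s in samples) {
      cs <- calls[calls$sample == s & calls$supporting_reads >= cc, , drop = FALSE]
      ts <- truth[truth$sample == s, , drop = FALSE]
      if (nrow(ts) == 0) {
        if (nrow(cs) == 0) tn <- tn + 1L else fp <- fp + nrow(cs)
        next
      }
      m <- match_truth(cs, ts, window = window)
      tp <- tp + sum(m$detected)
      fn <- fn + sum(!m$detected)
      fp <- fp + nrow(cs) - length(unique(m$matched_call[m$detected]))
    }
    out[[ci]] <- tibble(
      cutoff = cc, tp = tp, tn = tn, fp = fp, fn = fn,
      accuracy = if (tp + tn + fp + fn > 0) (tp + tn) / (tp + tn + fp + fn) else NA_real_,
      tpr = if (tp + fn > 0) tp / (tp + fn) else NA_real_
    )
  }
  structure(dplyr::bind_rows(out), class = c("fusion_sweep", "tbl_df", "tbl", "data.frame"))
}
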
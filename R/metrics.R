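#' Confusion counts with MCI as the positive class
#'
#' @param truth,pred Label vectors (`"MCI"` / `"HC"`).
#' @param positive Positive class label (default `"MCI"`).
#' @return List of class `confusion_counts` with `TP`, `FN`, `FP`, `TN`.
#' @export
confusion_counts <- function(truth, pred, positive = "MCI") {
  truth <- as.character(truth); pred <- as.character(pred)
  structure(list(
    TP = sum(truth == positive & pred == positive),
    FN = sum(truth == positive & pred != positive),
    FP = sum(truth != positive & pred == positive),
    TN = sum(truth != positive & pred != positive)
  ), class = "confusion_counts")
}

#' Classification metrics from confusion counts
#'
#' Accuracy, sensitivity, specificity, F1 and false-discovery rate, as
#' percentages. Two FDR conventions are available: `"reported"` (default)
#' is the false-discovery rate proper, `FP / (FP + TP)`; `"eq27"` is the
#' false-positive rate `FP / (FP + TN)` that some reports print under the
#' FDR name. Undefined ratios (zero denominators) are returned as `NaN`.
#'
#' @param counts A `confusion_counts` object (or list with TP/FN/FP/TN).
#' @param fdr_mode `"reported"` or `"eq27"`.
#' @return One-row tibble with columns `AC`, `SE`, `SP`, `F1`, `FDR` in
#'   percent.
#' @export
confusion_metrics <- function(counts, fdr_mode = c("reported", "eq27")) {
  fdr_mode <- match.arg(fdr_mode)
  TP <- counts$TP; FN <- counts$FN; FP <- counts$FP; TN <- counts$TN
  if (TP + FN == 0 || FP + TN == 0) {
    stop("confusion counts must include both classes", call. = FALSE)
  }
  fdr_den <- if (fdr_mode == "reported") FP + TP else FP + TN
  tibble::tibble(
    AC = 100 * (TP + TN) / (TP + FN + FP + TN),
    SE = 100 * TP / (TP + FN),
    SP = 100 * TN / (FP + TN),
    F1 = 100 * 2 * TP / (2 * TP + FP + FN),
    FDR = if (fdr_den == 0) 0 else 100 * FP / fdr_den
  )
}
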
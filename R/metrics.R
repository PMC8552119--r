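#' Confusion counts for binary ECM / non-ECM predictions
#'
#' @param labels Character vector of true classes (`"ECM"` / `"non-ECM"`).
#' @param predictions Character vector of predicted classes, same length.
#' @param positive The positive class label (default `"ECM"`).
#' @return A `confusion_counts` list with fields `tp`, `fp`, `tn`, `fn`.
#' @export
confusion <- function(labels, predictions, positive = "ECM") {
  if (length(labels) == 0L) stop("empty input", call. = FALSE)
  if (length(labels) != length(predictions)) {
    stop("labels and predictions lengths differ", call. = FALSE)
  }
  lp <- labels == positive
  pp <- predictions == positive
  confusion_counts(tp = sum(lp & pp), fp = sum(!lp & pp),
                   tn = sum(!lp & !pp), fn = sum(lp & !pp))
}

#' Construct confusion counts directly
#'
#' @param tp,fp,tn,fn Non-negative integer counts (positive class = ECM).
#' @return A `confusion_counts` object.
#' @export
confusion_counts <- function(tp, fp, tn, fn) {
  counts <- c(tp = tp, fp = fp, tn = tn, fn = fn)
  if (any(counts < 0) || any(counts != floor(counts))) {
    stop("confusion counts must be non-negative integers", call. = FALSE)
  }
  structure(as.list(counts), class = "confusion_counts")
}

#' Evaluation statistics from confusion counts
#'
#' Computes the metric set used for imbalanced binary protein
#' classification: sensitivity, specificity, accuracy, balanced accuracy
#' ((sensitivity+specificity)/2), Youden's index (sensitivity+specificity-1),
#' Matthews correlation coefficient and F1. All are fractions in their
#' natural ranges; per convention MCC is 0 when any marginal of the
#' confusion matrix is empty, and sensitivity/specificity are `NA` when the
#' corresponding class is absent.
#'
#' @param counts A `confusion_counts` object.
#' @return A `metrics_report` list.
#' @export
#' @examples
#' compute_metrics(confusion_counts(tp = 8, fp = 10, tn = 90, fn = 2))
compute_metrics <- function(counts) {
  stopifnot(inherits(counts, "confusion_counts"))
  # doubles: the MCC denominator product overflows 32-bit integers easily
  tp <- as.numeric(counts$tp); fp <- as.numeric(counts$fp)
  tn <- as.numeric(counts$tn); fn <- as.numeric(counts$fn)
  n <- tp + fp + tn + fn
  sens <- if (tp + fn >= 1) tp / (tp + fn) else NA_real_
  spec <- if (tn + fp >= 1) tn / (tn + fp) else NA_real_
  acc <- (tp + tn) / n
  ba <- (sens + spec) / 2
  youden <- sens + spec - 1
  f1 <- if (2 * tp + fp + fn > 0) 2 * tp / (2 * tp + fp + fn) else NA_real_
  denom <- (tp + fp) * (tp + fn) * (tn + fp) * (tn + fn)
  mcc <- if (denom == 0) 0 else (tp * tn - fp * fn) / sqrt(denom)
  structure(
    list(sensitivity = sens, specificity = spec, accuracy = acc,
         balanced_accuracy = ba, youden_index = youden, mcc = mcc,
         f1 = f1, counts = counts),
    class = "metrics_report"
  )
}

#' @export
print.metrics_report <- function(x, ...) {
  cat("ECM classification metrics\n")
  with(x$counts, cat(sprintf("  tp=%d fp=%d tn=%d fn=%d\n", tp, fp, tn, fn)))
  for (f in c("sensitivity", "specificity", "accuracy", "balanced_accuracy",
              "youden_index", "mcc", "f1")) {
    cat(sprintf("  %-18s %.4f\n", f, x[[f]]))
  }
  invisible(x)
}

#' Mean squared reconstruction error in decibels
#'
#' `10 * log10(mean((original - reconstructed)^2))`. An exactly zero error
#' is clamped to `floor_db`.
#'
#' @param original,reconstructed Numeric matrices of identical shape.
#' @param floor_db Value returned for exact-zero error (default -120 dB).
#' @return Scalar MSE in dB.
#' @export
mse_db <- function(original, reconstructed, floor_db = -120) {
  if (!identical(dim(original), dim(reconstructed))) {
    stop("shape mismatch between original and reconstruction", call. = FALSE)
  }
  mse <- mean((original - reconstructed)^2)
  if (mse == 0) return(floor_db)
  max(10 * log10(mse), floor_db)
}

#' Serialize a metrics report
#'
#' JSON, or a one-row TSV in the conventional column order (sensitivity,
#' specificity, MCC, Youden's index, accuracy, balanced accuracy).
#'
#' @param report A `metrics_report`.
#' @param path Output path.
#' @param format `"json"` or `"tsv"`.
#' @return `path`, invisibly.
#' @export
write_metrics <- function(report, path, format = c("json", "tsv")) {
  format <- match.arg(format)
  if (format == "json") {
    x <- unclass(report)
    x$counts <- unclass(x$counts)
    jsonlite::write_json(x, path, auto_unbox = TRUE, digits = NA)
  } else {
    df <- data.frame(sensitivity = report$sensitivity,
                     specificity = report$specificity,
                     mcc = report$mcc,
                     youden_index = report$youden_index,
                     accuracy = report$accuracy,
                     balanced_accuracy = report$balanced_accuracy)
    utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  }
  invisible(path)
}
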
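# Confusion-matrix construction and the four standard evaluation
# metrics: sensitivity, specificity, accuracy, and the Matthews
# correlation coefficient.

#' Construct confusion counts
#'
#' Either supply the four cells directly, or truth/call vectors (any
#' vectors coercible to the labels `"positive"`/`"negative"`).
#'
#' @param tp,fp,tn,fn non-negative integer cell counts.
#' @param truth,call character vectors of true and predicted labels
#'   (alternative to the cell counts).
#' @return an object of class `confusion_counts`.
#' @examples
#' confusion_counts(tp = 70, fp = 22, tn = 78, fn = 30)
#' @export
confusion_counts <- function(tp = NULL, fp = NULL, tn = NULL, fn = NULL,
                             truth = NULL, call = NULL) {
  if (!is.null(truth)) {
    stopifnot(length(truth) == length(call))
    tp <- sum(truth == "positive" & call == "positive")
    fp <- sum(truth == "negative" & call == "positive")
    tn <- sum(truth == "negative" & call == "negative")
    fn <- sum(truth == "positive" & call == "negative")
  }
  cells <- c(tp = tp, fp = fp, tn = tn, fn = fn)
  if (anyNA(cells) || any(cells < 0) || any(cells != round(cells))) {
    stop("confusion counts must be non-negative integers")
  }
  structure(as.list(setNames(as.integer(cells), names(cells))),
            class = "confusion_counts")
}

#' @export
print.confusion_counts <- function(x, ...) {
  cat(sprintf("confusion_counts: TP=%d FP=%d TN=%d FN=%d\n", x$tp, x$fp, x$tn, x$fn))
  invisible(x)
}

undefined_metric <- function(what, why) {
  warning(what, " is undefined: ", why, call. = FALSE)
  NA_real_
}

#' Sensitivity (true positive rate)
#'
#' `TP / (TP + FN)`. Undefined (returned as `NA` with a warning, never
#' silently 0) when no positives are present.
#'
#' @param c a `confusion_counts`.
#' @export
sensitivity <- function(c) {
  if (c$tp + c$fn == 0L) return(undefined_metric("sensitivity", "TP + FN = 0"))
  c$tp / (c$tp + c$fn)
}

#' Specificity (true negative rate)
#'
#' `TN / (TN + FP)`; `NA` with a warning when no negatives are present.
#'
#' @param c a `confusion_counts`.
#' @export
specificity <- function(c) {
  if (c$tn + c$fp == 0L) return(undefined_metric("specificity", "TN + FP = 0"))
  c$tn / (c$tn + c$fp)
}

#' Accuracy
#'
#' `(TP + TN) / (TP + TN + FP + FN)`; `NA` with a warning on an empty
#' confusion matrix.
#'
#' @param c a `confusion_counts`.
#' @export
accuracy <- function(c) {
  total <- c$tp + c$tn + c$fp + c$fn
  if (total == 0L) return(undefined_metric("accuracy", "empty confusion matrix"))
  (c$tp + c$tn) / total
}

#' Matthews correlation coefficient
#'
#' `(TP*TN - FP*FN) / sqrt((TP+FP)(TP+FN)(TN+FP)(TN+FN))`, in
#' `[-1, 1]`. When any factor of the denominator is zero the
#' coefficient is returned as 0 (the standard convention for a
#' degenerate matrix); an empty matrix yields `NA` with a warning.
#'
#' @param c a `confusion_counts`.
#' @export
mcc <- function(c) {
  total <- c$tp + c$tn + c$fp + c$fn
  if (total == 0L) return(undefined_metric("MCC", "empty confusion matrix"))
  f <- as.numeric(c(c$tp + c$fp, c$tp + c$fn, c$tn + c$fp, c$tn + c$fn))
  if (any(f == 0)) return(0)
  (as.numeric(c$tp) * c$tn - as.numeric(c$fp) * c$fn) / sqrt(prod(f))
}

#' Bundle confusion counts with all four metrics
#'
#' @param counts a `confusion_counts`.
#' @return an object of class `psi_eval` with fields `counts`, `sn`,
#'   `sp`, `acc`, `mcc`.
#' @export
eval_result <- function(counts) {
  structure(list(counts = counts,
                 sn = sensitivity(counts), sp = specificity(counts),
                 acc = accuracy(counts), mcc = mcc(counts)),
            class = "psi_eval")
}

#' @export
print.psi_eval <- function(x, ...) {
  cat(sprintf("SN = %s  SP = %s  ACC = %s  MCC = %s\n",
              fmt_pct(x$sn), fmt_pct(x$sp), fmt_pct(x$acc),
              ifelse(is.na(x$mcc), "NA", sprintf("%.2f", x$mcc))))
  print(x$counts)
  invisible(x)
}

fmt_pct <- function(p) if (is.na(p)) "NA" else sprintf("%.2f%%", 100 * p)

#' Write an evaluation result as one-row TSV and as JSON
#'
#' Metrics are stored as proportions; percentage formatting is
#' display-only.
#'
#' @param x a `psi_eval`.
#' @param path_prefix files `<prefix>.tsv` and `<prefix>.json` are
#'   written.
#' @export
write_eval_result <- function(x, path_prefix) {
  row <- data.frame(tp = x$counts$tp, fp = x$counts$fp,
                    tn = x$counts$tn, fn = x$counts$fn,
                    sn = x$sn, sp = x$sp, acc = x$acc, mcc = x$mcc)
  write.table(row, paste0(path_prefix, ".tsv"), sep = "\t",
              quote = FALSE, row.names = FALSE)
  jsonlite::write_json(as.list(row), paste0(path_prefix, ".json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  invisible(path_prefix)
}
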
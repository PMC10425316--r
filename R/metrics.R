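#' Confusion matrix for binary predictions
#'
#' Cross-tabulates true against predicted 0/1 labels, with class 1
#' (cases, e.g. "ASD") as the positive class.
#'
#' @param truth integer vector of true 0/1 labels.
#' @param pred integer vector of predicted 0/1 labels, same length.
#' @return An object of class `confusion_matrix`: a list with counts `tp`,
#'   `fp`, `fn`, `tn`.
#' @export
confusion_matrix <- function(truth, pred) {
  if (length(truth) != length(pred)) {
    stopf("truth (%d) and pred (%d) differ in length", length(truth), length(pred))
  }
  truth <- as.integer(truth)
  pred <- as.integer(pred)
  seen <- unique(c(truth, pred))
  if (!all(seen %in% c(0L, 1L))) {
    stopf("unseen label(s): %s", paste(setdiff(seen, c(0L, 1L)), collapse = ", "))
  }
  structure(
    list(tp = sum(truth == 1L & pred == 1L),
         fp = sum(truth == 0L & pred == 1L),
         fn = sum(truth == 1L & pred == 0L),
         tn = sum(truth == 0L & pred == 0L)),
    class = "confusion_matrix"
  )
}

#' @export
print.confusion_matrix <- function(x, ...) {
  m <- matrix(c(x$tp, x$fn, x$fp, x$tn), nrow = 2,
              dimnames = list(truth = c("pos", "neg"), pred = c("pos", "neg")))
  print(m)
  invisible(x)
}

# 0/0 ratios are reported as 0, with a warning, so degenerate confusion
# matrices (e.g. a constant classifier) never produce NaN scores.
safe_ratio <- function(num, den, what) {
  if (den == 0) {
    warnf("undefined %s (0/0) reported as 0", what)
    return(0)
  }
  num / den
}

#' Performance scores from a confusion matrix
#'
#' Computes every confusion-matrix measure the pipeline reports: accuracy and
#' error, positive-class precision and recall, micro- and macro-averaged
#' precision and recall under standard one-vs-rest pooling over the two
#' classes, and the F1 measure (harmonic mean of macro precision and macro
#' recall). Undefined 0/0 ratios are reported as 0 with a warning.
#'
#' @param cm a [confusion_matrix()].
#' @return A named list with elements `accuracy`, `error`, `precision`,
#'   `recall`, `micro_precision`, `macro_precision`, `micro_recall`,
#'   `macro_recall`, `f1`, all in `[0, 1]`.
#' @export
classification_scores <- function(cm) {
  stopifnot(inherits(cm, "confusion_matrix"))
  n <- cm$tp + cm$fp + cm$fn + cm$tn
  if (n == 0) stopf("empty confusion matrix")
  accuracy <- (cm$tp + cm$tn) / n
  precision <- safe_ratio(cm$tp, cm$tp + cm$fp, "precision")
  recall <- safe_ratio(cm$tp, cm$tp + cm$fn, "recall")
  # one-vs-rest view of the negative class: its tp are the tn, etc.
  precision_neg <- safe_ratio(cm$tn, cm$tn + cm$fn, "negative-class precision")
  recall_neg <- safe_ratio(cm$tn, cm$tn + cm$fp, "negative-class recall")
  micro_precision <- safe_ratio(cm$tp + cm$tn,
                                cm$tp + cm$fp + cm$tn + cm$fn, "micro precision")
  micro_recall <- safe_ratio(cm$tp + cm$tn,
                             cm$tp + cm$fn + cm$tn + cm$fp, "micro recall")
  macro_precision <- (precision + precision_neg) / 2
  macro_recall <- (recall + recall_neg) / 2
  f1 <- if (macro_precision + macro_recall == 0) {
    warnf("undefined F1 (0/0) reported as 0")
    0
  } else {
    2 * macro_precision * macro_recall / (macro_precision + macro_recall)
  }
  list(accuracy = accuracy, error = 1 - accuracy,
       precision = precision, recall = recall,
       micro_precision = micro_precision, macro_precision = macro_precision,
       micro_recall = micro_recall, macro_recall = macro_recall, f1 = f1)
}
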
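# Confusion-matrix evaluation: accuracy, per-class and macro-averaged
# precision/recall/F1, all in percent, and cross-fold aggregation.

#' Build a confusion matrix
#'
#' Entry `(i, j)` counts trials with true class `i` predicted as class `j`
#' (rows = true labels, columns = predictions); labels are 0-based.
#'
#' @param yTrue,yPred integer vectors of equal length with values in
#'   `[0, nClasses)`.
#' @param nClasses number of classes.
#' @return `nClasses x nClasses` integer matrix.
#' @examples
#' confusionMatrix(c(0, 0, 1), c(0, 1, 1), 2)
#' @export
confusionMatrix <- function(yTrue, yPred, nClasses) {
  if (length(yTrue) != length(yPred)) {
    stop(sprintf("length mismatch: %d true labels vs %d predictions",
                 length(yTrue), length(yPred)))
  }
  nClasses <- as.integer(nClasses)
  if (length(yTrue) &&
      (any(yTrue < 0 | yTrue >= nClasses) || any(yPred < 0 | yPred >= nClasses)))
    stop("labels out of range [0, ", nClasses, ")")
  cm <- matrix(0L, nClasses, nClasses,
               dimnames = list(true = 0:(nClasses - 1L),
                               predicted = 0:(nClasses - 1L)))
  if (length(yTrue)) {
    tab <- table(factor(yTrue, levels = 0:(nClasses - 1L)),
                 factor(yPred, levels = 0:(nClasses - 1L)))
    cm[] <- as.integer(tab)
  }
  cm
}

#' Per-class precision, recall and F1 from a confusion matrix
#'
#' For class c: TP is the diagonal entry, FP the rest of column c, FN the
#' rest of row c. Precision and recall are percentages; F1 is their harmonic
#' mean (already on the percent scale, so no further scaling). Classes with
#' a zero denominator get a 0 sentinel and `defined = FALSE` rather than an
#' error.
#'
#' @param confusion square count matrix (rows = true, columns = predicted).
#' @return data.frame with columns `class`, `precision`, `recall`, `f1`,
#'   `support`, `predicted`, `defined`.
#' @export
perClassMetrics <- function(confusion) {
  if (!is.matrix(confusion) || nrow(confusion) != ncol(confusion))
    stop("confusion matrix must be square")
  n <- nrow(confusion)
  tp <- diag(confusion)
  colTot <- colSums(confusion)   # predicted counts: TP + FP
  rowTot <- rowSums(confusion)   # true counts: TP + FN
  precision <- ifelse(colTot > 0, 100 * tp / colTot, 0)
  recall <- ifelse(rowTot > 0, 100 * tp / rowTot, 0)
  f1 <- f1FromPrecisionRecall(precision, recall)
  defined <- colTot > 0 & rowTot > 0
  data.frame(class = seq_len(n) - 1L, precision = precision, recall = recall,
             f1 = f1, support = as.integer(rowTot),
             predicted = as.integer(colTot), defined = defined,
             row.names = NULL)
}

#' Harmonic-mean F1 from precision and recall percentages
#'
#' `F1 = 2 P R / (P + R)`, staying on the percent scale. Zero-denominator
#' pairs give 0.
#'
#' @param precision,recall vectors of percentages.
#' @return vector of F1 percentages.
#' @examples
#' f1FromPrecisionRecall(89.70, 96.30)   # 92.88 to 2 decimals
#' @export
f1FromPrecisionRecall <- function(precision, recall) {
  ifelse(precision + recall > 0,
         2 * precision * recall / (precision + recall), 0)
}

#' Full metrics report from a confusion matrix
#'
#' Accuracy is `100 * trace / total` (the multiclass proportion of correct
#' trials). The headline precision/recall/F1 are unweighted macro averages
#' of the per-class values; classes with no true and no predicted instances
#' are excluded from the averages (and flagged). `average = "weighted"`
#' weights classes by support instead.
#'
#' @param confusion square count matrix.
#' @param average `"macro"` (default) or `"weighted"`.
#' @return a [MetricsReport-class].
#' @export
overallMetrics <- function(confusion, average = c("macro", "weighted")) {
  average <- match.arg(average)
  if (!is.matrix(confusion) || nrow(confusion) != ncol(confusion))
    stop("confusion matrix must be square")
  total <- sum(confusion)
  pc <- perClassMetrics(confusion)
  if (total == 0) {
    return(new("MetricsReport", confusion = confusion, perClass = pc,
               accuracy = NA_real_, macroPrecision = NA_real_,
               macroRecall = NA_real_, macroF1 = NA_real_,
               flags = list(undefined = TRUE)))
  }
  keep <- pc$support > 0 | pc$predicted > 0
  w <- if (average == "macro") rep(1, sum(keep)) else pc$support[keep]
  wavg <- function(x) sum(x[keep] * w) / sum(w)
  new("MetricsReport", confusion = confusion, perClass = pc,
      accuracy = 100 * sum(diag(confusion)) / total,
      macroPrecision = wavg(pc$precision),
      macroRecall = wavg(pc$recall),
      macroF1 = wavg(pc$f1),
      flags = list(undefined = FALSE, excluded = pc$class[!keep],
                   average = average))
}

#' Evaluate a model on labelled trials
#'
#' Runs evaluation-mode forward passes and summarizes the predictions as a
#' [MetricsReport-class].
#'
#' @param model a trained model.
#' @param dataset a [LabeledDataset-class].
#' @param indices optional subset of trial indices to evaluate (1-based).
#' @param chunk number of trials per forward batch.
#' @return a [MetricsReport-class].
#' @export
evaluateModel <- function(model, dataset, indices = NULL, chunk = 16L) {
  if (is.null(indices)) indices <- seq_len(nTrials(dataset))
  trialsList <- dataset@trials[indices]
  yTrue <- dataset@labels[indices]
  preds <- integer(length(indices))
  for (start in seq(1L, length(indices), by = chunk)) {
    sel <- start:min(start + chunk - 1L, length(indices))
    preds[sel] <- predictLabels(model, trialsList[sel])
  }
  overallMetrics(confusionMatrix(yTrue, preds, nClasses(dataset)))
}

#' Aggregate metrics across folds
#'
#' Computes the arithmetic mean and the sample standard deviation
#' (denominator k - 1) of each metric across folds. With fewer than two
#' values the standard deviation is NA.
#'
#' @param x a numeric vector of a single metric's per-fold values, or a
#'   list of [MetricsReport-class] objects.
#' @return for a numeric vector, `c(mean, sd)`; for reports, a data.frame
#'   with one row per metric (`metric`, `mean`, `sd`).
#' @examples
#' aggregateFolds(c(94.30, 92.56, 92.41, 91.77, 92.25))  # 92.66, 0.96
#' @export
aggregateFolds <- function(x) {
  if (is.numeric(x)) {
    return(c(mean = mean(x),
             sd = if (length(x) >= 2L) stats::sd(x) else NA_real_))
  }
  stopifnot(is.list(x), length(x) >= 1L,
            all(vapply(x, is, TRUE, "MetricsReport")))
  mm <- do.call(rbind, lapply(x, macroMetrics))
  data.frame(metric = colnames(mm),
             mean = colMeans(mm),
             sd = if (nrow(mm) >= 2L) apply(mm, 2L, stats::sd) else NA_real_,
             row.names = NULL)
}

#' Serialize a metrics report to JSON
#'
#' @param report a [MetricsReport-class].
#' @param path optional output path; when NULL the JSON string is returned.
#' @return the JSON string, invisibly when written to a file.
#' @export
metricsToJson <- function(report, path = NULL) {
  obj <- list(accuracy = report@accuracy,
              macro_precision = report@macroPrecision,
              macro_recall = report@macroRecall,
              macro_f1 = report@macroF1,
              per_class = report@perClass,
              confusion = unname(report@confusion),
              flags = report@flags)
  js <- jsonlite::toJSON(obj, auto_unbox = TRUE, digits = NA, na = "null")
  if (is.null(path)) return(js)
  writeLines(js, path)
  invisible(js)
}

#' Write a confusion matrix as CSV with class labels
#'
#' @param confusion square count matrix.
#' @param path output path.
#' @export
confusionToCsv <- function(confusion, path) {
  df <- as.data.frame(unclass(confusion))
  colnames(df) <- paste0("pred_", seq_len(ncol(confusion)) - 1L)
  df <- cbind(true = seq_len(nrow(confusion)) - 1L, df)
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}
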
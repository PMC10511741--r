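# Confusion-matrix construction and derived statistics, with RA fixed as the
# positive class throughout.

#' Confusion matrix for binary RA classification
#'
#' @param truth True labels (`"normal"` / `"RA"`), any vector coercible to
#'   those two values.
#' @param predicted Predicted labels, same length.
#' @return Object of class `confusion_matrix` with counts `TN`, `FP`, `FN`,
#'   `TP` (positive class = RA).
#' @export
confusion_matrix <- function(truth, predicted) {
  truth <- as.character(truth); predicted <- as.character(predicted)
  if (length(truth) != length(predicted))
    stop_input("truth and predicted must have equal length")
  bad <- setdiff(unique(c(truth, predicted)), thermo_labels)
  if (length(bad)) stop_input("unknown labels: ", paste(bad, collapse = ", "))
  structure(list(TN = sum(truth == "normal" & predicted == "normal"),
                 FP = sum(truth == "normal" & predicted == "RA"),
                 FN = sum(truth == "RA" & predicted == "normal"),
                 TP = sum(truth == "RA" & predicted == "RA")),
            class = "confusion_matrix")
}

#' Build a confusion matrix directly from counts
#'
#' @param TN,FP,FN,TP Non-negative counts; positive class = RA.
#' @return Object of class `confusion_matrix`.
#' @export
confusion_counts <- function(TN, FP, FN, TP) {
  counts <- c(TN, FP, FN, TP)
  if (any(counts < 0)) stop_input("counts must be non-negative")
  structure(list(TN = TN, FP = FP, FN = FN, TP = TP),
            class = "confusion_matrix")
}

#' @export
print.confusion_matrix <- function(x, ...) {
  m <- matrix(c(x$TN, x$FN, x$FP, x$TP), 2, 2,
              dimnames = list(predicted = c("normal", "RA"),
                              truth = c("normal", "RA")))
  print(m)
  invisible(x)
}

#' Classification report from a confusion matrix
#'
#' Per-class precision, recall and F1 plus support-weighted averages and
#' overall accuracy.  Statistics with a zero denominator are reported as 0
#' and flagged in `zero_division`.
#'
#' @param cm A `confusion_matrix`.
#' @return Object of class `classification_report` with elements `per_class`
#'   (data frame for normal and RA), `weighted` (precision, recall, f1),
#'   `accuracy`, `support`, `zero_division`, and optionally `auc`.
#' @export
classification_metrics <- function(cm) {
  total <- cm$TN + cm$FP + cm$FN + cm$TP
  if (total <= 0) stop_input("empty confusion matrix")
  zero_flag <- FALSE
  safe_div <- function(a, b) {
    if (b == 0) { zero_flag <<- TRUE; return(0) }
    a / b
  }
  # RA is positive: predicted-RA = TP + FP; predicted-normal = TN + FN
  prec <- c(normal = safe_div(cm$TN, cm$TN + cm$FN),
            RA = safe_div(cm$TP, cm$TP + cm$FP))
  rec <- c(normal = safe_div(cm$TN, cm$TN + cm$FP),
           RA = safe_div(cm$TP, cm$TP + cm$FN))
  f1 <- mapply(function(p, r) if (p + r == 0) { zero_flag <<- TRUE; 0 }
               else 2 * p * r / (p + r), prec, rec)
  support <- c(normal = cm$TN + cm$FP, RA = cm$TP + cm$FN)
  w <- support / total
  structure(list(per_class = data.frame(class = c("normal", "RA"),
                                        precision = unname(prec),
                                        recall = unname(rec),
                                        f1 = unname(f1),
                                        support = unname(support)),
                 weighted = list(precision = sum(w * prec),
                                 recall = sum(w * rec),
                                 f1 = sum(w * f1)),
                 accuracy = (cm$TP + cm$TN) / total,
                 support = support,
                 confusion = cm,
                 zero_division = zero_flag),
            class = "classification_report")
}

#' @export
print.classification_report <- function(x, digits = 2, ...) {
  df <- x$per_class
  df$precision <- round_half_up(df$precision, digits)
  df$recall <- round_half_up(df$recall, digits)
  df$f1 <- round_half_up(df$f1, digits)
  print(df, row.names = FALSE)
  cat(sprintf("Weighted avg: precision %.2f, recall %.2f, F1 %.2f\n",
              round_half_up(x$weighted$precision, digits),
              round_half_up(x$weighted$recall, digits),
              round_half_up(x$weighted$f1, digits)))
  cat(sprintf("Accuracy: %s%%\n",
              format(round_half_up(100 * x$accuracy, digits))))
  if (!is.null(x$auc) && !is.na(x$auc %||% NA))
    cat(sprintf("AUC: %.3f\n", x$auc))
  if (isTRUE(x$zero_division))
    cat("(one or more statistics had a zero denominator and were set to 0)\n")
  invisible(x)
}

#' ROC curve and AUC
#'
#' Thresholds the decision scores at every distinct value, yielding a
#' monotone (FPR, TPR) staircase from (0, 0) to (1, 1); the AUC is computed
#' by the trapezoidal rule, which equals the Mann-Whitney pair statistic with
#' ties counted one half.
#'
#' @param truth Binary labels (`"RA"` positive).
#' @param scores Real-valued decision scores (higher = more RA-like).
#' @return Object of class `roc_curve` with `points` (data frame of fpr, tpr)
#'   and `auc`.
#' @export
roc_auc <- function(truth, scores) {
  y <- as.character(truth) == "RA"
  if (length(y) != length(scores)) stop_input("length mismatch")
  np <- sum(y); nn <- sum(!y)
  if (np == 0 || nn == 0) stop_input("both classes must be present")
  ord <- order(scores, decreasing = TRUE)
  ys <- y[ord]; ss <- scores[ord]
  # group tied scores so the curve moves diagonally through ties
  grp <- cumsum(!duplicated(ss))
  tp <- cumsum(ys); fp <- cumsum(!ys)
  last <- !duplicated(grp, fromLast = TRUE)
  tpr <- c(0, tp[last] / np)
  fpr <- c(0, fp[last] / nn)
  auc <- sum(diff(fpr) * (head(tpr, -1) + tpr[-1]) / 2)
  structure(list(points = data.frame(fpr = fpr, tpr = tpr), auc = auc),
            class = "roc_curve")
}

#' @export
print.roc_curve <- function(x, ...) {
  cat(sprintf("<roc_curve> %d points, AUC = %.4f\n", nrow(x$points), x$auc))
  invisible(x)
}

#' @export
plot.roc_curve <- function(x, ...) {
  plot(x$points$fpr, x$points$tpr, type = "l", xlab = "False positive rate",
       ylab = "True positive rate", main = sprintf("ROC (AUC = %.3f)", x$auc))
  graphics::abline(0, 1, lty = 3)
  invisible(x)
}

#' Write / read a classification report
#'
#' `emit_report` writes a JSON rendering (full precision) and, for
#' `format = "csv"`, a table mirroring the per-class/weighted layout at
#' 2-decimal rounding.  `read_report` round-trips the JSON losslessly.
#'
#' @param report A `classification_report`.
#' @param path Output path (extension added per format).
#' @param format `"json"`, `"csv"` or both.
#' @return Invisibly, the paths written.
#' @export
emit_report <- function(report, path, format = c("json", "csv")) {
  format <- match.arg(format, several.ok = TRUE)
  paths <- character(0)
  base <- sub("\\.(json|csv)$", "", path)
  if ("json" %in% format) {
    p <- paste0(base, ".json")
    payload <- list(per_class = report$per_class,
                    weighted = report$weighted,
                    accuracy = report$accuracy,
                    support = as.list(report$support),
                    confusion = report$confusion[c("TN", "FP", "FN", "TP")],
                    zero_division = report$zero_division)
    if (!is.null(report$auc) && !is.na(report$auc %||% NA))
      payload$auc <- report$auc
    jsonlite::write_json(payload, p, auto_unbox = TRUE, digits = NA)
    paths <- c(paths, p)
  }
  if ("csv" %in% format) {
    p <- paste0(base, ".csv")
    pc <- report$per_class
    df <- data.frame(
      class = c(pc$class, "weighted average"),
      precision = round_half_up(c(pc$precision, report$weighted$precision)),
      recall = round_half_up(c(pc$recall, report$weighted$recall)),
      f1 = round_half_up(c(pc$f1, report$weighted$f1)),
      accuracy_pct = round_half_up(100 * report$accuracy))
    write.csv(df, p, row.names = FALSE)
    paths <- c(paths, p)
  }
  invisible(paths)
}

#' @rdname emit_report
#' @export
read_report <- function(path) {
  j <- jsonlite::read_json(path, simplifyVector = TRUE)
  cm <- confusion_counts(j$confusion$TN, j$confusion$FP, j$confusion$FN,
                         j$confusion$TP)
  rep <- classification_metrics(cm)
  if (!is.null(j$auc)) rep$auc <- j$auc
  rep
}
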
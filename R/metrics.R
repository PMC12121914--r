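#' Confusion-matrix counts
#'
#' @param labels Binary vector of true labels (1 = positive class).
#' @param predictions Binary vector of predicted labels, same length.
#' @return A `confusion_counts` list with integers `TP`, `FP`, `TN`, `FN`.
#' @export
confusion <- function(labels, predictions) {
  if (length(labels) != length(predictions))
    stop("labels and predictions must have equal length")
  labels <- as.integer(labels); predictions <- as.integer(predictions)
  if (length(labels) && (!all(labels %in% 0:1) || !all(predictions %in% 0:1)))
    stop("labels and predictions must be binary (0/1)")
  structure(list(
    TP = sum(labels == 1L & predictions == 1L),
    FP = sum(labels == 0L & predictions == 1L),
    TN = sum(labels == 0L & predictions == 0L),
    FN = sum(labels == 1L & predictions == 0L)
  ), class = "confusion_counts")
}

#' Sensitivity, specificity, accuracy and MCC from confusion counts
#'
#' Sn = TP/(TP+FN), Sp = TN/(TN+FP), Acc = (TP+TN)/N and the Matthews
#' correlation coefficient
#' MCC = (TP*TN - FP*FN) / sqrt((TP+FN)(TN+FP)(TP+FP)(TN+FN)).
#' A metric whose denominator is zero is reported as 0 and listed in the
#' `degenerate` field rather than raising an error, so reports stay
#' total on degenerate evaluation sets.
#'
#' @param counts A `confusion_counts` object (or list with TP/FP/TN/FN).
#' @param auc Optional AUC to carry into the report (see [roc_auc()]).
#' @return A `metrics_report` list: `sensitivity`, `specificity`,
#'   `accuracy`, `mcc`, `auc` (possibly `NA`), `counts`, `degenerate`
#'   (character vector of zero-denominator metrics).
#' @examples
#' compute_metrics(confusion(c(1, 1, 0, 0), c(1, 0, 0, 1)))
#' @export
compute_metrics <- function(counts, auc = NA_real_) {
  TP <- counts$TP; FP <- counts$FP; TN <- counts$TN; FN <- counts$FN
  degenerate <- character()
  safe <- function(num, den, what) {
    if (den == 0) { degenerate <<- c(degenerate, what); 0 } else num / den
  }
  sn <- safe(TP, TP + FN, "sensitivity")
  sp <- safe(TN, TN + FP, "specificity")
  acc <- safe(TP + TN, TP + FP + TN + FN, "accuracy")
  mcc_den <- sqrt(prod(c(TP + FN, TN + FP, TP + FP, TN + FN)))
  mcc <- if (mcc_den == 0) { degenerate <- c(degenerate, "mcc"); 0 } else
    (TP * TN - FP * FN) / mcc_den
  structure(list(sensitivity = sn, specificity = sp, accuracy = acc,
                 mcc = mcc, auc = auc, counts = counts,
                 degenerate = degenerate),
            class = "metrics_report")
}

#' @export
print.metrics_report <- function(x, digits = 4, ...) {
  cat(sprintf("Sn = %.*f  Sp = %.*f  Acc = %.*f  MCC = %.*f  AUC = %s\n",
              digits, x$sensitivity, digits, x$specificity,
              digits, x$accuracy, digits, x$mcc,
              if (is.na(x$auc)) "NA" else formatC(x$auc, digits = digits,
                                                  format = "f")))
  if (length(x$degenerate))
    cat("  (zero-denominator metric(s) reported as 0: ",
        paste(x$degenerate, collapse = ", "), ")\n", sep = "")
  invisible(x)
}

#' Area under the ROC curve from continuous scores
#'
#' Computed exactly via the rank (Mann-Whitney U) formulation: the
#' probability that a random positive scores above a random negative,
#' with ties contributing 1/2. Equivalent to the area under the
#' sensitivity vs (1 - specificity) curve over all thresholds.
#'
#' @param labels Binary vector (1 = positive); must contain both classes.
#' @param scores Numeric decision scores, same length.
#' @return AUC in `[0, 1]`.
#' @examples
#' roc_auc(c(1, 0, 1, 0), c(0.9, 0.8, 0.3, 0.1))  # 0.75
#' @export
roc_auc <- function(labels, scores) {
  if (length(labels) != length(scores))
    stop("labels and scores must have equal length")
  labels <- as.integer(labels)
  n_pos <- sum(labels == 1L); n_neg <- sum(labels == 0L)
  if (n_pos == 0L || n_neg == 0L)
    stop("AUC undefined: labels must contain both classes")
  r <- rank(scores, ties.method = "average")
  (sum(r[labels == 1L]) - n_pos * (n_pos + 1) / 2) / (n_pos * n_neg)
}

#' Write one-row-per-model metrics tables
#'
#' @param reports Named list of `metrics_report` objects; names become
#'   the `model` column.
#' @param path Output path (tab-separated with header).
#' @return The assembled data frame, invisibly.
#' @export
write_metrics_table <- function(reports, path = NULL) {
  df <- do.call(rbind, lapply(names(reports), function(nm) {
    r <- reports[[nm]]
    data.frame(model = nm, Sensitivity = r$sensitivity,
               Specificity = r$specificity, Accuracy = r$accuracy,
               MCC = r$mcc, AUC = r$auc)
  }))
  if (!is.null(path))
    utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(df)
}
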
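#' Confusion counts from truth and prediction
#'
#' For two classes, `positive` names the class counted as "positive" (TP/FN
#' live there). For more classes the full k x k confusion matrix is kept and
#' per-class counts are derived one-vs-rest.
#'
#' @param truth,pred label vectors of equal length.
#' @param positive positive class for the binary case (default: last level).
#' @return object of class `confusion_counts` with the confusion `table` and
#'   per-class `TP`, `TN`, `FP`, `FN`.
#' @export
confusion_counts <- function(truth, pred, positive = NULL) {
  lev <- union(levels(factor(truth)), levels(factor(pred)))
  truth <- factor(truth, levels = lev)
  pred <- factor(pred, levels = lev)
  if (length(truth) != length(pred)) stop_hos("truth/pred length mismatch")
  if (length(truth) == 0L) stop_hos("need at least one sample")
  tab <- table(truth = truth, pred = pred)
  per_class <- lapply(lev, function(cl) {
    tp <- tab[cl, cl]
    fn <- sum(tab[cl, ]) - tp
    fp <- sum(tab[, cl]) - tp
    tn <- sum(tab) - tp - fn - fp
    c(TP = tp, TN = tn, FP = fp, FN = fn)
  })
  names(per_class) <- lev
  if (!is.null(positive) && length(lev) == 2L) {
    per_class <- per_class[c(setdiff(lev, positive), positive)]
  }
  structure(list(table = tab, per_class = per_class, levels = names(per_class)),
            class = "confusion_counts")
}

#' Sensitivity, specificity and total accuracy
#'
#' `sensitivity = TP/(TP+FN) * 100`, `specificity = TN/(TN+FP) * 100`,
#' `total accuracy = (TP+TN)/(TP+TN+FP+FN) * 100`. For k > 2 classes the
#' per-class sensitivity/specificity are one-vs-rest and the total accuracy
#' is the fraction of correct predictions. Metrics with an empty denominator
#' are reported as `NA` (undefined), never as 0.
#'
#' @param counts a [confusion_counts()], or a list/vector with elements
#'   `TP`, `TN`, `FP`, `FN` for a single binary machine.
#' @return object of class `metrics_report`: data.frame `per_class`
#'   (sensitivity/specificity in percent) and `total_accuracy` in percent.
#' @export
compute_metrics <- function(counts) {
  rate <- function(num, den) if (den == 0) NA_real_ else 100 * num / den
  if (!inherits(counts, "confusion_counts")) {
    cc <- as.list(counts)
    if (!all(c("TP", "TN", "FP", "FN") %in% names(cc)))
      stop_hos("counts must provide TP, TN, FP, FN")
    with(cc, {
      if (TP + TN + FP + FN == 0) stop_hos("need at least one sample")
      per <- data.frame(class = "positive",
                        sensitivity = rate(TP, TP + FN),
                        specificity = rate(TN, TN + FP))
      structure(list(per_class = per,
                     total_accuracy = rate(TP + TN, TP + TN + FP + FN)),
                class = "metrics_report")
    })
  } else {
    per <- do.call(rbind, lapply(counts$levels, function(cl) {
      cc <- counts$per_class[[cl]]
      data.frame(class = cl,
                 sensitivity = rate(cc["TP"], cc["TP"] + cc["FN"]),
                 specificity = rate(cc["TN"], cc["TN"] + cc["FP"]))
    }))
    rownames(per) <- NULL
    total <- 100 * sum(diag(counts$table)) / sum(counts$table)
    structure(list(per_class = per, total_accuracy = total),
              class = "metrics_report")
  }
}

#' @export
print.metrics_report <- function(x, digits = 1, ...) {
  cat("<metrics_report>\n")
  for (r in seq_len(nrow(x$per_class))) {
    cat(sprintf("  %-12s sensitivity %s%%  specificity %s%%\n",
                x$per_class$class[r],
                fmt_pct(x$per_class$sensitivity[r], digits),
                fmt_pct(x$per_class$specificity[r], digits)))
  }
  cat(sprintf("  total accuracy %s%%\n", fmt_pct(x$total_accuracy, digits)))
  invisible(x)
}

fmt_pct <- function(v, digits) if (is.na(v)) "NA" else formatC(v, digits = digits, format = "f")
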
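# One-vs-rest evaluation metrics for the three-class task.

#' Build a 3x3 confusion matrix
#'
#' Rows are true classes, columns predicted, both ordered AD, HC, MCI.
#'
#' @param y_true,y_pred Labels in `c("AD", "HC", "MCI")`.
#' @return Integer 3x3 matrix with dimnames.
#' @export
confusion_matrix3 <- function(y_true, y_pred) {
  tb <- table(factor(as.character(y_true), CLASS_LEVELS),
              factor(as.character(y_pred), CLASS_LEVELS))
  m <- matrix(as.numeric(tb), 3, 3,
              dimnames = list(true = CLASS_LEVELS, pred = CLASS_LEVELS))
  m
}

#' Per-class one-vs-rest metrics from a (possibly fractional) confusion matrix
#'
#' Each class in turn is the positive class and the other two are pooled as
#' negative.  Entries may be fractional (fold-averaged matrices).  A class
#' absent from the true rows yields `NA` metrics and is flagged.
#'
#' @param cm 3x3 matrix, rows true / columns predicted, order AD, HC, MCI.
#' @return Tibble with columns `class`, `sensitivity`, `specificity`,
#'   `precision`, `f1`, `support`.
#' @export
confusion_metrics <- function(cm) {
  cm <- as.matrix(cm)
  stopifnot(all(dim(cm) == c(3, 3)), all(cm >= 0))
  total <- sum(cm)
  rows <- lapply(seq_len(3), function(k) {
    TP <- cm[k, k]
    FN <- sum(cm[k, ]) - TP
    FP <- sum(cm[, k]) - TP
    TN <- total - TP - FN - FP
    support <- TP + FN
    if (support == 0) {
      return(tibble::tibble(class = CLASS_LEVELS[k], sensitivity = NA_real_,
                            specificity = NA_real_, precision = NA_real_,
                            f1 = NA_real_, support = 0))
    }
    sens <- TP / (TP + FN)
    spec <- TN / (TN + FP)
    prec <- if (TP + FP > 0) TP / (TP + FP) else NA_real_
    f1 <- if (!is.na(prec) && (prec + sens) > 0) 2 * prec * sens / (prec + sens) else NA_real_
    tibble::tibble(class = CLASS_LEVELS[k], sensitivity = sens,
                   specificity = spec, precision = prec, f1 = f1,
                   support = support)
  })
  dplyr::bind_rows(rows)
}

#' Full classification metrics report
#'
#' Accuracy, per-class one-vs-rest sensitivity/specificity/precision/F1,
#' unweighted macro averages, and (when probabilities are supplied) macro
#' one-vs-rest AUC.  Classes absent from `y_true` are excluded from macro
#' averages with a warning.
#'
#' @param y_true True labels.
#' @param y_pred Predicted labels (default: argmax of `probs`).
#' @param probs Optional `n x 3` probability matrix / tibble with columns
#'   AD, HC, MCI.
#' @return An object of class `metrics_report`.
#' @export
classification_metrics <- function(y_true, y_pred = NULL, probs = NULL) {
  if (is.null(y_pred)) {
    if (is.null(probs)) stop("supply y_pred or probs", call. = FALSE)
    P <- as.matrix(probs)
    y_pred <- CLASS_LEVELS[max.col(P)]
  }
  cm <- confusion_matrix3(y_true, y_pred)
  per_class <- confusion_metrics(cm)
  if (any(per_class$support == 0)) {
    warning("class absent from y_true: excluded from macro averages")
  }
  ok <- per_class$support > 0
  auc <- NA_real_
  if (!is.null(probs)) {
    P <- as.matrix(probs)
    colnames(P) <- colnames(P) %||% CLASS_LEVELS
    aucs <- vapply(CLASS_LEVELS[ok], function(k) {
      resp <- as.integer(as.character(y_true) == k)
      if (length(unique(resp)) < 2) return(NA_real_)
      as.numeric(pROC::auc(pROC::roc(resp, P[, k], quiet = TRUE,
                                     direction = "<", levels = c(0, 1))))
    }, numeric(1))
    auc <- mean(aucs, na.rm = TRUE)
  }
  structure(list(
    confusion = cm,
    per_class = per_class,
    accuracy = sum(diag(cm)) / sum(cm),
    macro_sensitivity = mean(per_class$sensitivity[ok]),
    macro_precision = mean(per_class$precision[ok], na.rm = TRUE),
    macro_f1 = mean(per_class$f1[ok], na.rm = TRUE),
    macro_auc = auc), class = "metrics_report")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' @export
print.metrics_report <- function(x, ...) {
  cat(sprintf("<metrics_report> accuracy %.4f | macro F1 %.4f | macro AUC %s\n",
              x$accuracy, x$macro_f1,
              if (is.na(x$macro_auc)) "-" else sprintf("%.4f", x$macro_auc)))
  print(x$per_class)
  invisible(x)
}

#' Aggregate metric reports (mean and SD)
#'
#' @param reports List of `metrics_report` objects (e.g. one per fold).
#' @return Tibble with columns `metric`, `mean`, `sd`, `n`.
#' @export
aggregate_metrics <- function(reports) {
  grab <- function(r) {
    c(accuracy = r$accuracy, macro_sensitivity = r$macro_sensitivity,
      macro_precision = r$macro_precision, macro_f1 = r$macro_f1,
      macro_auc = r$macro_auc,
      stats::setNames(r$per_class$sensitivity, paste0("sens_", r$per_class$class)),
      stats::setNames(r$per_class$specificity, paste0("spec_", r$per_class$class)))
  }
  M <- do.call(rbind, lapply(reports, grab))
  tibble::tibble(metric = colnames(M),
                 mean = unname(colMeans(M, na.rm = TRUE)),
                 sd = unname(apply(M, 2, stats::sd, na.rm = TRUE)),
                 n = nrow(M))
}
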
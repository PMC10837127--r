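#' Multiclass evaluation metrics for cell-type predictions
#'
#' Computes the five-benchmark metric panel from aligned prediction and
#' truth vectors. Cells predicted as `"unassigned"`/`"unknown"` are
#' removed (from both vectors) before any computation. Conventions:
#' \itemize{
#'   \item sensitivity — macro-averaged recall over the classes present in
#'     the truth;
#'   \item f1 — macro-averaged F1 over truth classes (precision or recall
#'     of 0 gives F1 = 0);
#'   \item mcc — the Gorodkin multiclass generalization of Matthews'
#'     correlation coefficient;
#'   \item kappa — Cohen's kappa on the full confusion matrix;
#'   \item balanced_accuracy — mean per-class recall over truth classes
#'     (identical to macro sensitivity by construction).
#' }
#'
#' @param pred Predicted labels (tibble `cell_id`,`cell_type`, or a named
#'   or plain character vector aligned with `truth`).
#' @param truth Ground-truth labels in the same form.
#' @return A one-row `MetricsRecord` tibble with the five metrics and
#'   `n_cells`, the number of cells scored after unassigned removal.
#' @export
evaluate_predictions <- function(pred, truth) {
  pt <- align_pred_truth(pred, truth)
  keep <- !(pt$pred %in% reserved_label_tokens())
  if (!any(keep)) abort("no cells left after removing unassigned predictions")
  p <- pt$pred[keep]
  t <- pt$truth[keep]
  classes <- sort(union(p, t))
  cm <- table(factor(t, classes), factor(p, classes))
  truth_classes <- sort(unique(t))
  recall <- vapply(truth_classes, function(cl) {
    tp <- cm[cl, cl]; fn <- sum(cm[cl, ]) - tp
    if (tp + fn == 0) 0 else tp / (tp + fn)
  }, numeric(1))
  f1s <- vapply(truth_classes, function(cl) {
    tp <- cm[cl, cl]
    fn <- sum(cm[cl, ]) - tp
    fp <- sum(cm[, cl]) - tp
    prec <- if (tp + fp == 0) 0 else tp / (tp + fp)
    rec <- if (tp + fn == 0) 0 else tp / (tp + fn)
    if (prec + rec == 0) 0 else 2 * prec * rec / (prec + rec)
  }, numeric(1))
  tibble(
    sensitivity = mean(recall),
    f1 = mean(f1s),
    mcc = mcc_multiclass(cm),
    kappa = cohens_kappa(cm),
    balanced_accuracy = mean(recall),
    n_cells = length(p)
  )
}

align_pred_truth <- function(pred, truth) {
  to_vec <- function(x, arg) {
    if (is.data.frame(x)) setNames(as.character(x$cell_type),
                                   as.character(x$cell_id))
    else as.character(x)
  }
  pv <- to_vec(pred); tv <- to_vec(truth)
  if (!is.null(names(pv)) && !is.null(names(tv)) &&
      all(names(pv) %in% names(tv))) {
    tv <- tv[names(pv)]
  } else if (length(pv) != length(tv)) {
    abort("pred and truth must align (shared cell ids or equal length)")
  }
  list(pred = unname(pv), truth = unname(tv))
}

# Gorodkin's multiclass MCC from a confusion matrix (truth rows,
# prediction columns): cov(X,Y) / sqrt(cov(X,X) cov(Y,Y)).
mcc_multiclass <- function(cm) {
  cm <- as.matrix(cm)
  n <- sum(cm)
  tr <- sum(diag(cm))
  row_s <- rowSums(cm)
  col_s <- colSums(cm)
  num <- tr * n - sum(row_s * col_s)
  den <- sqrt(n^2 - sum(col_s^2)) * sqrt(n^2 - sum(row_s^2))
  if (den == 0) return(0)
  num / den
}

cohens_kappa <- function(cm) {
  cm <- as.matrix(cm)
  n <- sum(cm)
  po <- sum(diag(cm)) / n
  pe <- sum(rowSums(cm) * colSums(cm)) / n^2
  if (pe == 1) return(if (po == 1) 1 else 0)
  (po - pe) / (1 - pe)
}

#' Rank-based AUROC
#'
#' Area under the ROC curve computed from the Wilcoxon rank-sum statistic;
#' used to quantify how well predictive entropy separates corrupted from
#' clean training labels.
#'
#' @param score Numeric scores (higher = more suspect).
#' @param positive Logical vector marking the true positives.
#' @return AUROC in `[0, 1]`.
#' @export
auroc <- function(score, positive) {
  pos <- score[positive]
  neg <- score[!positive]
  if (length(pos) == 0 || length(neg) == 0) {
    abort("auroc needs both positive and negative cases")
  }
  r <- rank(c(pos, neg))
  (sum(r[seq_along(pos)]) - length(pos) * (length(pos) + 1) / 2) /
    (length(pos) * length(neg))
}
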
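## Held-out performance metrics and ROC construction.

#' ROC curve as an ordered staircase with trapezoidal AUROC
#'
#' Scores are swept from high to low; tied scores step simultaneously
#' (producing diagonal segments), so the trapezoidal area equals the
#' probability-of-correct-ranking (Mann-Whitney) estimator with half credit
#' for ties.
#'
#' @param scores numeric classifier scores (higher = more case-like).
#' @param labels binary 0/1 labels (at least one of each class).
#' @return list of class `"roc_curve"`: `points` (data frame fpr/tpr from
#'   (0,0) to (1,1)), `auroc`, `thresholds`.
#' @export
roc_points <- function(scores, labels) {
  stopifnot(length(scores) == length(labels))
  labels <- as.integer(labels)
  n_pos <- sum(labels == 1L)
  n_neg <- sum(labels == 0L)
  if (n_pos == 0 || n_neg == 0)
    stopf("ROC requires at least one observation of each class")
  ord <- order(scores, decreasing = TRUE)
  s <- scores[ord]; l <- labels[ord]
  uniq <- !duplicated(s)
  # cumulative counts at each distinct threshold
  cum_tp <- cumsum(l == 1L)
  cum_fp <- cumsum(l == 0L)
  last_of_tie <- c(uniq[-1], TRUE)
  tpr <- c(0, cum_tp[last_of_tie] / n_pos)
  fpr <- c(0, cum_fp[last_of_tie] / n_neg)
  auroc <- sum(diff(fpr) * (utils::head(tpr, -1) + utils::tail(tpr, -1)) / 2)
  structure(list(points = data.frame(fpr = fpr, tpr = tpr),
                 auroc = auroc,
                 thresholds = c(Inf, s[last_of_tie])),
            class = "roc_curve")
}

#' @export
print.roc_curve <- function(x, ...) {
  cat(sprintf("ROC curve: %d points, AUROC = %.4f\n", nrow(x$points), x$auroc))
  invisible(x)
}

#' @export
plot.roc_curve <- function(x, ...) {
  plot(x$points$fpr, x$points$tpr, type = "l",
       xlab = "false positive rate", ylab = "true positive rate",
       main = sprintf("AUROC = %.3f", x$auroc), ...)
  graphics::abline(0, 1, lty = 3)
  invisible(x)
}

#' Evaluation report from scores and labels
#'
#' Confusion counts at the given probability threshold (label 1 iff score
#' `>=` threshold), accuracy, precision and recall as fractions, and the
#' trapezoidal AUROC over all thresholds. With single-class labels the AUROC
#' is `NA` and flagged.
#'
#' @param scores class-1 probabilities.
#' @param labels binary 0/1 labels.
#' @param threshold decision threshold (default 0.5).
#' @return list of class `"eval_report"`.
#' @export
eval_report <- function(scores, labels, threshold = 0.5) {
  stopifnot(length(scores) == length(labels))
  labels <- as.integer(labels)
  pred <- classify(scores, threshold)
  tp <- sum(pred == 1L & labels == 1L)
  fp <- sum(pred == 1L & labels == 0L)
  tn <- sum(pred == 0L & labels == 0L)
  fn <- sum(pred == 0L & labels == 1L)
  n <- length(labels)
  single_class <- length(unique(labels)) < 2
  roc <- if (single_class) NULL else roc_points(scores, labels)
  structure(list(
    accuracy = (tp + tn) / n,
    precision = if (tp + fp > 0) tp / (tp + fp) else NA_real_,
    recall = if (tp + fn > 0) tp / (tp + fn) else NA_real_,
    auroc = if (single_class) NA_real_ else roc$auroc,
    auroc_defined = !single_class,
    confusion = c(TP = tp, FP = fp, TN = tn, FN = fn),
    n_test = n,
    threshold = threshold,
    roc = roc
  ), class = "eval_report")
}

#' Evaluate a trained model on held-out rows
#'
#' @param model an `"mlp_model"` (or any object accepted by
#'   [predict_proba()]).
#' @param x held-out feature matrix (disjoint from training rows).
#' @param y held-out binary labels.
#' @param threshold decision threshold (default 0.5).
#' @return an [eval_report()].
#' @export
test_metrics <- function(model, x, y, threshold = 0.5) {
  eval_report(predict_proba(model, x), y, threshold)
}

#' @export
print.eval_report <- function(x, ...) {
  cat("Held-out evaluation\n")
  cat(sprintf("  accuracy : %5.1f%%   precision: %5.1f%%   recall: %5.1f%%\n",
              100 * x$accuracy, 100 * x$precision, 100 * x$recall))
  cat(sprintf("  AUROC    : %s   (n = %d, threshold %.2f)\n",
              if (x$auroc_defined) sprintf("%.3f", x$auroc) else "undefined",
              x$n_test, x$threshold))
  cat(sprintf("  confusion: TP %d  FP %d  TN %d  FN %d\n",
              x$confusion[["TP"]], x$confusion[["FP"]],
              x$confusion[["TN"]], x$confusion[["FN"]]))
  invisible(x)
}

#' Correlation between experiment accuracy and mean predictor importance
#'
#' Pearson correlation between per-experiment accuracy (percent scale) and
#' per-experiment mean group-level importance, with `r_squared = r^2`; a
#' `log(accuracy)` column is also emitted for plotting on a compressed
#' scale (the correlation itself uses accuracy).
#'
#' @param experiments data frame with columns `accuracy` (percent) and
#'   `mean_importance`; one row per experiment (at least 2, normally >= 3).
#' @return list of class `"correlation_result"`: `r`, `r_squared`, `pairs`.
#' @export
accuracy_importance_correlation <- function(experiments) {
  df <- as.data.frame(experiments)
  stopifnot(all(c("accuracy", "mean_importance") %in% names(df)))
  df <- df[is.finite(df$accuracy) & is.finite(df$mean_importance), ,
           drop = FALSE]
  if (nrow(df) < 2) stopf("need at least 2 experiments to correlate")
  if (stats::sd(df$accuracy) == 0 || stats::sd(df$mean_importance) == 0)
    stopf("zero variance in accuracy or importance; correlation undefined")
  r <- stats::cor(df$accuracy, df$mean_importance)
  df$log_accuracy <- log(df$accuracy)
  structure(list(r = r, r_squared = r^2, pairs = df,
                 n_experiments = nrow(df)),
            class = "correlation_result")
}

#' @export
print.correlation_result <- function(x, ...) {
  cat(sprintf("Accuracy-importance correlation over %d experiments\n",
              x$n_experiments))
  cat(sprintf("  r = %.4f (%.1f%%),  r^2 = %.4f (%.1f%%)\n",
              x$r, 100 * x$r, x$r_squared, 100 * x$r_squared))
  invisible(x)
}
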
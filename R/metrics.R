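# Evaluation: confusion matrices, per-class recall/precision/F1, the
# breakup/non-breakup binary aggregation, ROC/AUC with confidence interval,
# and cross-validation summaries. Undefined ratios (0/0) surface as NA,
# never as silent zeros.

#' Confusion matrix from actual and predicted labels
#'
#' @param actual,predicted Equal-length label vectors.
#' @param class_order Label universe and ordering (rows = actual,
#'   columns = predicted).
#' @return An object of class `confusion_matrix` (an integer matrix).
#' @export
confusion <- function(actual, predicted, class_order = tbd_classes()) {
  if (length(actual) != length(predicted))
    stop_invalid("actual and predicted must have equal length")
  bad <- setdiff(unique(c(actual, predicted)), class_order)
  if (length(bad)) stop_invalid("label '%s' not in class_order", bad[1])
  tab <- table(factor(actual, levels = class_order),
               factor(predicted, levels = class_order))
  m <- matrix(as.integer(tab), nrow(tab),
              dimnames = list(actual = class_order,
                              predicted = class_order))
  structure(m, class = c("confusion_matrix", class(m)))
}

#' Per-class recall, precision and F1 plus overall accuracy
#'
#' `recall = diagonal / row sum`, `precision = diagonal / column sum`,
#' `F1 = 2 P R / (P + R)`; a zero denominator yields `NA` rather than an
#' arbitrary zero. Overall accuracy is trace over total.
#'
#' @param cm A [confusion()] matrix (any K x K labeled count matrix works).
#' @return List with `table` (data frame: class, recall, precision, f1) and
#'   `accuracy`.
#' @export
per_class_metrics <- function(cm) {
  cm <- unclass(cm)
  rs <- rowSums(cm); cs <- colSums(cm); d <- diag(cm)
  recall <- ifelse(rs > 0, d / rs, NA_real_)
  precision <- ifelse(cs > 0, d / cs, NA_real_)
  f1 <- f1_score(recall, precision)
  total <- sum(cm)
  list(table = data.frame(class = rownames(cm), recall = recall,
                          precision = precision, f1 = f1,
                          row.names = NULL, stringsAsFactors = FALSE),
       accuracy = if (total > 0) sum(d) / total else NA_real_)
}

#' F1 score from recall and precision
#'
#' Harmonic mean `2 P R / (P + R)`; `NA` when either input is `NA` or both
#' are zero.
#'
#' @param recall,precision Numeric vectors (fractions).
#' @return F1 values.
#' @export
f1_score <- function(recall, precision) {
  ifelse(is.na(recall) | is.na(precision) | (recall + precision) == 0,
         NA_real_, 2 * precision * recall / (precision + recall))
}

#' Aggregate a nine-class confusion matrix into breakup vs non-breakup
#'
#' Positive = \{area, spot, line\}, negative = the six other classes. Cells
#' are reassigned wholesale: TP sums all cells with actual and predicted in
#' the positive set, and so on; the total count is preserved.
#'
#' @param cm9 Nine-class [confusion()] matrix in canonical order.
#' @return List with `matrix` (2x2: breakup/non_breakup), `accuracy`,
#'   `sensitivity`, `specificity`.
#' @export
aggregate_binary <- function(cm9) {
  cm9 <- unclass(cm9)
  stopifnot(identical(rownames(cm9), tbd_classes()))
  pos <- rownames(cm9) %in% tbd_breakup_classes()
  tp <- sum(cm9[pos, pos]); fn <- sum(cm9[pos, !pos])
  fp <- sum(cm9[!pos, pos]); tn <- sum(cm9[!pos, !pos])
  m <- matrix(c(tp, fn, fp, tn), 2, byrow = TRUE,
              dimnames = list(actual = c("breakup", "non_breakup"),
                              predicted = c("breakup", "non_breakup")))
  total <- tp + fn + fp + tn
  list(matrix = m,
       accuracy = if (total > 0) (tp + tn) / total else NA_real_,
       sensitivity = if (tp + fn > 0) tp / (tp + fn) else NA_real_,
       specificity = if (tn + fp > 0) tn / (tn + fp) else NA_real_)
}

#' ROC curve and AUC for frame scores
#'
#' AUC is the rank-sum (Mann-Whitney) statistic with midrank tie handling:
#' the probability that a random positive frame outscores a random negative
#' one, ties counted half. Curve points come from sweeping every distinct
#' score as an inclusive threshold (`decision: score >= threshold`),
#' plus the two trivial endpoints.
#'
#' @param scores Numeric per-frame scores (higher = more breakup-like).
#' @param labels Logical (or 0/1) per-frame breakup presence.
#' @return An object of class `roc_result`: `points` (data frame:
#'   threshold, fpr, tpr), `auc`, `n_pos`, `n_neg`.
#' @export
roc_auc <- function(scores, labels) {
  labels <- as.logical(labels)
  if (length(scores) != length(labels) || anyNA(scores) || anyNA(labels))
    stop_invalid("scores and labels must be complete and equal-length")
  n_pos <- sum(labels); n_neg <- sum(!labels)
  if (n_pos == 0 || n_neg == 0)
    stop_invalid("AUC undefined: need at least one positive and one negative")
  r <- rank(scores, ties.method = "average")
  auc <- (sum(r[labels]) - n_pos * (n_pos + 1) / 2) / (n_pos * n_neg)
  thr <- sort(unique(scores), decreasing = TRUE)
  pts <- data.frame(
    threshold = c(Inf, thr),
    fpr = c(0, vapply(thr, function(t) mean(scores[!labels] >= t),
                      numeric(1))),
    tpr = c(0, vapply(thr, function(t) mean(scores[labels] >= t),
                      numeric(1))))
  structure(list(points = pts, auc = auc, n_pos = n_pos, n_neg = n_neg,
                 scores = scores, labels = labels),
            class = "roc_result")
}

#' @export
print.roc_result <- function(x, ...) {
  cat(sprintf("ROC: AUC %.3f (%d positive / %d negative frames, %d thresholds)\n",
              x$auc, x$n_pos, x$n_neg, nrow(x$points)))
  invisible(x)
}

#' @export
plot.roc_result <- function(x, ...) {
  plot(x$points$fpr, x$points$tpr, type = "s", xlim = c(0, 1),
       ylim = c(0, 1), xlab = "1 - specificity", ylab = "sensitivity",
       main = sprintf("ROC (AUC = %.3f)", x$auc), ...)
  graphics::abline(0, 1, lty = 3)
  invisible(x)
}

#' 95% confidence interval for the AUC
#'
#' Default is the DeLong variance estimate with a normal-approximation
#' interval clipped to \[0, 1\]; a seeded percentile bootstrap
#' (`method = "bootstrap"`) is available as a cross-check.
#'
#' @param scores,labels As in [roc_auc()].
#' @param method `"delong"` or `"bootstrap"`.
#' @param n_boot Bootstrap resamples.
#' @param seed Bootstrap seed.
#' @return Numeric `c(low, high)`.
#' @export
auc_ci95 <- function(scores, labels, method = c("delong", "bootstrap"),
                     n_boot = 2000, seed = 1L) {
  method <- match.arg(method)
  labels <- as.logical(labels)
  if (sum(labels) == 0 || sum(!labels) == 0)
    stop_invalid("CI undefined: need both classes")
  if (method == "delong") {
    r <- pROC::roc(response = labels, predictor = as.numeric(scores),
                   levels = c(FALSE, TRUE), direction = "<", quiet = TRUE)
    ci <- as.numeric(pROC::ci.auc(r, method = "delong"))
    return(c(low = max(0, ci[1]), high = min(1, ci[3])))
  }
  pos <- which(labels); neg <- which(!labels)
  aucs <- with_local_seed(derive_seed(seed, "aucboot"), {
    vapply(seq_len(n_boot), function(i) {
      idx <- c(sample(pos, replace = TRUE), sample(neg, replace = TRUE))
      roc_auc(scores[idx], labels[idx])$auc
    }, numeric(1))
  })
  q <- stats::quantile(aucs, c(0.025, 0.975), names = FALSE)
  c(low = max(0, q[1]), high = min(1, q[2]))
}

#' Sensitivity and specificity at a fixed score threshold
#'
#' Decision rule `score >= threshold`.
#'
#' @param scores,labels As in [roc_auc()].
#' @param threshold Decision threshold.
#' @return Named numeric `c(sensitivity, specificity)`.
#' @export
operating_point <- function(scores, labels, threshold) {
  labels <- as.logical(labels)
  pred <- scores >= threshold
  sens <- if (any(labels)) mean(pred[labels]) else NA_real_
  spec <- if (any(!labels)) mean(!pred[!labels]) else NA_real_
  c(sensitivity = sens, specificity = spec)
}

#' Mean and standard deviation over cross-validation folds
#'
#' Arithmetic mean and sample (n - 1) standard deviation per metric.
#'
#' @param fold_metrics Data frame or named list of numeric vectors, one
#'   value per fold (>= 2 folds).
#' @return Data frame with `metric`, `mean`, `sd`, `n`.
#' @export
crossval_summary <- function(fold_metrics) {
  df <- as.data.frame(fold_metrics)
  if (nrow(df) < 2) stop_invalid("need at least 2 folds to summarise")
  data.frame(metric = names(df),
             mean = vapply(df, mean, numeric(1)),
             sd = vapply(df, stats::sd, numeric(1)),
             n = nrow(df), row.names = NULL, stringsAsFactors = FALSE)
}
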
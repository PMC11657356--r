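#' Multiclass confusion matrix
#'
#' `counts[i, j]` is the number of items with true grade `i-1` predicted as
#' grade `j-1` (rows = truth, columns = prediction).
#'
#' @param true,pred integer label vectors in `0..K-1`, equal length.
#' @param K number of classes (default 5).
#' @return `K x K` integer matrix of class `confusion_matrix`.
#' @export
confusion_matrix <- function(true, pred, K = 5L) {
  check_number(K, "K", lower = 2, integer = TRUE)
  stop_if(length(true) != length(pred), "true and pred lengths differ")
  stop_if(length(true) > 0 &&
            (any(true < 0 | true >= K) || any(pred < 0 | pred >= K) ||
               any(true != round(true)) || any(pred != round(pred))),
          sprintf("labels must be integers in 0..%d", K - 1))
  cm <- matrix(0L, K, K, dimnames = list(true = 0:(K - 1), pred = 0:(K - 1)))
  if (length(true) > 0) {
    tab <- table(factor(true, levels = 0:(K - 1)),
                 factor(pred, levels = 0:(K - 1)))
    cm[] <- as.integer(tab)
  }
  structure(cm, class = c("confusion_matrix", "matrix", "array"))
}

#' One-vs-rest binary counts for one class
#'
#' Reduces a multiclass confusion matrix to TP/FP/FN/TN for class `k`
#' treated as positive.
#'
#' @param cm a [confusion_matrix()].
#' @param k 0-based class index.
#' @return list with integer fields `TP`, `FP`, `FN`, `TN`.
#' @export
one_vs_rest <- function(cm, k) {
  K <- nrow(cm)
  stop_if(k < 0 || k >= K, "class index out of range")
  i <- k + 1L
  tp <- cm[i, i]
  fp <- sum(cm[, i]) - tp
  fn <- sum(cm[i, ]) - tp
  tn <- sum(cm) - tp - fp - fn
  list(TP = as.integer(tp), FP = as.integer(fp), FN = as.integer(fn),
       TN = as.integer(tn))
}

#' Binary classification metrics
#'
#' `acc = (TP+TN)/(TP+FP+TN+FN)`, `pre = TP/(TP+FP)`, `rec = TP/(TP+FN)`,
#' `f1 = 2*p*r/(p+r)`.  Degenerate denominators for precision/recall return
#' 0 with a `"degenerate"` attribute rather than NaN, keeping macro averages
#' defined for pathological predictors; a zero total for accuracy is an
#' error.
#'
#' @param c list with fields `TP`, `FP`, `FN`, `TN` (see [one_vs_rest()]).
#' @return a number in `[0, 1]`.
#' @export
acc <- function(c) {
  total <- c$TP + c$FP + c$TN + c$FN
  stop_if(total == 0, "accuracy undefined on zero items")
  (c$TP + c$TN) / total
}

#' @rdname acc
#' @export
pre <- function(c) {
  den <- c$TP + c$FP
  if (den == 0) return(structure(0, degenerate = TRUE))
  c$TP / den
}

#' @rdname acc
#' @export
rec <- function(c) {
  den <- c$TP + c$FN
  if (den == 0) return(structure(0, degenerate = TRUE))
  c$TP / den
}

#' @rdname acc
#' @param p,r precision and recall in `[0, 1]`.
#' @export
f1 <- function(p, r) {
  p <- as.numeric(p); r <- as.numeric(r)
  stop_if(p < 0 || p > 1 || r < 0 || r > 1, "p and r must lie in [0, 1]")
  if (p + r == 0) return(0)
  2 * p * r / (p + r)
}

#' ROC curve and AUC for one class
#'
#' Sweeps thresholds over the distinct scores (predicting positive at or
#' above each threshold), yielding an (FPR, TPR) staircase from (0,0) to
#' (1,1); AUC is its trapezoidal integral, which equals the
#' probability-of-correct-ranking statistic with half credit for ties.
#'
#' @param scores numeric score (e.g. class-k probability) per item.
#' @param labels binary 0/1 labels (1 = positive); both classes must occur.
#' @return object of class `roc_curve`: data.frame `points` with columns
#'   `fpr`, `tpr`, and scalar `auc`.
#' @export
roc_auc <- function(scores, labels) {
  stop_if(length(scores) != length(labels), "scores and labels lengths differ")
  stop_if(!all(labels %in% c(0, 1)), "labels must be 0/1")
  np <- sum(labels == 1); nn <- sum(labels == 0)
  stop_if(np == 0 || nn == 0,
          "ROC undefined: need at least one positive and one negative")
  ord <- order(scores, decreasing = TRUE)
  s <- scores[ord]; l <- labels[ord]
  # collapse tied scores into single threshold steps
  last_of_tie <- c(s[-1] != s[-length(s)], TRUE)
  cum_tp <- cumsum(l)[last_of_tie]
  cum_fp <- cumsum(1 - l)[last_of_tie]
  tpr <- c(0, cum_tp / np)
  fpr <- c(0, cum_fp / nn)
  auc <- sum(diff(fpr) * (tpr[-1] + tpr[-length(tpr)]) / 2)
  structure(list(points = data.frame(fpr = fpr, tpr = tpr), auc = auc),
            class = "roc_curve")
}

#' @export
print.roc_curve <- function(x, ...) {
  cat(sprintf("<roc_curve> %d points, AUC = %.4f\n", nrow(x$points), x$auc))
  invisible(x)
}

#' Full evaluation report
#'
#' Per-class one-vs-rest ACC/PRE/REC/F1 and AUC, their macro (unweighted)
#' means, micro-average AUC (all one-vs-rest problems pooled), and the
#' overall multiclass accuracy (confusion-matrix trace over total) - the
#' latter reported alongside, explicitly distinct from macro one-vs-rest ACC.
#'
#' @param cm a [confusion_matrix()].
#' @param score_matrix `(n, K)` matrix of class scores (rows = items),
#'   or `NULL` to skip ROC/AUC.
#' @param labels integer true labels `0..K-1` matching `score_matrix` rows.
#' @return object of class `metrics_report` with fields `per_class`
#'   (data.frame), `macro` (named list), `overall_accuracy`, `micro_auc`,
#'   `confusion`, `roc` (list of [roc_auc()] curves or NULL).
#' @export
metrics_report <- function(cm, score_matrix = NULL, labels = NULL) {
  K <- nrow(cm)
  per <- lapply(0:(K - 1), function(k) {
    c_ <- one_vs_rest(cm, k)
    p <- pre(c_); r <- rec(c_)
    list(class = k, ACC = acc(c_), PRE = as.numeric(p), REC = as.numeric(r),
         F1 = f1(p, r),
         degenerate = isTRUE(attr(p, "degenerate")) || isTRUE(attr(r, "degenerate")))
  })
  per_df <- do.call(rbind, lapply(per, as.data.frame))
  roc <- NULL
  if (!is.null(score_matrix)) {
    stop_if(is.null(labels) || nrow(score_matrix) != length(labels),
            "labels must match score_matrix rows")
    stop_if(ncol(score_matrix) != K, "score_matrix must have K columns")
    roc <- lapply(0:(K - 1), function(k)
      roc_auc(score_matrix[, k + 1L], as.integer(labels == k)))
    per_df$AUC <- vapply(roc, `[[`, numeric(1), "auc")
    pooled <- roc_auc(as.vector(score_matrix),
                      as.vector(vapply(0:(K - 1), function(k)
                        as.integer(labels == k), integer(length(labels)))))
    micro_auc <- pooled$auc
  } else micro_auc <- NA_real_
  macro <- list(ACC = mean(per_df$ACC), PRE = mean(per_df$PRE),
                REC = mean(per_df$REC), F1 = mean(per_df$F1))
  if (!is.null(roc)) macro$AUC <- mean(per_df$AUC)
  structure(list(per_class = per_df, macro = macro,
                 overall_accuracy = sum(diag(cm)) / max(1, sum(cm)),
                 micro_auc = micro_auc, confusion = cm, roc = roc),
            class = "metrics_report")
}

#' @export
print.metrics_report <- function(x, ...) {
  cat("<metrics_report>\nper-class (one-vs-rest):\n")
  print(x$per_class, row.names = FALSE, digits = 4)
  cat(sprintf("macro: ACC %.4f  PRE %.4f  REC %.4f  F1 %.4f%s\n",
              x$macro$ACC, x$macro$PRE, x$macro$REC, x$macro$F1,
              if (!is.null(x$macro$AUC)) sprintf("  AUC %.4f", x$macro$AUC) else ""))
  cat(sprintf("overall multiclass accuracy (trace/total): %.4f\n",
              x$overall_accuracy))
  invisible(x)
}

#' Evaluate a model on a dataset
#'
#' @param model a `dms_model`.
#' @param ds an `image_dataset` with images matching the model input size.
#' @return a [metrics_report()].
#' @export
evaluate_model <- function(model, ds) {
  stop_if(!inherits(ds, "image_dataset"), "ds must be an image_dataset")
  labels <- dataset_labels(ds)
  x <- as_batch_array(ds)
  n <- dim(x)[4]
  probs <- matrix(0, n, model$cfg$num_classes)
  for (s in seq.int(1L, n, 64L)) {
    e <- min(s + 63L, n)
    probs[s:e, ] <- dms_forward_full(model, x[, , , s:e, drop = FALSE],
                                     training = FALSE)$probs
  }
  pred <- max.col(probs, ties.method = "first") - 1L
  cm <- confusion_matrix(labels, pred, K = model$cfg$num_classes)
  metrics_report(cm, probs, labels)
}
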
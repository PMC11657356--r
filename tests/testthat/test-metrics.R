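test_that("confusion_matrix tallies counts by (true, pred) cell", {
  cm <- confusion_matrix(0:4, 0:4)
  expect_equal(unclass(cm), diag(5), ignore_attr = TRUE)
  expect_equal(sum(diag(cm)), 5)

  cm <- confusion_matrix(c(0, 1, 2, 2), c(0, 2, 2, 2))
  expect_equal(cm[2, 3], 1L)
  expect_equal(cm[3, 3], 2L)
  expect_equal(cm[1, 1], 1L)
  expect_equal(sum(cm), 4)

  expect_equal(sum(confusion_matrix(integer(0), integer(0))), 0)
  expect_error(confusion_matrix(c(0, 5), c(0, 0)), "labels")
  expect_error(confusion_matrix(0:2, 0:1), "lengths")
})

test_that("one_vs_rest reduction matches direct tallies and partitions totals", {
  cm <- confusion_matrix(c(0, 1, 2, 2), c(0, 2, 2, 2))
  c2 <- one_vs_rest(cm, 2)
  expect_equal(c2, list(TP = 2L, FP = 1L, FN = 0L, TN = 1L))
  for (k in 0:4) {
    ck <- one_vs_rest(cm, k)
    expect_equal(ck$TP + ck$FP + ck$FN + ck$TN, sum(cm))
  }
  ident <- confusion_matrix(0:4, 0:4)
  for (k in 0:4) {
    ck <- one_vs_rest(ident, k)
    expect_equal(ck$FP, 0L)
    expect_equal(ck$FN, 0L)
  }
})

test_that("binary metrics follow their formulas with degenerate conventions", {
  expect_equal(acc(list(TP = 1, TN = 1, FP = 0, FN = 0)), 1)
  expect_equal(acc(list(TP = 2, FP = 1, FN = 0, TN = 1)), 0.75)
  expect_equal(acc(list(TP = 0, TN = 0, FP = 2, FN = 1)), 0)
  expect_error(acc(list(TP = 0, TN = 0, FP = 0, FN = 0)), "undefined")

  expect_equal(as.numeric(pre(list(TP = 3, FP = 1))), 0.75)
  expect_equal(as.numeric(pre(list(TP = 2, FP = 0))), 1)
  p0 <- pre(list(TP = 0, FP = 0))
  expect_equal(as.numeric(p0), 0)
  expect_true(isTRUE(attr(p0, "degenerate")))

  expect_equal(as.numeric(rec(list(TP = 2, FN = 0))), 1)
  expect_equal(as.numeric(rec(list(TP = 1, FN = 3))), 0.25)
  r0 <- rec(list(TP = 0, FN = 0))
  expect_equal(as.numeric(r0), 0)
  expect_true(isTRUE(attr(r0, "degenerate")))

  expect_equal(f1(1, 1), 1)
  expect_equal(f1(0.5, 1), 2 / 3)
  expect_equal(f1(0, 0.8), 0)
  expect_equal(f1(0, 0), 0)
})

test_that("roc_auc handles separation, partial ranking and ties", {
  r <- roc_auc(c(0.9, 0.8, 0.3, 0.1), c(1, 1, 0, 0))
  expect_equal(r$auc, 1)
  # 3 of 4 (pos, neg) pairs correctly ranked
  r <- roc_auc(c(0.9, 0.4, 0.6, 0.1), c(1, 1, 0, 0))
  expect_equal(r$auc, 0.75)
  # ties get half credit
  r <- roc_auc(c(0.5, 0.5), c(1, 0))
  expect_equal(r$auc, 0.5)
  expect_error(roc_auc(c(0.1, 0.2), c(1, 1)), "positive and .* negative")
})

test_that("ROC curves are monotone staircases from (0,0) to (1,1)", {
  set.seed(42)
  for (i in 1:20) {
    n <- sample(5:80, 1)
    labels <- c(0, 1, sample(0:1, n - 2, TRUE))
    scores <- round(runif(n), sample(c(1, 2, 6), 1))  # induce ties sometimes
    r <- roc_auc(scores, labels)
    pts <- r$points
    expect_equal(pts$fpr[1], 0)
    expect_equal(pts$tpr[1], 0)
    expect_equal(pts$fpr[nrow(pts)], 1)
    expect_equal(pts$tpr[nrow(pts)], 1)
    expect_true(all(diff(pts$fpr) >= 0))
    expect_true(all(diff(pts$tpr) >= 0))
    expect_equal(r$auc, oracle_auc(scores, labels), tolerance = 1e-12)
  }
})

test_that("AUC is invariant under strictly monotone score transforms", {
  set.seed(7)
  scores <- runif(60)
  labels <- sample(0:1, 60, TRUE, prob = c(0.6, 0.4))
  base <- roc_auc(scores, labels)$auc
  expect_equal(roc_auc(2 * scores + 3, labels)$auc, base, tolerance = 1e-12)
  expect_equal(roc_auc(exp(scores), labels)$auc, base, tolerance = 1e-12)
  expect_equal(roc_auc(qlogis(scores / 2 + 0.25), labels)$auc, base,
               tolerance = 1e-12)
})

test_that("shuffled labels give chance-level AUC", {
  set.seed(123)
  scores <- runif(4000)
  labels <- sample(0:1, 4000, TRUE)
  expect_equal(roc_auc(scores, labels)$auc, 0.5, tolerance = 0.05)
})

test_that("metrics_report aggregates per-class and macro values correctly", {
  # perfect predictor
  cm <- confusion_matrix(rep(0:4, 4), rep(0:4, 4))
  scores <- diag(5)[rep(1:5, 4), ] * 0.9 + 0.02
  rep_ <- metrics_report(cm, scores, rep(0:4, 4))
  expect_equal(rep_$macro$ACC, 1)
  expect_equal(rep_$macro$F1, 1)
  expect_equal(rep_$macro$AUC, 1)
  expect_equal(rep_$overall_accuracy, 1)

  # single-class predictor on a balanced set: macro REC = 1/5
  true <- rep(0:4, each = 6)
  pred <- rep(0L, 30)
  rep2 <- metrics_report(confusion_matrix(true, pred))
  expect_equal(rep2$macro$REC, 0.2)
  expect_equal(rep2$overall_accuracy, 0.2)
  # macro equals the mean of the per-class columns, definitionally
  expect_equal(rep2$macro$ACC, mean(rep2$per_class$ACC))
  expect_equal(rep2$macro$F1, mean(rep2$per_class$F1))
  # macro one-vs-rest ACC differs from overall multiclass accuracy here
  expect_gt(rep2$macro$ACC, rep2$overall_accuracy)
})

test_that("implementation agrees with the brute-force oracle on random triples", {
  # scaled-down version of the acceptance sweep for fast feedback
  set.seed(99)
  for (rep_i in 1:50) {
    n <- sample(2:60, 1)
    true <- sample(0:4, n, TRUE)
    pred <- sample(0:4, n, TRUE)
    cm <- confusion_matrix(true, pred)
    expect_identical(unclass(unname(cm)), oracle_confusion(true, pred, 5L))
    k <- sample(0:4, 1)
    bc <- one_vs_rest(cm, k)
    oc <- oracle_binary_counts(true, pred, k)
    expect_equal(bc$TP, oc$TP)
    expect_equal(bc$FP, oc$FP)
    expect_equal(bc$FN, oc$FN)
    expect_equal(bc$TN, oc$TN)
  }
})
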
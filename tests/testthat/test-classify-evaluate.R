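test_that("prediction probabilities are tree-vote fractions that sum to one", {
  sub <- fix_mat[, 1:120]
  m <- gv_fit(sub, fix_orders, hyper = list(num_trees = 100),
              level = "order", seed = 2)
  pred <- predict(m, sub)
  prob <- attr(pred, "prob")
  expect_equal(unname(rowSums(prob)), rep(1, nrow(prob)), tolerance = 1e-9)
  # predicted class is the argmax of the probability vector
  expect_identical(pred$predicted_class,
                   colnames(prob)[max.col(prob, ties.method = "first")])
  expect_identical(pred$low_confidence, pred$probability < 0.5)
  # feature mismatch is an explicit error naming the offender
  expect_error(predict(m, sub[, -2]), "missing")
})

test_that("an all-zero GVOG row still yields a prediction", {
  sub <- fix_mat[, 1:120]
  m <- gv_fit(sub, fix_orders, hyper = list(num_trees = 100),
              level = "order", seed = 3)
  empty_row <- sub[1, , drop = FALSE]
  empty_row[, -1] <- 0
  empty_row[, 1] <- 0.45
  rownames(empty_row) <- "no_hits"
  pred <- predict(m, empty_row)
  expect_equal(nrow(pred), 1)
  expect_true(pred$probability <= 1 && pred$probability >= 0)
})

test_that("rare families are aggregated into order bins", {
  labels <- data.frame(
    genome_id = sprintf("g%02d", 1:66),
    order = c(rep("Imitervirales", 34), rep("Pandoravirales", 32)),
    family = c(rep("IM_01", 31), rep("IM_99", 3), rep("PV_01", 32)))
  agg <- aggregate_rare_families(labels, min_members = 30)
  # a family with 31 members keeps its name
  expect_identical(unique(agg$family_class[agg$family == "IM_01"]), "IM_01")
  # 3 members in Imitervirales collapse to the IM bin
  expect_identical(unique(agg$family_class[agg$family == "IM_99"]), "IM")
  # min_members = 0 is the identity
  agg0 <- aggregate_rare_families(labels, min_members = 0)
  expect_identical(agg0$family_class, labels$family)
})

test_that("precision/recall/F1 reproduce the published classification-report rows", {
  # order-level report: precision 1, recall 0.92 -> F1 0.96 (support 63)
  chito <- precision_recall_f1(tp = 58, fp = 0, fn = 5)
  expect_equal(round(chito$precision, 2), 1.00)
  expect_equal(round(chito$recall, 2), 0.92)
  expect_equal(round(chito$f1, 2), 0.96)
  # precision 0.98, recall 1 -> F1 0.99 (support 463)
  imiter <- precision_recall_f1(tp = 463, fp = 9, fn = 0)
  expect_equal(round(imiter$precision, 2), 0.98)
  expect_equal(round(imiter$recall, 2), 1.00)
  expect_equal(round(imiter$f1, 2), 0.99)
  # zero-denominator convention: a class never predicted and never hit
  zero <- precision_recall_f1(tp = 0, fp = 0, fn = 2)
  expect_equal(unlist(zero), c(precision = 0, recall = 0, f1 = 0))
  expect_error(precision_recall_f1(-1, 0, 0), "non-negative")
})

test_that("evaluation agrees with a brute-force confusion-matrix oracle", {
  set.seed(31)
  for (n in c(50, 300, 1000)) {
    classes <- LETTERS[1:4]
    truth <- stats::setNames(sample(classes, n, replace = TRUE),
                             sprintf("g%04d", 1:n))
    pred <- stats::setNames(sample(classes, n, replace = TRUE), names(truth))
    ev <- gv_evaluate(pred, truth)
    cm <- oracle_confusion(truth, pred, sort(classes))
    expect_identical(unname(ev$confusion), unname(cm))
    expect_equal(ev$accuracy, sum(diag(cm)) / n)
    # rows of the normalized matrix sum to 1 for classes with support
    sup <- rowSums(cm)
    expect_equal(unname(rowSums(ev$confusion_normalized)[sup > 0]),
                 rep(1, sum(sup > 0)))
    # per-class F1 lies between min and max of precision and recall
    with(ev$per_class, {
      expect_true(all(f1 >= pmin(precision, recall) - 1e-12))
      expect_true(all(f1 <= pmax(precision, recall) + 1e-12))
    })
    # micro view: trace/n equals accuracy by construction, and the
    # support-weighted recall equals the accuracy (standard identity)
    expect_equal(ev$weighted[["recall"]], ev$accuracy)
  }
})

test_that("misclassification percentages reproduce the published error rates", {
  make_eval <- function(n_err, n) {
    truth <- stats::setNames(rep("A", n), sprintf("g%04d", 1:n))
    pred <- truth
    pred[seq_len(n_err)] <- "B"
    gv_evaluate(pred, truth)
  }
  expect_equal(round(misclassification_pct(make_eval(11, 823)), 1), 1.3)
  expect_equal(round(misclassification_pct(make_eval(34, 823)), 1), 4.1)
  # all correct: accuracy 1, identity confusion matrix
  ev <- gv_evaluate(stats::setNames(c("A", "B"), c("g1", "g2")),
                    stats::setNames(c("A", "B"), c("g1", "g2")))
  expect_equal(ev$accuracy, 1)
  expect_equal(unname(ev$confusion), diag(2), ignore_attr = TRUE)

  expect_error(
    gv_evaluate(stats::setNames("A", "gX"), stats::setNames("A", "gY")),
    "without a truth label")
})

test_that("order/family disagreement is reported, not enforced", {
  po <- structure(data.frame(genome_id = c("g1", "g2"),
                             predicted_class = c("Imitervirales", "Pandoravirales"),
                             stringsAsFactors = FALSE),
                  class = c("gv_prediction", "data.frame"))
  pf <- structure(data.frame(genome_id = c("g1", "g2"),
                             predicted_class = c("IM_01", "IM_02"),
                             stringsAsFactors = FALSE),
                  class = c("gv_prediction", "data.frame"))
  dis <- level_disagreement(po, pf)
  expect_identical(unname(dis), c(FALSE, TRUE))
})
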
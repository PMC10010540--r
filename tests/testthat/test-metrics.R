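# Confusion matrices, per-class metrics, binary aggregation, ROC/AUC.

test_that("confusion matrices count label pairs exactly", {
  cls3 <- c("area", "uniform", "particle")
  perfect <- confusion(cls3, cls3, cls3)
  expect_identical(unname(diag(unclass(perfect))), rep(1L, 3))
  expect_identical(sum(unclass(perfect)) - sum(diag(unclass(perfect))), 0L)

  empty <- confusion(character(0), character(0), cls3)
  expect_true(all(unclass(empty) == 0))

  set.seed(20)
  act <- sample(cls3, 60, replace = TRUE)
  pred <- sample(cls3, 60, replace = TRUE)
  cm <- confusion(act, pred, cls3)
  for (i in 1:3) for (j in 1:3) {
    brute <- 0
    for (k in 1:60)
      if (act[k] == cls3[i] && pred[k] == cls3[j]) brute <- brute + 1
    expect_identical(unclass(cm)[i, j], as.integer(brute))
  }
  expect_identical(unname(rowSums(unclass(cm))),
                   as.numeric(table(factor(act, cls3))))
  expect_error(confusion("area", "smudge", cls3), "smudge")
  expect_error(confusion(c("area", "area"), "area", cls3), "equal length")
})

test_that("per-class F1 reproduces the harmonic-mean identity and handles 0/0", {
  expect_equal(f1_score(1, 1), 1)
  expect_true(is.na(f1_score(0, 0)))
  # F1 <= arithmetic and geometric means of precision and recall
  set.seed(21)
  for (i in 1:50) {
    p <- runif(1, 0.01, 1); r <- runif(1, 0.01, 1)
    f <- f1_score(r, p)
    expect_lte(f, (p + r) / 2 + 1e-12)
    expect_lte(f, sqrt(p * r) + 1e-12)
  }
  # undefined rows never crash and surface as NA
  cm <- confusion(c("area", "area"), c("spot", "spot"),
                  c("area", "spot", "line"))
  pm <- per_class_metrics(cm)
  expect_identical(pm$table$recall[1], 0)
  expect_true(is.na(pm$table$precision[1]))     # no predictions of 'area'
  expect_true(is.na(pm$table$recall[3]))        # no actual 'line'
  expect_identical(pm$accuracy, 0)
  # metrics table is internally consistent with f1_score
  set.seed(22)
  act <- sample(tbd_classes(), 300, replace = TRUE)
  prd <- sample(tbd_classes(), 300, replace = TRUE)
  pm2 <- per_class_metrics(confusion(act, prd))
  expect_equal(pm2$table$f1,
               f1_score(pm2$table$recall, pm2$table$precision))
})

test_that("binary aggregation reclassifies all 81 cells correctly", {
  # diagonal matrix: no cross-group errors
  d <- confusion(tbd_classes(), tbd_classes())
  agg <- aggregate_binary(d)
  expect_identical(agg$sensitivity, 1)
  expect_identical(agg$specificity, 1)
  expect_identical(sum(agg$matrix), 9L)

  # all mass in one breakup-actual / non-breakup-predicted cell
  cm0 <- confusion(rep("spot", 5), rep("uniform", 5))
  expect_identical(aggregate_binary(cm0)$sensitivity, 0)

  set.seed(23)
  m <- matrix(sample(0:20, 81, replace = TRUE), 9,
              dimnames = list(actual = tbd_classes(),
                              predicted = tbd_classes()))
  agg2 <- aggregate_binary(structure(m, class = c("confusion_matrix",
                                                  "matrix")))
  pos <- tbd_breakup_classes()
  tp <- fp <- fn <- tn <- 0
  for (i in tbd_classes()) for (j in tbd_classes()) {
    v <- m[i, j]
    if (i %in% pos && j %in% pos) tp <- tp + v
    else if (i %in% pos) fn <- fn + v
    else if (j %in% pos) fp <- fp + v
    else tn <- tn + v
  }
  expect_equal(unname(agg2$matrix["breakup", "breakup"]), tp)
  expect_equal(unname(agg2$matrix["breakup", "non_breakup"]), fn)
  expect_equal(unname(agg2$matrix["non_breakup", "breakup"]), fp)
  expect_identical(sum(agg2$matrix), sum(m))
  expect_equal(agg2$sensitivity, tp / (tp + fn))
  expect_equal(agg2$specificity, tn / (tn + fp))
})

test_that("AUC equals the pairwise Mann-Whitney oracle and is rank-invariant", {
  expect_identical(roc_auc(c(5, 6, 1, 2), c(TRUE, TRUE, FALSE, FALSE))$auc, 1)
  expect_identical(roc_auc(rep(3, 6), rep(c(TRUE, FALSE), 3))$auc, 0.5)
  expect_error(roc_auc(1:4, rep(TRUE, 4)), "undefined")

  set.seed(24)
  for (i in 1:100) {
    n <- sample(10:200, 1)
    scores <- sample(0:49, n, replace = TRUE)
    labels <- runif(n) < runif(1, 0.2, 0.8)
    if (!any(labels) || all(labels)) next
    r <- roc_auc(scores, labels)
    expect_equal(r$auc, auc_pairwise_oracle(scores, labels),
                 tolerance = 1e-12)
    # invariance under a strictly increasing transform
    expect_equal(roc_auc(exp(scores / 10), labels)$auc, r$auc,
                 tolerance = 1e-12)
    # cross-check against the reference ROC implementation
    if (i <= 5) {
      pr <- pROC::roc(response = labels, predictor = as.numeric(scores),
                      levels = c(FALSE, TRUE), direction = "<",
                      quiet = TRUE)
      expect_equal(r$auc, as.numeric(pROC::auc(pr)), tolerance = 1e-12)
    }
  }
})

test_that("ROC points trace the threshold sweep consistently with operating points", {
  set.seed(25)
  scores <- sample(0:20, 80, replace = TRUE)
  labels <- runif(80) < 0.4
  r <- roc_auc(scores, labels)
  expect_true(all(diff(r$points$fpr) >= 0))
  expect_true(all(diff(r$points$tpr) >= 0))
  expect_identical(r$points$fpr[1], 0)
  expect_identical(r$points$tpr[1], 0)
  expect_identical(utils::tail(r$points$fpr, 1), 1)

  for (k in seq_len(nrow(r$points))) {
    thr <- r$points$threshold[k]
    if (!is.finite(thr)) next
    op <- operating_point(scores, labels, thr)
    expect_equal(unname(op["sensitivity"]), r$points$tpr[k])
    expect_equal(1 - unname(op["specificity"]), r$points$fpr[k])
  }
  expect_identical(unname(operating_point(scores, labels, -1)),
                   c(1, 0))
  expect_identical(unname(operating_point(scores, labels, 99)),
                   c(0, 1))
  # monotone threshold family: sensitivity non-increasing, specificity
  # non-decreasing in the threshold
  ops <- vapply(0:21, function(t) operating_point(scores, labels, t),
                numeric(2))
  expect_true(all(diff(ops["sensitivity", ]) <= 1e-12))
  expect_true(all(diff(ops["specificity", ]) >= -1e-12))
})

test_that("AUC confidence intervals behave and the two methods agree", {
  set.seed(26)
  scores <- c(rnorm(60, 1.2), rnorm(60))
  labels <- rep(c(TRUE, FALSE), each = 60)
  dl <- auc_ci95(scores, labels)
  expect_lte(dl["low"], roc_auc(scores, labels)$auc)
  expect_gte(dl["high"], roc_auc(scores, labels)$auc)

  # perfectly separated: upper bound clips to 1
  sep <- suppressWarnings(auc_ci95(c(5, 6, 7, 1, 2, 3),
                                   c(TRUE, TRUE, TRUE, FALSE, FALSE, FALSE)))
  expect_identical(unname(sep["high"]), 1)

  # doubling the data narrows the interval
  dl2 <- auc_ci95(rep(scores, 2), rep(labels, 2))
  expect_lt(diff(dl2), diff(dl))

  # DeLong and seeded bootstrap agree on a fixed 40-frame synthetic set
  set.seed(11)
  sc40 <- sample(0:49, 40, replace = TRUE) +
    ifelse(rep(c(TRUE, FALSE), each = 20), 8, 0)
  lb40 <- rep(c(TRUE, FALSE), each = 20)
  d <- auc_ci95(sc40, lb40, method = "delong")
  b <- auc_ci95(sc40, lb40, method = "bootstrap", seed = 11)
  expect_lt(max(abs(d - b)), 0.04)
  expect_error(auc_ci95(1:3, c(TRUE, TRUE, TRUE)), "both classes")
})

test_that("fold summaries report mean and sample standard deviation", {
  same <- data.frame(accuracy = rep(0.8, 6))
  s <- crossval_summary(same)
  expect_identical(s$sd, 0)
  two <- data.frame(accuracy = c(80, 82))
  s2 <- crossval_summary(two)
  expect_identical(s2$mean, 81)
  expect_equal(s2$sd, sqrt(2), tolerance = 1e-12)
  set.seed(27)
  accs <- data.frame(a = runif(6), b = runif(6))
  s3 <- crossval_summary(accs)
  # independent two-pass computation
  mu <- sum(accs$a) / 6
  expect_equal(s3$mean[1], mu, tolerance = 1e-12)
  expect_equal(s3$sd[1], sqrt(sum((accs$a - mu)^2) / 5), tolerance = 1e-12)
  expect_error(crossval_summary(data.frame(a = 1)), "2 folds")
})
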
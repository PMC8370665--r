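test_that("the stratified 80/20 split keeps per-class proportions", {
  labels <- rep(c("normal", "mild_dme"), each = 100)
  sp <- split_data(labels, 0.8, seed = 4L)
  expect_length(sp$train, 160L)
  expect_length(sp$test, 40L)
  expect_equal(unname(table(labels[sp$train])), c(80L, 80L),
               ignore_attr = TRUE)
  expect_equal(unname(table(labels[sp$test])), c(20L, 20L),
               ignore_attr = TRUE)
  expect_length(intersect(sp$train, sp$test), 0L)

  sp10 <- split_data(rep("a", 10), 0.8, seed = 1L)
  expect_length(sp10$train, 8L)
  expect_length(sp10$test, 2L)

  expect_identical(split_data(labels, 0.8, seed = 9L),
                   split_data(labels, 0.8, seed = 9L))
  expect_error(split_data(c("a", "a", "b"), 0.8), "at least 2")
})

test_that("k-fold assignments tile the data in near-equal stratified folds", {
  labels <- rep(c("normal", "mild_dme"), each = 100)
  f <- kfold(labels, 10L, seed = 2L)
  expect_length(f, 200L)
  expect_equal(unname(table(f)), rep(20L, 10L), ignore_attr = TRUE)
  for (k in 1:10)
    expect_equal(sum(labels[f == k] == "normal"), 10L)

  # k = n is leave-one-out
  loo <- kfold(rep("a", 7), 7L, seed = 1L)
  expect_setequal(loo, 1:7)

  # disjoint union: every index in exactly one fold
  f2 <- kfold(rep(c("x", "y", "z"), times = c(9, 7, 5)), 4L, seed = 3L)
  expect_length(f2, 21L)
  expect_true(all(f2 %in% 1:4))
  expect_lte(diff(range(table(f2))), 1)

  expect_error(kfold(rep("a", 3), 10L), "n < k")
})

test_that("undersampling balances classes reproducibly", {
  labels <- rep(c("a", "b"), times = c(120, 300))
  keep <- undersample(labels, 100L, seed = 5L)
  expect_equal(unname(table(labels[keep])), c(100L, 100L), ignore_attr = TRUE)
  expect_identical(keep, undersample(labels, 100L, seed = 5L))

  # a class already at the target is kept whole
  keep2 <- undersample(labels, 120L, seed = 1L)
  expect_identical(which(labels == "a"), keep2[labels[keep2] == "a"])

  expect_error(undersample(labels, 200L), "insufficient class size")
})

test_that("confusion counts match a direct tally", {
  cm <- confusion(rep(c(1, 0), each = 10), rep(c(1, 0), each = 10))
  expect_equal(unlist(cm[c("TP", "TN", "FP", "FN")]), c(TP = 10, TN = 10, FP = 0, FN = 0))

  cm2 <- confusion(c(1, 1, 0, 0), c(1, 1, 1, 1))
  expect_equal(cm2$FN, 0)
  expect_equal(cm2$TN, 0)

  set.seed(30)
  t50 <- sample(0:1, 50, TRUE); p50 <- sample(0:1, 50, TRUE)
  cm3 <- confusion(t50, p50)
  expect_equal(cm3$TP, sum(t50 & p50))
  expect_equal(cm3$TN, sum(!t50 & !p50))
  expect_equal(cm3$FP, sum(!t50 & p50))
  expect_equal(cm3$FN, sum(t50 & !p50))
  expect_equal(cm3$TP + cm3$TN + cm3$FP + cm3$FN, 50)

  expect_error(confusion(0:1, c(0, 1, 1)), "length")
})

test_that("metrics follow their definitions and flag undefined cases", {
  cm <- structure(list(TP = 9, FN = 1, TN = 8, FP = 2),
                  class = "confusion_matrix")
  m <- classification_metrics(cm)
  expect_equal(m$sensitivity, 0.9)
  expect_equal(m$specificity, 0.8)
  expect_equal(m$accuracy, 0.85)
  expect_equal(m$precision, 9 / 11)

  perfect <- classification_metrics(confusion(rep(c(1, 0), 5), rep(c(1, 0), 5)))
  expect_true(all(unlist(perfect) == 1))

  even <- structure(list(TP = 25, FN = 25, TN = 25, FP = 25),
                    class = "confusion_matrix")
  expect_true(all(unlist(classification_metrics(even)) == 0.5))

  nopos <- classification_metrics(confusion(rep(0, 4), rep(0, 4)))
  expect_true(is.na(nopos$sensitivity))
  expect_true("sensitivity" %in% attr(nopos, "undefined"))
  expect_true("precision" %in% attr(nopos, "undefined"))
})

test_that("accuracy decomposes into the class-weighted sensitivity/specificity", {
  set.seed(44)
  for (i in 1:10) {
    v <- sample(1:40, 4, replace = TRUE)
    cm <- structure(list(TP = v[1], FN = v[2], TN = v[3], FP = v[4]),
                    class = "confusion_matrix")
    m <- classification_metrics(cm)
    P <- v[1] + v[2]; N <- v[3] + v[4]
    expect_equal(m$accuracy, (m$sensitivity * P + m$specificity * N) / (P + N))
  }
})

test_that("training histories are seeded, sized by epochs, and learn a separable set", {
  spec <- build_proposed_cnn(32L, 2L, filters_scale = 1 / 16)
  set.seed(77)
  imgs <- lapply(1:24, function(i) {
    a <- array(runif(32 * 32 * 3, 80, 120), c(32, 32, 3))
    if (i %% 2 == 0) a[8:24, 8:24, ] <- a[8:24, 8:24, ] + 100
    a
  })
  y <- as.integer(seq_len(24) %% 2 == 0)
  cfg0 <- train_config(image_side = 32L, epochs = 0L, seed = 3L)
  fit0 <- train_model(spec, imgs, y, cfg0)
  expect_equal(nrow(fit0$history), 0L)

  cfg <- train_config(image_side = 32L, epochs = 10L, batch_size = 8L, seed = 3L)
  fit <- train_model(spec, imgs, y, cfg)
  expect_equal(nrow(fit$history), 10L)
  expect_true(all(is.finite(fit$history$loss)))
  p <- predict_cnn(fit$model, as_batch_array(imgs))
  expect_gte(mean(as.integer(p > 0.5) == y), 0.9)

  fit2 <- train_model(spec, imgs, y, cfg)
  expect_identical(fit$history, fit2$history)

  expect_error(train_model(spec, imgs, y[-1], cfg), "shape mismatch")
})

test_that("roc curves are monotone with unit-range AUC", {
  set.seed(8)
  truth <- rep(c(1, 0), each = 25)
  scores <- truth * 0.5 + runif(50)
  roc <- roc_curve(scores, truth)
  expect_true(all(diff(roc$tpr) >= 0))
  expect_true(all(diff(roc$fpr) >= 0))
  auc <- attr(roc, "auc")
  expect_gte(auc, 0.5)
  expect_lte(auc, 1)
})
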
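test_that("hold-out split has rounded-fraction sizes and partitions the data", {
  sp <- split_spec(seed = 3)
  idx <- split_holdout(1000, sp)
  expect_length(idx$train, 800L)
  expect_length(idx$val, 100L)
  expect_length(idx$test, 100L)
  all_idx <- c(idx$train, idx$val, idx$test)
  expect_setequal(all_idx, 1:1000)
  expect_equal(anyDuplicated(all_idx), 0L)
  expect_identical(split_holdout(1000, sp), idx)     # same seed, same split
  expect_false(identical(split_holdout(1000, split_spec(seed = 4)), idx))
  expect_error(split_spec(fractions = c(0.8, 0.1, 0.2)), "sum to 1")
})

test_that("subject-level splits keep each subject in one partition", {
  subj <- rep(sprintf("S%02d", 1:20), each = 4)
  idx <- split_holdout(80, split_spec(unit = "subject", seed = 1), subj)
  for (part in idx) {
    expect_equal(length(part) %% 4, 0L)
  }
  parts <- rep(NA_character_, 80)
  parts[idx$train] <- "train"; parts[idx$val] <- "val"; parts[idx$test] <- "test"
  expect_true(all(tapply(parts, subj, function(p) length(unique(p))) == 1))
  expect_error(split_holdout(80, split_spec(unit = "subject", seed = 1)),
               "subjects")
})

test_that("confusion counts follow the positive-HPT convention", {
  cm <- confusion_matrix(c("HPT", "HC"), c("HPT", "HC"))
  expect_equal(unclass(cm), c(tp = 1L, fp = 0L, tn = 1L, fn = 0L))
  cm2 <- confusion_matrix(c("HPT", "HC", "HC"), rep("HPT", 3))
  expect_equal(unclass(cm2), c(tp = 1L, fp = 2L, tn = 0L, fn = 0L))
  expect_error(confusion_matrix(c("HPT"), c("HPT", "HC")), "lengths")
  expect_error(confusion_matrix("sick", "HPT"), "labels")
  withr::with_seed(2, {
    yt <- sample(c("HC", "HPT"), 50, replace = TRUE)
    yp <- sample(c("HC", "HPT"), 50, replace = TRUE)
    expect_equal(sum(unclass(confusion_matrix(yt, yp))), 50L)
  })
})

test_that("metrics match hand arithmetic and flag undefined ratios", {
  m <- metrics_from_confusion(c(tp = 2, fp = 1, tn = 6, fn = 1))
  expect_equal(m$accuracy, 0.8)
  expect_equal(m$sensitivity, 2 / 3, tolerance = 1e-12)
  expect_equal(m$specificity, 6 / 7, tolerance = 1e-12)
  expect_equal(m$precision, 2 / 3, tolerance = 1e-12)
  expect_equal(m$f1, 2 / 3, tolerance = 1e-12)

  perfect <- metrics_from_confusion(c(tp = 50, fp = 0, tn = 50, fn = 0))
  expect_true(all(unlist(perfect) == 1))

  w <- capture_warnings(
    m0 <- metrics_from_confusion(c(tp = 0, fp = 0, tn = 5, fn = 0)))
  expect_match(w, "precision", all = FALSE)
  expect_match(w, "sensitivity", all = FALSE)
  expect_true(is.na(m0$precision))
  expect_true(is.na(m0$sensitivity))
  expect_error(metrics_from_confusion(c(tp = 0, fp = 0, tn = 0, fn = 0)),
               "empty")
})

test_that("accuracy decomposes into class-weighted sensitivity/specificity", {
  withr::with_seed(7, {
    for (i in 1:20) {
      cm <- c(tp = sample(0:30, 1), fp = sample(0:30, 1),
              tn = sample(1:30, 1), fn = sample(1:30, 1))
      m <- suppressWarnings(metrics_from_confusion(cm))
      n_pos <- cm[["tp"]] + cm[["fn"]]
      n_neg <- cm[["tn"]] + cm[["fp"]]
      expect_equal(m$accuracy,
                   (m$sensitivity * n_pos + m$specificity * n_neg) /
                     (n_pos + n_neg))
    }
  })
})

test_that("cross-validation folds partition the data with balanced sizes", {
  toy <- toy_images(15, seed = 3)         # 30 images
  hp <- bcg_hyperparams(batch_size = 30, epochs = 1)
  cv <- kfold_crossval(toy$images, toy$labels, k = 3, hp = hp, seed = 5)
  expect_equal(nrow(cv$folds), 3L)
  expect_true(max(cv$folds$n_test) - min(cv$folds$n_test) <= 1)
  expect_equal(sum(cv$pooled), 30)        # every instance tested once
  expect_equal(sum(cv$folds$tp + cv$folds$fp + cv$folds$tn + cv$folds$fn),
               30)
  expect_error(kfold_crossval(toy$images, toy$labels, k = 31, hp = hp),
               "exceeds")
  expect_error(kfold_crossval(toy$images, toy$labels, k = 1, hp = hp),
               "at least 2")
})

test_that("training history bookkeeping and determinism contracts hold", {
  toy <- toy_images(15, seed = 6)
  hp <- bcg_hyperparams(batch_size = 10, epochs = 3)
  f1 <- hpt_cnn(toy$images, toy$labels, hp = hp,
                split = split_spec(seed = 2), seed = 9)
  expect_equal(nrow(f1$history), 3L)
  expect_named(f1$history,
               c("epoch", "loss", "data_loss", "accuracy", "val_loss",
                 "val_accuracy"))
  f2 <- hpt_cnn(toy$images, toy$labels, hp = hp,
                split = split_spec(seed = 2), seed = 9)
  expect_identical(f1$history, f2$history)
  expect_identical(unclass(f1$confusion), unclass(f2$confusion))
  pred <- predict(f1, toy$images)
  expect_true(all(pred %in% c("HC", "HPT")))
  sc <- predict(f1, toy$images, type = "score")
  expect_equal(dim(sc), c(30L, 2L))
  m <- build_model(seed = 1)
  expect_error(train_network(m, toy$images[0, , drop = FALSE],
                             character(0)), "empty")
})

test_that("single-batch loss decreases over the first training steps", {
  toy <- toy_images(5, seed = 8)          # one batch of 10 duplicated-ish images
  hp <- bcg_hyperparams(batch_size = 10, epochs = 5, l1 = 0)
  m <- build_model(hp = hp, seed = 2)
  fit <- train_network(m, toy$images, toy$labels, epochs = 5, seed = 2)
  expect_true(all(diff(fit$history$data_loss) < 0))
})
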
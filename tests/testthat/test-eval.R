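balanced_fs <- function(n_per_class = 64, d = 3, sep = 5, seed = 1) {
  make_gaussian_fs(n_per_class, n_per_class, d = d, sep = sep, seed = seed)
}

test_that("the 64/64 stratified split preserves class counts exactly", {
  fs <- balanced_fs(64)
  sp <- split_dataset(fs, 64, 64, seed = 3)
  expect_equal(as.integer(table(droplevels(sp$train$labels))), c(32L, 32L))
  expect_equal(as.integer(table(droplevels(sp$test$labels))), c(32L, 32L))
  expect_length(intersect(sp$train_idx, sp$test_idx), 0)
})

test_that("splits are seeded-reproducible and validate their inputs", {
  fs <- balanced_fs(20)
  a <- split_dataset(fs, 10, 10, seed = 7)
  b <- split_dataset(fs, 10, 10, seed = 7)
  expect_identical(a$train_idx, b$train_idx)
  expect_identical(a$test_idx, b$test_idx)
  expect_error(split_dataset(fs, 0, 10), class = "myograsp_invalid_argument")
  expect_error(split_dataset(fs, 30, 30), class = "myograsp_invalid_argument")
})

test_that("accuracy implements trace-over-total percent with an exact complement", {
  cm <- matrix(c(31, 1, 1, 31), 2, 2)
  expect_equal(accuracy(cm), 100 * 62 / 64)
  expect_identical(accuracy(cm), 96.875)
  expect_identical(accuracy(cm) + error_rate(cm), 100)
  expect_equal(accuracy(diag(c(10, 20, 5))), 100)
  expect_equal(accuracy(matrix(c(0, 3, 4, 0), 2, 2)), 0)
  expect_error(accuracy(matrix(0, 2, 2)), class = "myograsp_invalid_argument")
  expect_error(accuracy(matrix(1, 2, 3)), class = "myograsp_invalid_argument")
})

test_that("permuting class order permutes the confusion matrix but not accuracy", {
  truth <- rep(c("open", "grasp"), c(30, 34))
  pred <- truth
  pred[2] <- "grasp"; pred[40] <- "open"
  cm1 <- confusion_matrix(truth, pred, c("open", "grasp"))
  cm2 <- confusion_matrix(truth, pred, c("grasp", "open"))
  expect_equal(unclass(cm1)[2:1, 2:1], unclass(cm2), ignore_attr = TRUE)
  expect_identical(accuracy(cm1), accuracy(cm2))
})

test_that("naive Bayes separates clean clusters and behaves sanely at the mean", {
  train <- balanced_fs(30, sep = 6, seed = 5)
  test <- balanced_fs(30, sep = 6, seed = 6)
  expect_equal(accuracy(baseline_nb(train, test)), 100)
  # single test point at a class mean with equal priors -> that class
  m1 <- colMeans(train$matrix[as.character(train$labels) == "open", ])
  at_mean <- labeled_feature_set(matrix(m1, 1), "open", train$feature_names)
  expect_equal(accuracy(baseline_nb(train, at_mean)), 100)
})

test_that("naive Bayes is at chance for identical class distributions", {
  accs <- vapply(1:15, function(seed) {
    train <- balanced_fs(40, sep = 0, seed = seed)
    test <- balanced_fs(40, sep = 0, seed = seed + 100)
    accuracy(baseline_nb(train, test))
  }, 0)
  expect_gt(mean(accs), 35)
  expect_lt(mean(accs), 65)
})

test_that("naive Bayes survives zero-variance features via the floor", {
  X <- cbind(c(rep(0, 10), rep(1, 10)), 1) # second feature constant
  fs <- labeled_feature_set(X, rep(c("open", "grasp"), each = 10), c("a", "b"))
  cm <- baseline_nb(fs, fs)
  expect_equal(accuracy(cm), 100)
})

test_that("k-nearest-neighbour matches its contract at the extremes", {
  train <- balanced_fs(25, sep = 6, seed = 7)
  test <- balanced_fs(25, sep = 6, seed = 8)
  expect_equal(accuracy(baseline_knn(train, test, k = 5)), 100)
  # k = 1 on a duplicated training point returns that label
  dup <- labeled_feature_set(train$matrix[1, , drop = FALSE],
                             train$labels[1], train$feature_names)
  expect_equal(accuracy(baseline_knn(train, dup, k = 1)), 100)
  # k = n_train always votes the majority training class
  unbal <- labeled_feature_set(rbind(train$matrix, train$matrix[1:10, ]),
                               c(as.character(train$labels),
                                 rep("open", 10)), train$feature_names)
  cm <- baseline_knn(unbal, test, k = 60)
  expect_true(all(colnames(cm)[apply(cm, 1, which.max)] == "open"))
  expect_error(baseline_knn(train, test, k = 51), class = "myograsp_invalid_argument")
})

test_that("in-package knn agrees with an independent implementation off ties", {
  skip_if_not_installed("class")
  train <- balanced_fs(30, sep = 2, seed = 9)
  test <- balanced_fs(30, sep = 2, seed = 10)
  mine <- baseline_knn(train, test, k = 5)
  ref <- class::knn(train$matrix, test$matrix,
                    droplevels(train$labels), k = 5)
  cm_ref <- confusion_matrix(droplevels(test$labels), ref,
                             levels(droplevels(train$labels)))
  expect_identical(unclass(mine), unclass(cm_ref))
})

test_that("the decision tree handles canonical single-split and pure cases", {
  X <- matrix(c(1:10, 21:30), ncol = 1)
  fs <- labeled_feature_set(X, rep(c("open", "grasp"), each = 10), "x")
  expect_equal(accuracy(baseline_dt(fs, fs, max_depth = 1)), 100)
  pure <- labeled_feature_set(matrix(rnorm(20), 10), rep("grasp", 10), c("a", "b"))
  mixed_test <- balanced_fs(5, seed = 11)
  cm <- baseline_dt(pure, mixed_test)
  expect_true(all(cm[, "grasp"] == rowSums(cm))) # single leaf predicts grasp
  # deterministic across repeated fits
  train <- balanced_fs(30, sep = 2, seed = 12)
  test <- balanced_fs(30, sep = 2, seed = 13)
  expect_identical(baseline_dt(train, test), baseline_dt(train, test))
})

test_that("the comparison harness emits the protocol-shaped report", {
  # wide separation so even the axis-aligned tree is comfortably above 90%
  subjects <- lapply(1:6, function(i) balanced_fs(30, sep = 12, seed = 20 + i))
  report <- compare_classifiers(subjects, n_train = 30, n_test = 30, seed = 1)
  expect_identical(rownames(report$accuracy), c("NB", "KNN", "DT", "LDA"))
  expect_identical(colnames(report$accuracy), c(paste0("S", 1:6), "Average"))
  expect_equal(report$accuracy$Average,
               unname(rowMeans(report$accuracy[, 1:6])), tolerance = 1e-12)
  expect_true(all(report$accuracy >= 0 & report$accuracy <= 100))
  expect_true(all(report$accuracy[, 1:6] >= 90)) # separable data
  expect_length(report$confusions, 6)
  expect_named(report$confusions[[1]], c("NB", "KNN", "DT", "LDA"))
})

test_that("a failing classifier yields an NA cell, not an abort", {
  subjects <- list(balanced_fs(10, seed = 30))
  boom <- function(train, test) stop("boom")
  cls <- c(default_classifiers()[c("LDA")], list(BOOM = boom))
  expect_warning(
    report <- compare_classifiers(subjects, n_train = 8, n_test = 8,
                                  seed = 2, classifiers = cls),
    "BOOM")
  expect_true(is.na(report$accuracy["BOOM", 1]))
  expect_false(is.na(report$accuracy["LDA", 1]))
})

test_that("subsampling to the per-class protocol count is exact and seeded", {
  fs <- protocol_subject_fs(seed = 201, n_reps = 3, hold_s = 2, n_per_class = 10)
  expect_equal(as.integer(table(droplevels(fs$labels))), c(10L, 10L))
  expect_error(subsample_windows(fs, 1000), class = "myograsp_invalid_argument")
})
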
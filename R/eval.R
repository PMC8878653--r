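#' Confusion matrix of true vs predicted labels
#'
#' @param truth True labels.
#' @param predicted Predicted labels.
#' @param classes Class order (rows = truth, columns = predicted);
#'   defaults to the union of levels in `truth`.
#'
#' @return A c x c integer matrix of class `confusion_matrix`.
#' @export
confusion_matrix <- function(truth, predicted, classes = NULL) {
  truth <- as.character(truth); predicted <- as.character(predicted)
  if (length(truth) != length(predicted))
    abort_invalid("`truth` and `predicted` must have equal length")
  if (is.null(classes)) classes <- sort(unique(c(truth, predicted)))
  cm <- table(factor(truth, levels = classes), factor(predicted, levels = classes))
  structure(unclass(cm), dimnames = list(truth = classes, predicted = classes),
            class = c("confusion_matrix", "matrix"))
}

#' Recognition accuracy and error rate
#'
#' Accuracy is the fraction of correctly classified windows in percent:
#' `(total - errors) / total * 100`, i.e. `100 * trace / total` of the
#' confusion matrix. `error_rate` is its exact complement
#' (`100 - accuracy`).
#'
#' @param cm A [confusion_matrix()] (any square count matrix works).
#'
#' @return A percentage in `[0, 100]`.
#' @export
accuracy <- function(cm) {
  cm <- as.matrix(cm)
  if (length(cm) == 0 || nrow(cm) != ncol(cm))
    abort_invalid("`cm` must be a non-empty square matrix")
  total <- sum(cm)
  if (total <= 0) abort_invalid("`cm` must contain at least one count")
  100 * sum(diag(cm)) / total
}

#' @rdname accuracy
#' @export
error_rate <- function(cm) 100 - accuracy(cm)

# deterministic proportional allocation (largest remainder)
allocate_stratified <- function(n_i, n_take) {
  exact <- n_take * n_i / sum(n_i)
  base <- floor(exact)
  rem <- n_take - sum(base)
  if (rem > 0) {
    order_by_frac <- order(exact - base, decreasing = TRUE)
    base[order_by_frac[seq_len(rem)]] <- base[order_by_frac[seq_len(rem)]] + 1L
  }
  as.integer(base)
}

subset_fs <- function(fs, idx) {
  labeled_feature_set(fs$matrix[idx, , drop = FALSE], fs$labels[idx],
                      fs$feature_names)
}

#' Seeded train/test split of a feature set
#'
#' Disjoint, reproducible split; stratified by default so class counts are
#' preserved within one window (the 64/64 split of the 128-window,
#' 64-per-class protocol yields exactly 32 + 32 per side).
#'
#' @param fs A [labeled_feature_set()].
#' @param n_train,n_test Window counts for each side; `n_test` defaults to
#'   all remaining windows.
#' @param stratified Preserve class proportions (default TRUE).
#' @param seed Integer seed.
#'
#' @return List with elements `train`, `test` (feature sets) and the index
#'   vectors `train_idx`, `test_idx`.
#' @export
split_dataset <- function(fs, n_train, n_test = NULL, stratified = TRUE, seed = 1L) {
  if (!inherits(fs, "labeled_feature_set")) abort_invalid("`fs` must be a labeled_feature_set")
  n <- nrow(fs$matrix)
  if (is.null(n_test)) n_test <- n - n_train
  if (n_train < 1 || n_test < 1) abort_invalid("`n_train` and `n_test` must be >= 1")
  if (n_train + n_test > n)
    abort_invalid(sprintf("split (%d + %d) exceeds available windows (%d)",
                          n_train, n_test, n))
  y <- droplevels(fs$labels)
  withr::with_seed(as.integer(seed), {
    if (stratified) {
      classes <- levels(y)
      n_i <- as.integer(table(y)[classes])
      tr_i <- allocate_stratified(n_i, n_train)
      te_i <- allocate_stratified(n_i, n_test)
      if (any(tr_i + te_i > n_i))
        abort_invalid("stratified split exceeds a class's available windows")
      train_idx <- integer(0); test_idx <- integer(0)
      for (k in seq_along(classes)) {
        pool <- which(y == classes[k])
        picked <- sample(pool, tr_i[k] + te_i[k])
        train_idx <- c(train_idx, picked[seq_len(tr_i[k])])
        test_idx <- c(test_idx, picked[tr_i[k] + seq_len(te_i[k])])
      }
    } else {
      picked <- sample(n, n_train + n_test)
      train_idx <- picked[seq_len(n_train)]
      test_idx <- picked[n_train + seq_len(n_test)]
    }
  })
  train_idx <- sort(train_idx); test_idx <- sort(test_idx)
  list(train = subset_fs(fs, train_idx), test = subset_fs(fs, test_idx),
       train_idx = train_idx, test_idx = test_idx)
}

#' Subsample a feature set to a fixed per-class window count
#'
#' Restricts to the requested classes and draws a seeded random subset of
#' `n_per_class` windows from each, e.g. to form the 128-window (64 per
#' gesture) recognition protocol from a longer recording session.
#'
#' @param fs A [labeled_feature_set()].
#' @param n_per_class Windows to keep per class.
#' @param classes Classes to keep (default `c("open", "grasp")`).
#' @param seed Integer seed.
#'
#' @return A [labeled_feature_set()] with `n_per_class * length(classes)` rows.
#' @export
subsample_windows <- function(fs, n_per_class, classes = c("open", "grasp"),
                              seed = 1L) {
  y <- as.character(fs$labels)
  idx <- withr::with_seed(as.integer(seed), {
    unlist(lapply(classes, function(cl) {
      pool <- which(y == cl)
      if (length(pool) < n_per_class)
        abort_invalid(sprintf("class `%s` has only %d windows (< %d)",
                              cl, length(pool), n_per_class))
      sort(sample(pool, n_per_class))
    }))
  })
  subset_fs(fs, sort(idx))
}

as_df <- function(fs) {
  df <- as.data.frame(fs$matrix)
  df$.label <- droplevels(fs$labels)
  df
}

#' Baseline classifiers
#'
#' Reference classifiers for the comparison harness; each fits on `train`,
#' predicts `test` and returns the test [confusion_matrix()].
#'
#' * `baseline_nb` — Gaussian naive Bayes (via \pkg{e1071}); each fitted
#'   per-class, per-feature standard deviation is floored at
#'   `sqrt(var_floor)` so zero-variance features cannot produce degenerate
#'   densities.
#' * `baseline_knn` — Euclidean k-nearest-neighbour majority vote
#'   (default `k = 5`), implemented in-package so that vote ties resolve
#'   deterministically to the smaller class index.
#' * `baseline_dt` — CART decision tree with Gini impurity (via
#'   \pkg{rpart}; exhaustive per-feature threshold search), depth-limited
#'   (default `max_depth = 4`), deterministic.
#' * `classify_lda` — the package's own [fit_lda()] + [predict.lda_model()]
#'   wrapped into the same interface.
#'
#' @param train,test [labeled_feature_set()] objects.
#' @param var_floor Variance floor for naive Bayes (default 1e-12 mV^2
#'   scale).
#' @param k Neighbourhood size, `1 <= k <= n_train`.
#' @param max_depth Maximum tree depth (>= 1).
#'
#' @return A [confusion_matrix()] over the model's class order.
#' @name baselines
NULL

#' @rdname baselines
#' @export
baseline_nb <- function(train, test, var_floor = 1e-12) {
  df <- as_df(train)
  fit <- e1071::naiveBayes(.label ~ ., data = df)
  fit$tables <- lapply(fit$tables, function(tab) {
    tab[, 2] <- pmax(tab[, 2], sqrt(var_floor))
    tab
  })
  pred <- predict(fit, as.data.frame(test$matrix))
  confusion_matrix(droplevels(test$labels), pred, classes = levels(droplevels(train$labels)))
}

#' @rdname baselines
#' @export
baseline_knn <- function(train, test, k = 5) {
  n_tr <- nrow(train$matrix)
  if (k < 1 || k > n_tr) abort_invalid("`k` must be in [1, n_train]")
  classes <- levels(droplevels(train$labels))
  y <- as.integer(factor(droplevels(train$labels), levels = classes))
  Xtr <- train$matrix; Xte <- test$matrix
  d2 <- outer(rowSums(Xte^2), rowSums(Xtr^2), "+") - 2 * Xte %*% t(Xtr)
  pred <- apply(d2, 1, function(row) {
    nn <- y[order(row)[seq_len(k)]]
    votes <- tabulate(nn, nbins = length(classes))
    which.max(votes) # first max = smaller class index on ties
  })
  confusion_matrix(droplevels(test$labels), classes[pred], classes = classes)
}

#' @rdname baselines
#' @export
baseline_dt <- function(train, test, max_depth = 4) {
  if (max_depth < 1) abort_invalid("`max_depth` must be >= 1")
  classes <- levels(droplevels(train$labels))
  if (length(classes) == 1) {
    # zero impurity: the tree is a single leaf predicting the only class
    pred <- rep(classes, nrow(test$matrix))
    all_classes <- sort(unique(c(classes, as.character(droplevels(test$labels)))))
    return(confusion_matrix(droplevels(test$labels), pred, all_classes))
  }
  df <- as_df(train)
  fit <- rpart::rpart(.label ~ ., data = df, method = "class",
                      parms = list(split = "gini"),
                      control = rpart::rpart.control(maxdepth = max_depth,
                                                     cp = 0, minsplit = 2,
                                                     minbucket = 1, xval = 0))
  pred <- predict(fit, as.data.frame(test$matrix), type = "class")
  confusion_matrix(droplevels(test$labels), pred, classes = levels(droplevels(train$labels)))
}

#' @rdname baselines
#' @export
classify_lda <- function(train, test) {
  model <- fit_lda(train)
  pred <- predict(model, test$matrix)
  confusion_matrix(droplevels(test$labels), pred, classes = model$class_labels)
}

default_classifiers <- function() {
  list(NB = baseline_nb, KNN = baseline_knn, DT = baseline_dt, LDA = classify_lda)
}

#' Compare classifiers across subjects
#'
#' Runs every classifier on every subject's feature set with the same
#' seeded stratified split, and reports per-subject accuracies, the
#' per-classifier mean, and all confusion matrices.
#'
#' @param subjects List of [labeled_feature_set()] objects (one per
#'   subject).
#' @param n_train,n_test Split sizes per subject (default 64/64).
#' @param seed Base seed; subject `i` uses `seed + i`.
#' @param classifiers Named list of `function(train, test)` classifiers;
#'   defaults to NB, KNN, DT and the package's LDA. A pluggable slot: add
#'   e.g. an SVM by appending a function.
#'
#' @return An object of class `comparison_report`: `accuracy` (classifiers
#'   x subjects data frame with an `Average` column, in percent) and
#'   `confusions` (nested list). A classifier failing on a subject yields
#'   an `NA` cell with a warning rather than aborting.
#' @export
compare_classifiers <- function(subjects, n_train = 64, n_test = 64, seed = 42L,
                                classifiers = default_classifiers()) {
  if (length(subjects) < 1) abort_invalid("at least one subject required")
  subj_names <- paste0("S", seq_along(subjects))
  acc <- matrix(NA_real_, length(classifiers), length(subjects),
                dimnames = list(names(classifiers), subj_names))
  confusions <- stats::setNames(vector("list", length(subjects)), subj_names)
  for (i in seq_along(subjects)) {
    sp <- split_dataset(subjects[[i]], n_train, n_test, stratified = TRUE,
                        seed = as.integer(seed) + i)
    confusions[[i]] <- list()
    for (cl in names(classifiers)) {
      cm <- tryCatch(classifiers[[cl]](sp$train, sp$test), error = function(e) {
        warning(sprintf("classifier %s failed on subject %d: %s",
                        cl, i, conditionMessage(e)), call. = FALSE)
        NULL
      })
      if (!is.null(cm)) {
        acc[cl, i] <- accuracy(cm)
        confusions[[i]][[cl]] <- cm
      }
    }
  }
  report <- as.data.frame(acc)
  report$Average <- rowMeans(acc)
  structure(list(accuracy = report, confusions = confusions,
                 n_train = n_train, n_test = n_test, seed = seed),
            class = "comparison_report")
}

#' @export
print.comparison_report <- function(x, ...) {
  cat(sprintf("<comparison_report> %d subject(s), %d/%d split\n",
              ncol(x$accuracy) - 1, x$n_train, x$n_test))
  print(round(x$accuracy, 2))
  invisible(x)
}
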
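test_that("the fitted direction matches the two-class closed form on a worked example", {
  X <- rbind(c(1, 2), c(2, 3), c(3, 3), c(6, 5), c(7, 8), c(8, 5))
  fs <- labeled_feature_set(X, rep(c("open", "grasp"), each = 3), c("f1", "f2"))
  model <- fit_lda(fs)
  expect_gt(abs(cosine_sim(model$omega[, 1], lda_closed_form(model))), 1 - 1e-8)
  # omega is canonicalized: unit norm, leading component positive
  expect_equal(sum(model$omega[, 1]^2), 1)
  expect_gt(model$omega[which(abs(model$omega[, 1]) > 1e-12)[1], 1], 0)
})

test_that("scatter matrices are symmetric PSD and class bookkeeping is exact", {
  fs <- make_gaussian_fs(20, 30, d = 4, seed = 2)
  model <- fit_lda(fs)
  expect_equal(model$Sb, t(model$Sb))
  expect_equal(model$Sw, t(model$Sw))
  expect_gte(min(eigen(model$Sb, symmetric = TRUE)$values), -1e-9)
  expect_gte(min(eigen(model$Sw, symmetric = TRUE)$values), -1e-9)
  expect_lte(qr(model$Sb)$rank, length(model$class_labels) - 1)
  expect_equal(sum(model$n_per_class), 50L)
  # total scatter identity: Sb + Sw equals scatter about the grand mean
  Xc <- sweep(fs$matrix, 2, colMeans(fs$matrix))
  expect_equal(model$Sb + model$Sw, crossprod(Xc), tolerance = 1e-10)
})

test_that("degenerate inputs raise the documented errors", {
  fs1 <- labeled_feature_set(matrix(rnorm(6), 3), rep("open", 3), c("a", "b"))
  expect_error(fit_lda(fs1), class = "myograsp_invalid_argument") # one class
  fs2 <- labeled_feature_set(matrix(rnorm(8), 4),
                             c("open", "open", "open", "grasp"), c("a", "b"))
  expect_error(fit_lda(fs2), class = "myograsp_degenerate_class")
})

test_that("identical class clouds give a near-zero criterion and chance predictions", {
  withr::with_seed(7, {
    X <- matrix(rnorm(200), 100, 2)
    fs <- labeled_feature_set(rbind(X, X), rep(c("open", "grasp"), each = 100),
                              c("a", "b"))
    model <- fit_lda(fs)
    expect_lt(fisher_criterion(model, model$omega[, 1]), 1e-6)
    test <- make_gaussian_fs(50, 50, d = 2, sep = 0, seed = 8)
    acc <- accuracy(confusion_matrix(droplevels(test$labels),
                                     predict(model, test$matrix),
                                     model$class_labels))
    expect_lt(acc, 70)
  })
})

test_that("duplicating every training sample leaves the projection unchanged", {
  fs <- make_gaussian_fs(15, 25, d = 3, seed = 3)
  doubled <- labeled_feature_set(rbind(fs$matrix, fs$matrix),
                                 c(as.character(fs$labels), as.character(fs$labels)),
                                 fs$feature_names)
  expect_equal(fit_lda(fs)$omega, fit_lda(doubled)$omega, tolerance = 1e-10)
})

test_that("refitting with permuted sample order yields the same model", {
  fs <- make_gaussian_fs(20, 20, d = 3, seed = 4)
  perm <- withr::with_seed(5, sample(40))
  fs_perm <- labeled_feature_set(fs$matrix[perm, ], fs$labels[perm], fs$feature_names)
  a <- fit_lda(fs); b <- fit_lda(fs_perm)
  expect_equal(a$omega, b$omega, tolerance = 1e-10)
  expect_equal(a$class_means, b$class_means, tolerance = 1e-12)
})

test_that("the Fisher criterion is maximized at the fitted direction and is scale-free", {
  fs <- make_gaussian_fs(30, 30, d = 4, seed = 6)
  model <- fit_lda(fs)
  J_star <- fisher_criterion(model, model$omega[, 1])
  withr::with_seed(9, {
    for (i in 1:1000) {
      v <- rnorm(4)
      expect_gte(J_star, fisher_criterion(model, v) - 1e-10)
    }
  })
  expect_equal(fisher_criterion(model, 5.3 * model$omega[, 1]), J_star)
  expect_error(fisher_criterion(model, rep(0, 4)), class = "myograsp_invalid_argument")
})

test_that("the retained pairs satisfy the generalized eigen equation", {
  fs <- make_gaussian_fs(40, 25, d = 5, seed = 10)
  model <- fit_lda(fs)
  Swr <- model$Sw + model$ridge_eps * diag(5)
  for (j in seq_len(ncol(model$omega))) {
    resid <- model$Sb %*% model$omega[, j] -
      model$eigenvalues[j] * Swr %*% model$omega[, j]
    expect_lt(sqrt(sum(resid^2)), 1e-8 * norm(model$Sb, "F"))
  }
})

test_that("projection is consistent, orthogonal-complement blind, and (c-1)-dimensional", {
  fs <- make_gaussian_fs(20, 20, d = 4, seed = 11)
  model <- fit_lda(fs)
  expect_identical(ncol(model$omega), 1L)
  expect_equal(project(model, model$class_means), model$projected_means)
  x <- fs$matrix[1, , drop = FALSE]
  v <- withr::with_seed(12, rnorm(4))
  v <- v - model$omega[, 1] * sum(v * model$omega[, 1]) # v orthogonal to omega
  expect_equal(project(model, x), project(model, x + rep(v, each = 1)),
               tolerance = 1e-10)
  expect_error(project(model, matrix(0, 2, 3)), class = "myograsp_invalid_argument")
})

test_that("prediction assigns nearest projected mean with documented tie-breaking", {
  fs <- make_gaussian_fs(25, 25, d = 3, sep = 6, seed = 13)
  model <- fit_lda(fs)
  # class means classify to their own class
  pred_means <- predict(model, model$class_means)
  expect_identical(as.character(pred_means), model$class_labels)
  # clean clusters classify perfectly
  test <- make_gaussian_fs(40, 40, d = 3, sep = 6, seed = 14)
  expect_identical(as.character(predict(model, test$matrix)),
                   as.character(test$labels))
  # midpoint between projected means -> first class in label order
  mid_proj <- mean(model$projected_means)
  omega <- model$omega[, 1]
  x_mid <- matrix(mid_proj * omega, 1) # projects exactly onto the midpoint
  expect_identical(as.character(predict(model, x_mid)), model$class_labels[1])
})

test_that("predictions are invariant to a common affine feature rescaling", {
  fs <- make_gaussian_fs(25, 30, d = 3, seed = 15)
  test <- make_gaussian_fs(30, 30, d = 3, seed = 16)
  base <- predict(fit_lda(fs), test$matrix)
  shift <- c(2, -1, 0.5)
  tr <- function(X) sweep(4.2 * X, 2, shift, "+")
  fs_scaled <- labeled_feature_set(tr(fs$matrix), fs$labels, fs$feature_names)
  scaled <- predict(fit_lda(fs_scaled), tr(test$matrix))
  expect_identical(as.character(base), as.character(scaled))
})

test_that("the from-scratch fit agrees with an independent reference implementation", {
  skip_if_not_installed("MASS")
  fs <- make_gaussian_fs(40, 40, d = 4, sep = 3, seed = 17)
  model <- fit_lda(fs)
  ref <- MASS::lda(fs$matrix, grouping = droplevels(fs$labels),
                   prior = c(0.5, 0.5))
  expect_gt(abs(cosine_sim(model$omega[, 1], ref$scaling[, 1])), 1 - 1e-6)
  test <- make_gaussian_fs(50, 50, d = 4, sep = 3, seed = 18)
  expect_identical(as.character(predict(model, test$matrix)),
                   as.character(predict(ref, test$matrix)$class))
})

test_that("model serialization round-trips through JSON", {
  fs <- make_gaussian_fs(20, 20, d = 3, seed = 19)
  model <- fit_lda(fs)
  path <- withr::local_tempfile(fileext = ".json")
  write_lda_model(model, path)
  restored <- read_lda_model(path)
  expect_equal(restored$omega, model$omega)
  expect_equal(restored$class_means, model$class_means)
  expect_equal(restored$ridge_eps, model$ridge_eps)
  test <- make_gaussian_fs(30, 30, d = 3, seed = 20)
  expect_identical(as.character(predict(restored, test$matrix)),
                   as.character(predict(model, test$matrix)))
})
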
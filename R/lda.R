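#' Fit a Fisher linear discriminant from first principles
#'
#' Computes, directly from their definitions: per-class mean vectors
#' \eqn{u_i = (1/n_i) \sum_{x \in i} x}; the grand mean over all `m`
#' training samples \eqn{u = (1/m) \sum x}; the between-class scatter
#' \eqn{S_b = \sum_i n_i (u_i - u)(u_i - u)^T} (count-weighted, so unequal
#' class sizes are handled and \eqn{S_b + S_w} equals the total scatter);
#' the within-class scatter \eqn{S_w = \sum_i \sum_{x \in i} (x - u_i)(x -
#' u_i)^T}; and the projection \eqn{\omega} maximizing the Fisher
#' criterion, the generalized Rayleigh quotient
#' \eqn{J(\omega) = (\omega^T S_b \omega) / (\omega^T S_w \omega)}.
#'
#' The maximizers are the leading generalized eigenvectors of
#' \eqn{(S_b, S_w + \epsilon I)}, computed by Cholesky whitening of the
#' ridge-regularized within-class scatter followed by a symmetric
#' eigendecomposition. At most `c - 1` directions are retained (the rank of
#' \eqn{S_b}). Columns of \eqn{\omega} are canonicalized to unit norm with
#' their first non-negligible component positive, so refits are
#' reproducible and serializable.
#'
#' The ridge \eqn{\epsilon} defaults to `1e-6 * trace(Sw)/d` with an
#' absolute floor of `1e-12`: deterministic, scale-aware protection against
#' singular within-class scatter (few windows, collinear features).
#'
#' @param train A [labeled_feature_set()] with >= 2 classes, each with
#'   >= 2 samples.
#' @param ridge_eps Optional explicit regularization scalar.
#'
#' @return An object of class `lda_model` with elements `class_labels`,
#'   `n_per_class`, `class_means` (c x d), `grand_mean`, `Sb`, `Sw`,
#'   `ridge_eps`, `omega` (d x (c-1)), `eigenvalues`, `projected_means`
#'   (c x (c-1)) and `feature_names`.
#' @export
fit_lda <- function(train, ridge_eps = NULL) {
  if (!inherits(train, "labeled_feature_set"))
    abort_invalid("`train` must be a labeled_feature_set")
  X <- train$matrix
  y <- droplevels(train$labels)
  d <- ncol(X)
  if (d < 1) abort_invalid("at least one feature required")
  classes <- levels(y)
  c_ <- length(classes)
  if (c_ < 2) abort_invalid("at least two classes required")
  n_i <- as.integer(table(y)[classes])
  if (any(n_i < 2))
    abort_degenerate_class(sprintf("class `%s` has fewer than 2 samples",
                                   classes[which(n_i < 2)[1]]))
  means <- do.call(rbind, lapply(classes, function(cl) colMeans(X[y == cl, , drop = FALSE])))
  rownames(means) <- classes
  grand <- colMeans(X)

  Sb <- matrix(0, d, d)
  for (i in seq_len(c_)) {
    dm <- means[i, ] - grand
    Sb <- Sb + n_i[i] * tcrossprod(dm)
  }
  Sw <- matrix(0, d, d)
  for (i in seq_len(c_)) {
    Xi <- sweep(X[y == classes[i], , drop = FALSE], 2, means[i, ])
    Sw <- Sw + crossprod(Xi)
  }

  if (is.null(ridge_eps))
    ridge_eps <- max(1e-6 * sum(diag(Sw)) / d, 1e-12)
  Swr <- Sw + ridge_eps * diag(d)

  # whiten: Swr = R'R; maximize y'(R^-T Sb R^-1)y / y'y, omega = R^-1 y
  R <- chol(Swr)
  Ri <- backsolve(R, diag(d))
  M <- crossprod(Ri, Sb %*% Ri)
  M <- (M + t(M)) / 2
  eig <- eigen(M, symmetric = TRUE)
  k <- min(c_ - 1L, d)
  omega <- Ri %*% eig$vectors[, seq_len(k), drop = FALSE]
  # canonicalize: unit norm, first non-negligible component positive
  for (j in seq_len(k)) {
    v <- omega[, j] / sqrt(sum(omega[, j]^2))
    lead <- which(abs(v) > 1e-12)[1]
    if (!is.na(lead) && v[lead] < 0) v <- -v
    omega[, j] <- v
  }
  rownames(omega) <- train$feature_names

  structure(list(class_labels = classes, n_per_class = n_i,
                 class_means = means, grand_mean = grand,
                 Sb = Sb, Sw = Sw, ridge_eps = ridge_eps,
                 omega = omega, eigenvalues = eig$values[seq_len(k)],
                 projected_means = means %*% omega,
                 feature_names = train$feature_names),
            class = "lda_model")
}

#' @export
print.lda_model <- function(x, ...) {
  cat(sprintf("<lda_model> %d classes (%s), %d features, %d discriminant direction(s)\n",
              length(x$class_labels), paste(x$class_labels, collapse = "/"),
              length(x$grand_mean), ncol(x$omega)))
  cat(sprintf("  J(omega) = %s, ridge = %.3g\n",
              paste(signif(x$eigenvalues, 4), collapse = ", "), x$ridge_eps))
  invisible(x)
}

#' Fisher criterion along a direction
#'
#' Evaluates \eqn{J(\omega) = (\omega^T S_b \omega)/(\omega^T (S_w +
#' \epsilon I) \omega)} with the model's scatter matrices and ridge.
#' Invariant to scaling of `direction`.
#'
#' @param model An [fit_lda()] model.
#' @param direction Non-zero numeric vector of length d.
#'
#' @return The criterion value (scalar).
#' @export
fisher_criterion <- function(model, direction) {
  if (length(direction) != length(model$grand_mean))
    abort_invalid("`direction` has the wrong length")
  if (all(direction == 0)) abort_invalid("`direction` must be non-zero")
  num <- drop(crossprod(direction, model$Sb %*% direction))
  den <- drop(crossprod(direction, model$Sw %*% direction)) +
    model$ridge_eps * sum(direction^2)
  num / den
}

check_dims <- function(model, features) {
  features <- as.matrix(features)
  if (ncol(features) != nrow(model$omega))
    abort_invalid(sprintf("feature matrix has %d columns, model expects %d",
                          ncol(features), nrow(model$omega)))
  features
}

#' Project features onto the discriminant directions
#'
#' Computes \eqn{y = \omega^T x} row-wise: the n x d feature matrix is
#' mapped to n x (c - 1) discriminant scores.
#'
#' @param model An [fit_lda()] model.
#' @param features Numeric matrix (n x d) or [labeled_feature_set()].
#'
#' @return An n x (c - 1) matrix of projections.
#' @export
project <- function(model, features) {
  if (inherits(features, "labeled_feature_set")) features <- features$matrix
  check_dims(model, features) %*% model$omega
}

#' Classify feature vectors with a fitted discriminant
#'
#' Each row is projected and assigned to the class whose projected mean is
#' nearest (Euclidean) in the discriminant space; for two balanced classes
#' this is the usual midpoint threshold on the single discriminant score.
#' Exact ties go to the class listed first in the model's class order.
#'
#' @param object An [fit_lda()] model.
#' @param features Numeric matrix (n x d) or [labeled_feature_set()].
#' @param ... Unused.
#'
#' @return Factor of predicted gesture labels, one per row.
#' @export
predict.lda_model <- function(object, features, ...) {
  proj <- project(object, features)
  pm <- object$projected_means
  d2 <- outer(rowSums(proj^2), rowSums(pm^2), "+") - 2 * proj %*% t(pm)
  idx <- apply(d2, 1, function(row) {
    which(row <= min(row) + 1e-12 * max(1, abs(min(row))))[1]
  })
  factor(object$class_labels[idx], levels = object$class_labels)
}

#' Serialize / restore a fitted discriminant as JSON
#'
#' Writes every model component (means, scatter matrices, projection,
#' ridge, class order, feature names) to a JSON document at full numeric
#' precision, and restores it.
#'
#' @param model An [fit_lda()] model.
#' @param path File path.
#'
#' @return `write_lda_model` returns `path` invisibly; `read_lda_model`
#'   returns the restored `lda_model`.
#' @export
write_lda_model <- function(model, path) {
  doc <- list(class_labels = model$class_labels,
              n_per_class = model$n_per_class,
              class_means = model$class_means,
              grand_mean = model$grand_mean,
              Sb = model$Sb, Sw = model$Sw,
              ridge_eps = model$ridge_eps,
              omega = model$omega,
              eigenvalues = model$eigenvalues,
              feature_names = model$feature_names)
  jsonlite::write_json(doc, path, digits = NA, auto_unbox = TRUE)
  invisible(path)
}

#' @rdname write_lda_model
#' @export
read_lda_model <- function(path) {
  doc <- jsonlite::fromJSON(path)
  as_mat <- function(m, rn = NULL, cn = NULL) {
    m <- as.matrix(m)
    if (!is.null(rn)) rownames(m) <- rn
    if (!is.null(cn)) colnames(m) <- cn
    m
  }
  means <- as_mat(doc$class_means, doc$class_labels, doc$feature_names)
  omega <- as_mat(doc$omega, doc$feature_names)
  structure(list(class_labels = doc$class_labels,
                 n_per_class = as.integer(doc$n_per_class),
                 class_means = means,
                 grand_mean = stats::setNames(as.numeric(doc$grand_mean), doc$feature_names),
                 Sb = as_mat(doc$Sb), Sw = as_mat(doc$Sw),
                 ridge_eps = doc$ridge_eps,
                 omega = omega,
                 eigenvalues = as.numeric(doc$eigenvalues),
                 projected_means = means %*% omega,
                 feature_names = doc$feature_names),
            class = "lda_model")
}
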
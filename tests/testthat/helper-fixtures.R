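# Shared fixtures, all generated in code.

# two Gaussian classes separated by `sep` along a unit direction; the
# direction depends only on `dir_seed` so train/test draws with different
# `seed`s share the same class structure
make_gaussian_fs <- function(n1 = 30, n2 = 30, d = 3, sep = 4, seed = 1,
                             classes = c("open", "grasp"), dir_seed = 99) {
  dir <- withr::with_seed(dir_seed, stats::rnorm(d))
  dir <- dir / sqrt(sum(dir^2))
  withr::with_seed(seed, {
    X <- rbind(matrix(stats::rnorm(n1 * d), n1),
               matrix(stats::rnorm(n2 * d), n2) +
                 matrix(sep * dir, n2, d, byrow = TRUE))
    labeled_feature_set(X, rep(classes, c(n1, n2)), paste0("f", seq_len(d)))
  })
}

# closed-form two-class Fisher direction: (Sw + eps I)^-1 (u1 - u2)
lda_closed_form <- function(model) {
  d <- nrow(model$Sw)
  solve(model$Sw + model$ridge_eps * diag(d),
        model$class_means[1, ] - model$class_means[2, ])
}

cosine_sim <- function(a, b) sum(a * b) / sqrt(sum(a^2) * sum(b^2))

# full acquisition -> conditioning -> windows -> features -> 128-window set
protocol_subject_fs <- function(seed, n_reps = 10, hold_s = 5, n_per_class = 64) {
  rec <- make_subject_dataset(synth_params(), n_reps = n_reps, hold_s = hold_s,
                              seed = seed)
  fs <- extract_features(segment(condition_signal(rec)))
  subsample_windows(fs, n_per_class, seed = seed + 1000L)
}

quiet_cli <- function(...) {
  suppressMessages(myograsp_cli(c(...)))
}
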
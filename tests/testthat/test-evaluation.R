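test_that("stratified folds balance classes to within one trial", {
  f <- stratified_folds(rep(1:2, each = 90), k = 10, seed = 3)
  expect_equal(as.integer(table(f)), rep(18L, 10))
  per_class <- table(f, rep(1:2, each = 90))
  expect_true(all(per_class == 9L))

  f4 <- stratified_folds(rep(1:4, each = 70), k = 10, seed = 3)
  expect_equal(as.integer(table(f4)), rep(28L, 10))
  expect_true(all(table(f4, rep(1:4, each = 70)) == 7L))

  expect_identical(stratified_folds(rep(1:2, 20), 5, seed = 9),
                   stratified_folds(rep(1:2, 20), 5, seed = 9))
  expect_error(stratified_folds(c(rep(1, 30), rep(2, 5)), k = 10), "at least k")

  # uneven class sizes still differ by at most one per fold
  lab <- c(rep(1, 23), rep(2, 31))
  f5 <- stratified_folds(lab, k = 5, seed = 1)
  counts <- table(f5, lab)
  expect_true(all(apply(counts, 2, function(x) diff(range(x))) <= 1))
})

test_that("SVM wrapper scores separable data perfectly and chance at chance", {
  fm <- blob_fm(n_per_class = 30, sep = 8)
  tr <- minmax_normalize(.subset_rows_for_test(fm, c(1:20, 31:50)))
  te <- minmax_normalize(.subset_rows_for_test(fm, c(21:30, 51:60)),
                         params = tr$norm_params)
  res <- train_eval_svm(tr, te, svm_config(), details = TRUE)
  expect_equal(res$accuracy, 1.0)

  # shuffled labels, 2 balanced classes: accuracy near 0.5 over seeds
  accs <- vapply(1:5, function(seed) {
    set.seed(seed)
    fmr <- random_fm(n = 300, f = 4, n_bands = 4, seed = seed + 50)
    fmr$labels <- sample(rep(1:2, 150))
    tr <- minmax_normalize(.subset_rows_for_test(fmr, 1:100))
    te <- minmax_normalize(.subset_rows_for_test(fmr, 101:300),
                           params = tr$norm_params)
    train_eval_svm(tr, te, svm_config())
  }, 0)
  expect_lt(abs(mean(accs) - 0.5), 0.1)

  # 4 classes -> 6 pairwise classifiers (one-against-one)
  fm4 <- random_fm(n = 40, f = 3, n_bands = 3, seed = 2, classes = 4)
  res4 <- train_eval_svm(minmax_normalize(fm4), minmax_normalize(fm4),
                         svm_config(), details = TRUE)
  expect_equal(length(res4$model$rho), 4 * 3 / 2)

  one <- feature_matrix(matrix(rnorm(10), 5), rep(1, 5), 1)
  expect_error(train_eval_svm(one, one, svm_config()), "single class")
})

test_that("cross-validated accuracy is the exact mean of fold accuracies", {
  fm <- blob_fm(n_per_class = 25, sep = 3, seed = 4)
  cv <- cv_accuracy(fm, svm_config(), k = 5, seed = 2)
  expect_equal(cv$mean_accuracy, mean(cv$fold_accuracies))
  expect_equal(length(cv$fold_accuracies), 5L)
})

test_that("select_optimal prefers the smallest channel set at peak accuracy", {
  nb <- 13
  steps <- list(seq_len(59 * nb),                      # 59 channels
                feature_index(rep(1:20, each = 2), rep(c(1, 5), 20), nb),
                feature_index(rep(1:12, each = 2), rep(c(5, 6), 12), nb),
                feature_index(1:3, c(5, 5, 5), nb))
  acc <- c(0.80, 0.85, 0.85, 0.70)
  out <- select_optimal(acc, steps, n_bands = nb)
  expect_equal(out$step, 3L)
  expect_equal(out$channels, 1:12)
  expect_equal(out$accuracy, 0.85)
  expect_equal(out$bands_per_channel[["3"]], c(5L, 6L))

  expect_equal(select_optimal(0.9, list(1:5))$step, 1L)
  # unimodal curve: the peak step wins
  expect_equal(select_optimal(c(0.6, 0.8, 0.9, 0.7),
                              list(1:40, 1:30, 1:20, 1:10))$step, 3L)
  expect_error(select_optimal(numeric(0), list()), "empty")
})

test_that("band usage counts channels retaining each band", {
  ids <- c(feature_index(1, 5), feature_index(2, 5), feature_index(1, 6))
  counts <- band_usage_counts(ids, n_bands = 13)
  expect_equal(counts[5], 2L)
  expect_equal(counts[6], 1L)
  expect_equal(sum(counts), 3L)
  expect_equal(band_usage_counts(integer(0)), integer(13))
  # the complete 59-channel map retains every band in every channel
  expect_equal(band_usage_counts(1:767), rep(59L, 13))
})

test_that("selection CV is leakage-free and consistent with plain CV", {
  fm <- planted_fm(n_per_class = 30, f = 24, informative = 1:6, effect = 1.5,
                   seed = 12, n_bands = 4)
  cv <- run_selection_cv(fm, relief_config(k = 5), svm_config(), N = 8,
                         k = 5, seed = 3, inner_folds = 0)
  expect_equal(cv$step_sizes, c(24L, 16L, 8L))
  expect_equal(cv$mean_step_acc, colMeans(cv$fold_step_acc))
  # step 1 (full feature set) must equal plain CV without selection
  plain <- cv_accuracy(fm, svm_config(), k = 5, seed = 3)
  expect_equal(cv$fold_step_acc[, 1], plain$fold_accuracies)

  opt <- select_optimal(cv, fm, relief_config(k = 5))
  expect_true(opt$step %in% 1:3)
  expect_equal(opt$accuracy, max(cv$mean_step_acc))
})

test_that("accuracy-vs-channels curve is consistent at the full set", {
  fm <- planted_fm(n_per_class = 25, f = 12, informative = 1:3, effect = 2,
                   seed = 5, n_bands = 3)   # 4 channels x 3 bands
  fmn <- minmax_normalize(fm)
  cw <- channel_weights(fmn, relief_config(k = 5))
  expect_equal(which.max(cw), 1L)           # planted channel ranks first
  curve <- accuracy_vs_channels(fm, cw, svm_config(), k = 5, seed = 2)
  expect_equal(curve$n_channels, 1:4)
  full <- cv_accuracy(fm, svm_config(), k = 5, seed = 2)
  expect_equal(curve$mean_accuracy[4], full$mean_accuracy)
  # equal weights fall back to channel-index order
  curve2 <- accuracy_vs_channels(fm, rep(0, 4), svm_config(), k = 5, seed = 2)
  expect_equal(curve2$channel_added, 1:4)
})

test_that("permuted labels stay within binomial chance bounds", {
  # the standard leakage alarm: after destroying the label-feature link,
  # cross-validated accuracy must look like coin flips
  fm <- planted_fm(n_per_class = 50, f = 20, informative = 1:4, effect = 2,
                   seed = 20, n_bands = 4)
  set.seed(21)
  fm$labels <- sample(fm$labels)
  cv <- run_selection_cv(fm, relief_config(k = 5), svm_config(), N = 10,
                         k = 5, seed = 4, inner_folds = 0)
  n_test <- length(fm$labels)
  bound <- qbinom(1 - 0.01 / length(cv$mean_step_acc), n_test, 0.5) / n_test
  expect_lt(max(cv$mean_step_acc), bound)
})
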
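# Tenfold cross-validated evaluation: stratified folds, RBF-SVM wrapper,
# per-fold selection, optimal-channel determination, and report arithmetic.

#' SVM configuration
#'
#' Radial-basis-function support vector machine settings. Multiclass
#' problems are handled one-against-one (the native libsvm scheme): `K`
#' classes train `K * (K - 1) / 2` pairwise classifiers.
#'
#' @param C Soft-margin regularization weight (> 0).
#' @param gamma RBF kernel width; `NULL` (default) uses `1 / n_features` of
#'   the training matrix at fit time.
#' @param tune_C When `TRUE`, a small log-grid over `C` (0.1, 1, 10) is
#'   searched by 3-fold CV inside the training fold before the final fit.
#' @return An object of class `SVMConfig`.
#' @export
svm_config <- function(C = 1, gamma = NULL, tune_C = FALSE) {
  .assert_scalar_num(C, "C", lower = 0, strict = TRUE)
  if (!is.null(gamma)) .assert_scalar_num(gamma, "gamma", lower = 0, strict = TRUE)
  structure(list(kernel = "radial", C = C, gamma = gamma,
                 tune_C = isTRUE(tune_C)),
            class = "SVMConfig")
}

#' Stratified fold assignment
#'
#' Partitions trials into `k` folds so that per-fold class counts differ by
#' at most one from perfect proportion: within each class, indices are
#' shuffled (deterministically from `seed`) and dealt round-robin.
#'
#' @param labels Integer class label per trial; every class needs at least
#'   `k` members.
#' @param k Number of folds.
#' @param seed RNG seed.
#' @return Integer vector of fold numbers (`1..k`), one per trial.
#' @examples
#' f <- stratified_folds(rep(1:2, each = 90), k = 10, seed = 1)
#' table(f)  # 18 trials per fold, 9 per class
#' @export
stratified_folds <- function(labels, k = 10L, seed = 1L) {
  k <- .assert_count(k, "k")
  sizes <- table(labels)
  if (any(sizes < k))
    stop(sprintf("every class needs at least k = %d members (smallest has %d)",
                 k, min(sizes)), call. = FALSE)
  set.seed(seed)
  folds <- integer(length(labels))
  for (cl in sort(unique(labels))) {
    idx <- which(labels == cl)
    folds[sample(idx)] <- rep_len(seq_len(k), length(idx))
  }
  folds
}

.fit_svm <- function(x, y, cfg) {
  if (length(unique(y)) < 2L)
    stop("training fold contains a single class", call. = FALSE)
  gamma <- if (is.null(cfg$gamma)) 1 / ncol(x) else cfg$gamma
  C <- cfg$C
  if (cfg$tune_C && length(y) >= 6L) {
    grid <- c(0.1, 1, 10)
    inner <- stratified_folds(y, k = 3L, seed = 1L)
    cv_err <- vapply(grid, function(cc) {
      mean(vapply(1:3, function(f) {
        mod <- e1071::svm(x[inner != f, , drop = FALSE], factor(y[inner != f]),
                          kernel = "radial", cost = cc, gamma = gamma,
                          scale = FALSE)
        mean(as.character(predict(mod, x[inner == f, , drop = FALSE])) !=
               as.character(y[inner == f]))
      }, 0))
    }, 0)
    C <- grid[which.min(cv_err)]
  }
  e1071::svm(x, factor(y), kernel = "radial", cost = C, gamma = gamma,
             scale = FALSE)
}

#' Train an RBF-SVM on one feature matrix and test on another
#'
#' `train` and `test` must share the feature layout and normalization
#' parameters (fit the normalization on `train` only and apply it to `test`
#' via the `params` argument of [minmax_normalize()]).
#'
#' @param train,test [feature_matrix()] objects.
#' @param cfg An [svm_config()].
#' @param details When `TRUE`, also return the fitted model.
#' @return Test-set accuracy (fraction of correct predictions), or a list
#'   `list(accuracy, model)` when `details = TRUE`.
#' @export
train_eval_svm <- function(train, test, cfg = svm_config(), details = FALSE) {
  stopifnot(inherits(train, "FeatureMatrix"), inherits(test, "FeatureMatrix"))
  if (ncol(train$values) != ncol(test$values) ||
      !identical(train$feature_ids, test$feature_ids))
    stop("train and test matrices must share the same features", call. = FALSE)
  model <- .fit_svm(train$values, train$labels, cfg)
  pred <- predict(model, test$values)
  acc <- mean(as.character(pred) == as.character(test$labels))
  if (details) list(accuracy = acc, model = model) else acc
}

#' Cross-validated SVM accuracy of a feature subset
#'
#' Stratified k-fold CV on raw (unnormalized) features: within each fold,
#' min--max normalization is fitted on the training portion and applied to
#' the held-out portion before the SVM sees either. The reported mean is
#' the exact arithmetic mean of the fold accuracies.
#'
#' @param fm An unnormalized [feature_matrix()].
#' @param cfg An [svm_config()].
#' @param feature_ids Optional global feature ids restricting the columns.
#' @param k Number of folds.
#' @param seed Fold-assignment seed.
#' @return A list: `fold_accuracies`, `mean_accuracy`, `fold_assignments`.
#' @export
cv_accuracy <- function(fm, cfg = svm_config(), feature_ids = NULL, k = 10L,
                        seed = 1L) {
  stopifnot(inherits(fm, "FeatureMatrix"))
  if (!is.null(feature_ids)) {
    cols <- match(feature_ids, fm$feature_ids)
    if (anyNA(cols)) stop("unknown feature id(s)", call. = FALSE)
    fm <- .fm_subset(fm, cols)
  }
  folds <- stratified_folds(fm$labels, k, seed)
  accs <- vapply(seq_len(k), function(f) {
    tr <- minmax_normalize(.fm_rows(fm, folds != f))
    te <- minmax_normalize(.fm_rows(fm, folds == f), params = tr$norm_params)
    train_eval_svm(tr, te, cfg)
  }, 0)
  list(fold_accuracies = accs, mean_accuracy = mean(accs),
       fold_assignments = folds)
}

#' Cross-validated channel selection
#'
#' The full evaluation protocol: stratified k-fold CV where, inside every
#' fold, min--max normalization is fitted on the training portion,
#' [iterrelcen()] is run on the normalized training data (its inner
#' evaluator is `inner_folds`-fold CV accuracy computed on the training
#' portion only, so the held-out fold never influences selection), and the
#' held-out fold is scored at every elimination step. Step-wise mean
#' accuracy across folds is the quantity the optimal channel set is chosen
#' from.
#'
#' @param fm An unnormalized [feature_matrix()] over all channels.
#' @param relief_cfg A [relief_config()].
#' @param svm_cfg An [svm_config()].
#' @param N Features removed per [iterrelcen()] iteration.
#' @param k Number of outer folds.
#' @param seed Fold-assignment seed (inner folds derive from it).
#' @param inner_folds Folds for the selection evaluator inside each
#'   training fold; `0` disables inner evaluation (faster; the trace then
#'   records `NA` inner accuracies, outer scoring is unaffected).
#' @return A `SelectionCV` object: `step_sizes` (surviving feature count per
#'   step), `fold_step_acc` (`k x steps` matrix of held-out accuracies),
#'   `mean_step_acc` (its column means, the Acc curve), `fold_assignments`,
#'   and `traces` (per-fold `SelectionTrace`s).
#' @seealso [select_optimal()] to extract the optimal channel set.
#' @export
run_selection_cv <- function(fm, relief_cfg = relief_config(),
                             svm_cfg = svm_config(), N = 10L, k = 10L,
                             seed = 1L, inner_folds = 5L) {
  stopifnot(inherits(fm, "FeatureMatrix"))
  folds <- stratified_folds(fm$labels, k, seed)
  n_steps <- ceiling(ncol(fm$values) / N)
  fold_step_acc <- matrix(NA_real_, k, n_steps)
  traces <- vector("list", k)
  for (f in seq_len(k)) {
    raw_tr <- .fm_rows(fm, folds != f)
    tr <- minmax_normalize(raw_tr)
    te <- minmax_normalize(.fm_rows(fm, folds == f), params = tr$norm_params)
    evaluator <- if (inner_folds > 0L) {
      function(ids) cv_accuracy(raw_tr, svm_cfg, feature_ids = ids,
                                k = inner_folds, seed = seed + f)$mean_accuracy
    } else NULL
    trace <- iterrelcen(tr, relief_cfg, N = N, evaluator = evaluator)
    traces[[f]] <- trace
    for (s in seq_along(trace$iterations)) {
      ids <- trace$iterations[[s]]$surviving
      cols <- match(ids, tr$feature_ids)
      fold_step_acc[f, s] <- train_eval_svm(.fm_subset(tr, cols),
                                            .fm_subset(te, cols), svm_cfg)
    }
  }
  structure(list(step_sizes = vapply(traces[[1L]]$iterations,
                                     function(it) length(it$surviving), 0L),
                 fold_step_acc = fold_step_acc,
                 mean_step_acc = colMeans(fold_step_acc),
                 fold_assignments = folds,
                 traces = traces, N = N,
                 n_bands = fm$n_bands),
            class = "SelectionCV")
}

#' @export
print.SelectionCV <- function(x, ...) {
  best <- which.max(x$mean_step_acc)
  cat(sprintf("SelectionCV: %d folds x %d steps (N = %d)\n",
              nrow(x$fold_step_acc), length(x$step_sizes), x$N))
  cat(sprintf("  best mean accuracy %.3f at %d surviving features\n",
              x$mean_step_acc[best], x$step_sizes[best]))
  invisible(x)
}

#' Select the optimal feature and channel set
#'
#' "Optimal" means best accuracy with the fewest channels: among the steps
#' whose mean accuracy ties the maximum (within `1e-12`), the step whose
#' surviving features span the smallest channel set wins.
#'
#' The default method takes explicit step-wise accuracies and feature sets.
#' The `SelectionCV` method picks the step from the cross-validated mean
#' accuracy curve and then reruns [iterrelcen()] once on the full data
#' (folds generally disagree on feature identities) to obtain a single
#' reportable feature/channel set of that step's size; the accuracy remains
#' the cross-validated estimate, the identities are a full-data point
#' estimate.
#'
#' @param x Step-wise mean accuracies (numeric vector), or a `SelectionCV`
#'   object.
#' @param features List of surviving feature-id vectors, one per step.
#' @param n_bands Bands per channel.
#' @param ... Passed between methods.
#' @return A list: `step`, `accuracy`, `features`, `channels`, and
#'   `bands_per_channel` (which bands each optimal channel retains).
#' @examples
#' steps <- list(1:26, c(1:10, 14:19), c(2, 15, 16))
#' select_optimal(c(0.80, 0.85, 0.85), steps, n_bands = 13)$channels
#' @export
select_optimal <- function(x, ...) UseMethod("select_optimal")

#' @rdname select_optimal
#' @export
select_optimal.default <- function(x, features, n_bands = 13L, ...) {
  if (!length(x)) stop("empty step list", call. = FALSE)
  if (length(features) != length(x))
    stop("one feature set per accuracy step is required", call. = FALSE)
  best <- which(x >= max(x) - 1e-12)
  n_ch <- vapply(best, function(s)
    length(features_to_channels(features[[s]], n_bands)), 0L)
  step <- best[order(n_ch, lengths(features[best]), best)[1L]]
  feats <- sort(features[[step]])
  ch <- features_to_channels(feats, n_bands)
  bands <- lapply(ch, function(c)
    sort(((feats[(feats - 1L) %/% n_bands + 1L == c] - 1L) %% n_bands) + 1L))
  names(bands) <- as.character(ch)
  list(step = step, accuracy = x[step], features = feats, channels = ch,
       bands_per_channel = bands)
}

#' @rdname select_optimal
#' @param fm The unnormalized [feature_matrix()] the `SelectionCV` was run
#'   on (for the final full-data pass).
#' @param relief_cfg The [relief_config()] used.
#' @export
select_optimal.SelectionCV <- function(x, fm, relief_cfg = relief_config(),
                                       ...) {
  stopifnot(inherits(fm, "FeatureMatrix"))
  full <- iterrelcen(minmax_normalize(fm), relief_cfg, N = x$N,
                     evaluator = NULL)
  features <- lapply(full$iterations, function(it) it$surviving)
  out <- select_optimal.default(x$mean_step_acc, features,
                                n_bands = x$n_bands)
  out$fold_accuracies <- x$fold_step_acc[, out$step]
  out
}

#' Per-channel weight map
#'
#' Aggregates feature weights to channels for topographic display: a
#' channel's weight is the sum of the weights of its surviving features
#' (e.g. three retained bands weighing 0.001, 0.002 and 0.003 give channel
#' weight 0.006); channels with no surviving feature get 0.
#'
#' @param weights A `WeightVector` from [relieff_weights()] (its
#'   `feature_ids` locate the surviving features).
#' @param n_channels Total number of channels.
#' @param n_bands Bands per channel.
#' @return Numeric vector of length `n_channels`.
#' @export
channel_weight_map <- function(weights, n_channels, n_bands = 13L) {
  stopifnot(inherits(weights, "WeightVector"))
  n_channels <- .assert_count(n_channels, "n_channels")
  ch <- (weights$feature_ids - 1L) %/% n_bands + 1L
  if (any(ch > n_channels))
    stop("feature ids exceed the channel layout", call. = FALSE)
  out <- numeric(n_channels)
  agg <- tapply(weights$weights, ch, sum)
  out[as.integer(names(agg))] <- agg
  out
}

#' Accuracy as channels are added by decreasing weight
#'
#' Channels are ranked by `channel_weights` (ties by ascending channel
#' index); for every `c` from 1 to the channel count, the cross-validated
#' accuracy using all bands of the top-`c` channels is computed. The
#' resulting curve shows where accuracy peaks and how it degrades as noisy
#' channels join.
#'
#' @param fm An unnormalized [feature_matrix()].
#' @param channel_weights Numeric per-channel weights (see
#'   [channel_weights()]).
#' @param cfg An [svm_config()].
#' @param k,seed Cross-validation folds and seed.
#' @return A data.frame with columns `n_channels`, `mean_accuracy`,
#'   `sd_accuracy`, and `channel_added`.
#' @export
accuracy_vs_channels <- function(fm, channel_weights, cfg = svm_config(),
                                 k = 10L, seed = 1L) {
  stopifnot(inherits(fm, "FeatureMatrix"))
  nch <- ncol(fm$values) / fm$n_bands
  if (length(channel_weights) != nch)
    stop(sprintf("expected %d channel weights, got %d", nch,
                 length(channel_weights)), call. = FALSE)
  ord <- order(-channel_weights, seq_along(channel_weights))
  res <- lapply(seq_len(nch), function(c) {
    ids <- feature_index(rep(ord[seq_len(c)], each = fm$n_bands),
                         rep(seq_len(fm$n_bands), c), fm$n_bands)
    cv <- cv_accuracy(fm, cfg, feature_ids = sort(ids), k = k, seed = seed)
    c(mean = cv$mean_accuracy, sd = sd(cv$fold_accuracies))
  })
  data.frame(n_channels = seq_len(nch),
             mean_accuracy = vapply(res, `[[`, 0, "mean"),
             sd_accuracy = vapply(res, `[[`, 0, "sd"),
             channel_added = ord)
}

#' Count channels retaining each frequency band
#'
#' For a set of optimal features, counts per band how many distinct
#' channels kept that band -- the bar heights of a band-usage summary. Mu-
#' and beta-range bands are expected to dominate in motor imagery.
#'
#' @param feature_ids Global feature indices of the optimal set.
#' @param n_bands Bands per channel.
#' @return Integer vector of length `n_bands`.
#' @examples
#' band_usage_counts(c(feature_index(1, 5), feature_index(2, 5),
#'                     feature_index(1, 6)))
#' @export
band_usage_counts <- function(feature_ids, n_bands = 13L) {
  feature_ids <- unique(as.integer(feature_ids))
  if (!length(feature_ids)) return(integer(n_bands))
  tabulate(((feature_ids - 1L) %% n_bands) + 1L, nbins = n_bands)
}
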
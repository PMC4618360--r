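# Relieff feature weighting and the iterative, center-targeted selection
# loop (IterRelCen), plus feature-to-channel aggregation.
#
# Distances everywhere are the sum over current features of the
# range-normalized absolute difference
#   d(f, R, Ro) = |value(f, R) - value(f, Ro)| / (max(f) - min(f)),
# i.e. Manhattan distance on range-scaled values, with ranges taken over the
# current training set and current (surviving) features. Ties in neighbor
# search, center ordering and removal always break by ascending index, so
# every result is reproducible.

#' Relieff configuration
#'
#' @param k Number of nearest hits/misses per target sample; must stay below
#'   the smallest class size.
#' @param m Number of target samples per weighting pass; `NULL` (default)
#'   means every training sample is used.
#' @param seed RNG seed for random target sampling in [relieff_weights()]
#'   (unused by the deterministic [iterrelcen()] loop).
#' @return An object of class `ReliefConfig`.
#' @export
relief_config <- function(k = 10L, m = NULL, seed = 1L) {
  k <- .assert_count(k, "k")
  if (!is.null(m)) m <- .assert_count(m, "m")
  structure(list(k = k, m = m, seed = seed), class = "ReliefConfig")
}

.check_relief_cfg <- function(cfg, labels) {
  stopifnot(inherits(cfg, "ReliefConfig"))
  sizes <- table(labels)
  if (length(sizes) < 2L)
    stop("at least 2 classes are required for Relieff weighting", call. = FALSE)
  if (any(sizes < cfg$k + 1L))
    stop(sprintf("every class needs at least k + 1 = %d members (smallest has %d)",
                 cfg$k + 1L, min(sizes)), call. = FALSE)
  m <- if (is.null(cfg$m)) length(labels) else cfg$m
  if (m > length(labels))
    stop("`m` cannot exceed the number of training samples", call. = FALSE)
  m
}

#' Range-normalized per-feature difference
#'
#' `|value(f, R) - value(f, Ro)| / (max(f) - min(f))`, the per-feature
#' distance contribution used throughout Relieff. A degenerate feature
#' (`max == min`) contributes 0 with a warning.
#'
#' @param f Feature (column) index.
#' @param R,Ro Sample feature vectors.
#' @param range Numeric pair `(min, max)` of feature `f` over the current
#'   training set.
#' @return A number in `[0, 1]` when the samples lie within `range`.
#' @examples
#' feature_diff(1, c(0.3), c(0.7), range = c(0, 1))  # 0.4
#' @export
feature_diff <- function(f, R, Ro, range) {
  if (range[2L] <= range[1L]) {
    warning("degenerate feature range (max <= min); difference defined as 0")
    return(0)
  }
  abs(R[f] - Ro[f]) / (range[2L] - range[1L])
}

# columns scaled by feature range; constant columns -> all zero (they can
# never separate samples, matching feature_diff's degenerate rule)
.range_scale <- function(x) {
  rng <- apply(x, 2L, max) - apply(x, 2L, min)
  rng[rng <= 0] <- Inf
  sweep(x, 2L, rng, "/")
}

#' Nearest neighbors under the Relieff distance
#'
#' Returns the `k` rows of `values` among `pool` closest to row `target`
#' under the sum of range-normalized absolute feature differences
#' (Manhattan distance on range-scaled columns, ranges over all rows of
#' `values`). Distance ties break by ascending row index.
#'
#' @param values Numeric sample-by-feature matrix (the current training set).
#' @param target Row index of the target sample.
#' @param pool Candidate row indices; must not contain `target`.
#' @param k Number of neighbors.
#' @return Integer vector of `k` row indices.
#' @export
nearest_neighbors <- function(values, target, pool, k) {
  k <- .assert_count(k, "k")
  if (target %in% pool)
    stop("`pool` must exclude the target sample", call. = FALSE)
  if (length(pool) < k)
    stop(sprintf("pool of %d candidate(s) cannot supply k = %d neighbors",
                 length(pool), k), call. = FALSE)
  xs <- .range_scale(values)
  d <- rowSums(abs(xs[pool, , drop = FALSE] -
                     rep(xs[target, ], each = length(pool))))
  pool[order(d, pool)[seq_len(k)]]
}

#' Relieff feature weights
#'
#' Scores each feature by its ability to separate nearby samples of
#' different classes. Weights start at zero; for each target sample `R`,
#' the averaged distance to its `k` nearest same-class neighbors (near
#' hits) is subtracted and the averaged, prior-weighted distance to the `k`
#' nearest neighbors of every other class (near misses) is added:
#'
#' \deqn{W(f) \mathrel{-}= \sum_j d(f, R, H_j) / (m k), \quad
#'       W(f) \mathrel{+}= \sum_{C \ne class(R)}
#'       \frac{p(C)}{1 - p(class(R))} \sum_j d(f, R, M_j(C)) / (m k)}
#'
#' with `p` the empirical class priors of the training set. On two-class
#' input this reduces to classic Relief weighting. On min--max normalized
#' input every weight lies in `[-1, 1]`.
#'
#' @param fm A [feature_matrix()] (normally min--max normalized).
#' @param cfg A [relief_config()].
#' @param targets Optional explicit target row indices; when omitted, `m`
#'   targets are drawn uniformly without replacement using `cfg$seed`.
#' @return A `WeightVector`: list with `weights` and the matching global
#'   `feature_ids`.
#' @export
relieff_weights <- function(fm, cfg = relief_config(), targets = NULL) {
  stopifnot(inherits(fm, "FeatureMatrix"))
  m <- .check_relief_cfg(cfg, fm$labels)
  x <- fm$values
  y <- fm$labels
  n <- nrow(x)
  if (is.null(targets)) {
    set.seed(cfg$seed)
    targets <- sample.int(n, m)
  } else {
    if (any(targets < 1L | targets > n))
      stop("`targets` contains out-of-range sample indices", call. = FALSE)
    m <- length(targets)
  }
  xs <- .range_scale(x)
  classes <- sort(unique(y))
  idx_by_class <- lapply(classes, function(cl) which(y == cl))
  priors <- vapply(idx_by_class, length, 0L) / n
  names(priors) <- classes
  k <- cfg$k
  w <- numeric(ncol(x))
  for (R in targets) {
    diffs <- abs(xs - rep(xs[R, ], each = n))   # n x f per-feature d()
    d <- rowSums(diffs)
    ci <- match(y[R], classes)
    hit_pool <- setdiff(idx_by_class[[ci]], R)
    hits <- hit_pool[order(d[hit_pool], hit_pool)[seq_len(k)]]
    w <- w - colSums(diffs[hits, , drop = FALSE]) / (m * k)
    for (cj in seq_along(classes)[-ci]) {
      pool <- idx_by_class[[cj]]
      misses <- pool[order(d[pool], pool)[seq_len(k)]]
      w <- w + priors[cj] / (1 - priors[ci]) *
        colSums(diffs[misses, , drop = FALSE]) / (m * k)
    }
  }
  structure(list(weights = unname(w), feature_ids = fm$feature_ids),
            class = "WeightVector")
}

#' @export
print.WeightVector <- function(x, ...) {
  cat(sprintf("WeightVector: %d features, weights in [%.4g, %.4g]\n",
              length(x$weights), min(x$weights), max(x$weights)))
  invisible(x)
}

#' Order the samples of a class by distance to the class center
#'
#' The class center is the per-feature mean of the class's samples
#' (`Ct = 1/n * sum(S_i)` over current features); samples are ranked by
#' ascending Relieff distance (sum of range-normalized absolute
#' differences) to `Ct`, ties by ascending index. Samples near the center
#' are the most typical of their class, which is why the iterative selector
#' targets them first instead of sampling at random.
#'
#' @param fm A [feature_matrix()].
#' @param cls Class label.
#' @return Integer vector of the class's row indices, nearest-to-center
#'   first.
#' @export
class_center_order <- function(fm, cls) {
  stopifnot(inherits(fm, "FeatureMatrix"))
  idx <- which(fm$labels == cls)
  if (!length(idx))
    stop(sprintf("class '%s' has no samples", cls), call. = FALSE)
  xs <- .range_scale(fm$values)
  ct <- colMeans(xs[idx, , drop = FALSE])
  d <- rowSums(abs(xs[idx, , drop = FALSE] - rep(ct, each = length(idx))))
  idx[order(d, idx)]
}

#' Iterative centered Relief feature elimination
#'
#' Runs Relieff weighting repeatedly, each pass discarding the `N`
#' lowest-weight features, until no features remain. Two changes harden the
#' weighting against noise compared to plain Relieff: target samples are
#' taken deterministically in order of closeness to their class center
#' (atypical, noise-dominated samples are never targets), and weights,
#' ranges and centers are recomputed from scratch on the surviving features
#' each iteration, so discarded noisy features stop corrupting the distance
#' metric. The loop contains no randomness.
#'
#' Each iteration records the surviving feature set, its weights, the `N`
#' features removed (ties by ascending feature index), and the evaluator's
#' accuracy on the surviving set -- the first iteration therefore evaluates
#' the full feature set before anything is removed. There are
#' `ceiling(n_features / N)` iterations.
#'
#' @param fm A [feature_matrix()] (normally min--max normalized training
#'   data).
#' @param cfg A [relief_config()]; `m` targets are allotted to classes
#'   proportionally (`m_c = round(m * n_c / n)`) and taken from the head of
#'   each class's center order.
#' @param N Number of lowest-weight features removed per iteration.
#' @param evaluator Optional `function(feature_ids) -> accuracy` called on
#'   every surviving set; `NULL` records `NA` accuracies.
#' @param targets Optional fixed target rows overriding center ordering
#'   (used for equivalence checks against [relieff_weights()]).
#' @return A `SelectionTrace`: list with `iterations` (each a list
#'   `surviving`, `weights`, `removed`, `accuracy`), `N`, and `n_features`.
#' @examples
#' fm <- feature_matrix(matrix(rnorm(40 * 26), 40), rep(1:2, 20), n_bands = 13)
#' fm <- minmax_normalize(fm)
#' tr <- iterrelcen(fm, relief_config(k = 3), N = 10)
#' vapply(tr$iterations, function(it) length(it$surviving), 0L)  # 26 16 6
#' @export
iterrelcen <- function(fm, cfg = relief_config(), N = 10L, evaluator = NULL,
                       targets = NULL) {
  stopifnot(inherits(fm, "FeatureMatrix"))
  N <- .assert_count(N, "N")
  nf <- ncol(fm$values)
  if (N > nf) stop("`N` cannot exceed the number of features", call. = FALSE)
  m <- .check_relief_cfg(cfg, fm$labels)
  n <- nrow(fm$values)
  classes <- sort(unique(fm$labels))
  surviving <- seq_len(nf)          # column positions; global ids via feature_ids
  iterations <- vector("list", ceiling(nf / N))
  it <- 0L
  while (length(surviving)) {
    it <- it + 1L
    cur <- .fm_subset(fm, surviving)
    if (is.null(targets)) {
      tg <- unlist(lapply(classes, function(cl) {
        ord <- class_center_order(cur, cl)
        utils::head(ord, round(m * length(ord) / n))
      }))
    } else tg <- targets
    wv <- relieff_weights(cur, cfg, targets = tg)
    acc <- if (is.null(evaluator)) NA_real_ else evaluator(cur$feature_ids)
    drop_n <- min(N, length(surviving))
    drop_pos <- order(wv$weights, seq_along(wv$weights))[seq_len(drop_n)]
    iterations[[it]] <- list(surviving = cur$feature_ids,
                             weights = wv,
                             removed = cur$feature_ids[sort(drop_pos)],
                             accuracy = acc)
    surviving <- surviving[-drop_pos]
  }
  structure(list(iterations = iterations, N = N, n_features = nf),
            class = "SelectionTrace")
}

#' @export
print.SelectionTrace <- function(x, ...) {
  sizes <- vapply(x$iterations, function(it) length(it$surviving), 0L)
  accs <- vapply(x$iterations, function(it) it$accuracy, 0)
  cat(sprintf("SelectionTrace: %d features, N = %d, %d iterations\n",
              x$n_features, x$N, length(x$iterations)))
  cat("  surviving:", paste(utils::head(sizes, 10L), collapse = " "),
      if (length(sizes) > 10L) "..." else "", "\n")
  if (!all(is.na(accs)))
    cat(sprintf("  accuracy: %.3f .. %.3f (best %.3f at %d features)\n",
                accs[1L], accs[length(accs)], max(accs, na.rm = TRUE),
                sizes[which.max(accs)]))
  invisible(x)
}

#' Summarize a selection trace
#'
#' @param trace A `SelectionTrace` from [iterrelcen()].
#' @return A data.frame with one row per iteration: surviving feature count,
#'   surviving channel count, and evaluator accuracy.
#' @param n_bands Bands per channel for the channel count.
#' @export
trace_steps <- function(trace, n_bands = 13L) {
  stopifnot(inherits(trace, "SelectionTrace"))
  data.frame(
    iteration = seq_along(trace$iterations),
    n_features = vapply(trace$iterations, function(it) length(it$surviving), 0L),
    n_channels = vapply(trace$iterations, function(it)
      length(features_to_channels(it$surviving, n_bands)), 0L),
    accuracy = vapply(trace$iterations, function(it) it$accuracy, 0))
}

#' Channels holding at least one of the given features
#'
#' Under the channel-major layout, feature `i` belongs to channel
#' `floor((i - 1) / n_bands) + 1`.
#'
#' @param feature_ids Global feature indices.
#' @param n_bands Bands per channel.
#' @return Sorted unique channel indices.
#' @examples
#' features_to_channels(c(1, 14, 26), n_bands = 13)  # channels 1 and 2
#' @export
features_to_channels <- function(feature_ids, n_bands = 13L) {
  if (!length(feature_ids)) return(integer(0))
  if (any(feature_ids < 1L))
    stop("feature indices are 1-based", call. = FALSE)
  sort(unique(as.integer((feature_ids - 1L) %/% n_bands + 1L)))
}

#' Per-channel weights from a single centered Relieff pass
#'
#' Convenience wrapper producing the channel ranking used for
#' accuracy-versus-channel-count curves: one Relieff pass over the full
#' feature set with center-ordered targets (the first [iterrelcen()]
#' iteration), followed by [channel_weight_map()].
#'
#' @param fm A min--max normalized [feature_matrix()] over all features.
#' @param cfg A [relief_config()].
#' @param n_channels Number of channels (default inferred from the layout).
#' @return Numeric vector of per-channel weights.
#' @export
channel_weights <- function(fm, cfg = relief_config(),
                            n_channels = ncol(fm$values) / fm$n_bands) {
  tr <- iterrelcen(fm, cfg, N = ncol(fm$values), evaluator = NULL)
  channel_weight_map(tr$iterations[[1L]]$weights, n_channels = n_channels,
                     n_bands = fm$n_bands)
}
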
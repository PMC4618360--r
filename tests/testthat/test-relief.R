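test_that("feature_diff implements the range-normalized difference", {
  expect_equal(feature_diff(1, 0.3, 0.7, range = c(0, 1)), 0.4)
  expect_equal(feature_diff(1, 0.5, 0.5, range = c(0, 1)), 0)
  expect_equal(feature_diff(1, 5, 9, range = c(1, 9)), 0.5)
  expect_warning(d <- feature_diff(1, 3, 4, range = c(2, 2)), "degenerate")
  expect_equal(d, 0)
})

test_that("nearest_neighbors sorts by aggregate distance with index ties", {
  x <- matrix(c(0.0, 0.1, 0.5, 0.9), ncol = 1)
  expect_equal(nearest_neighbors(x, target = 1, pool = 2:4, k = 2), c(2L, 3L))
  # duplicate distances (exactly representable): lower index wins
  xd <- matrix(c(0.5, 0.25, 0.75, 0, 1), ncol = 1)
  expect_equal(nearest_neighbors(xd, target = 1, pool = 2:5, k = 1), 2L)
  expect_error(nearest_neighbors(x, 1, 2:3, k = 3), "cannot supply")
  expect_error(nearest_neighbors(x, 1, 1:3, k = 1), "exclude the target")
})

test_that("nearest_neighbors agrees with exhaustive search on random pools", {
  for (seed in 1:5) {
    set.seed(seed)
    x <- matrix(runif(12 * 5), ncol = 5)
    rng <- apply(x, 2, max) - apply(x, 2, min)
    got <- nearest_neighbors(x, target = 1, pool = 2:12, k = 3)
    d <- vapply(2:12, function(i) sum(abs(x[1, ] - x[i, ]) / rng), 0)
    want <- (2:12)[order(d, 2:12)][1:3]
    expect_equal(got, want)
  }
})

test_that("relieff weights match hand-evaluated updates", {
  # two equal classes, m = 1, k = 1, range 1: target 0.2, hit at 0
  # (d_hit = 0.2), nearest miss at 1.0 (d_miss = 0.8), prior factor
  # 0.5 / (1 - 0.5) = 1 -> W = -0.2 + 0.8 = 0.6
  fm <- feature_matrix(matrix(c(0.0, 0.2, 1.0, 1.0), ncol = 1),
                       c(1, 1, 2, 2), n_bands = 1)
  wv <- relieff_weights(fm, relief_config(k = 1, m = 1), targets = 2)
  expect_equal(wv$weights, 0.6, tolerance = 1e-12)

  # constant feature never separates anything: weight exactly 0
  fm2 <- feature_matrix(cbind(c(0, 0.2, 0.8, 1), rep(3, 4)),
                        c(1, 1, 2, 2), n_bands = 1)
  wv2 <- relieff_weights(fm2, relief_config(k = 1))
  expect_equal(wv2$weights[2], 0)

  # three equal classes: each miss term scaled by (1/3)/(2/3) = 1/2
  fm3 <- feature_matrix(matrix(c(0, 0.1, 0.5, 0.55, 0.9, 1.0), ncol = 1),
                        c(1, 1, 2, 2, 3, 3), n_bands = 1)
  wv3 <- relieff_weights(fm3, relief_config(k = 1, m = 1), targets = 1)
  # hit: 0.1; misses: 0.5 (class 2) and 0.9 (class 3), range 1
  expect_equal(wv3$weights, -0.1 + 0.5 * (0.5 + 0.9), tolerance = 1e-12)

  expect_error(relieff_weights(fm, relief_config(k = 2)), "k \\+ 1")
  one_class <- feature_matrix(matrix(1:4, ncol = 1), rep(1, 4), n_bands = 1)
  expect_error(relieff_weights(one_class, relief_config(k = 1)), "2 classes")
})

test_that("relieff equals the brute-force oracle on random instances", {
  for (seed in 1:4) {
    n <- c(20, 30, 40, 50)[seed]
    classes <- if (seed %% 2) 2 else 3
    fm <- random_fm(n = n, f = 8, n_bands = 8, seed = seed, classes = classes,
                    normalize = TRUE)
    targets <- seq_len(n)
    got <- relieff_weights(fm, relief_config(k = 3), targets = targets)
    want <- oracle_relieff(fm$values, fm$labels, k = 3, targets = targets)
    expect_equal(got$weights, want, tolerance = 1e-12)
  }
})

test_that("relieff weights are bounded and symmetric features score zero", {
  # boundedness on normalized input
  for (seed in 1:3) {
    fm <- random_fm(n = 24, f = 10, n_bands = 10, seed = seed, normalize = TRUE)
    wv <- relieff_weights(fm, relief_config(k = 5))
    expect_true(all(wv$weights >= -1 & wv$weights <= 1))
  }
  # balanced two-class geometry where every target's nearest hit and
  # nearest miss lie at identical distances: both classes share the same
  # duplicated sample locations, so the feature cannot separate them
  x <- matrix(c(0, 0, 1, 1, 0, 0, 1, 1), ncol = 1)
  fm <- feature_matrix(x, rep(1:2, each = 4), n_bands = 1)
  wv <- relieff_weights(fm, relief_config(k = 1), targets = 1:8)
  expect_lt(abs(wv$weights), 1e-12)
})

test_that("ranking is invariant to positive affine feature rescaling", {
  fm <- planted_fm(n_per_class = 15, f = 12, informative = 1:3, seed = 7)
  fm2 <- fm
  set.seed(8)
  scale <- runif(12, 0.1, 50)
  shift <- rnorm(12, sd = 10)
  fm2$values <- sweep(sweep(fm$values, 2, scale, "*"), 2, shift, "+")
  w1 <- relieff_weights(fm, relief_config(k = 4), targets = 1:30)
  w2 <- relieff_weights(fm2, relief_config(k = 4), targets = 1:30)
  expect_equal(w1$weights, w2$weights, tolerance = 1e-9)
  expect_equal(order(w1$weights), order(w2$weights))
})

test_that("class_center_order ranks by distance to the class mean", {
  x <- rbind(c(0, 0), c(4, 0), c(0, 4), c(4, 4), c(2, 2))
  fm <- feature_matrix(x, c(1, 1, 1, 1, 1), n_bands = 2)
  # center of the first four is (2,2); the added center point ranks first
  expect_equal(class_center_order(fm, 1)[1], 5L)

  single <- feature_matrix(matrix(c(1, 9), 2), c(1, 2), n_bands = 1)
  expect_equal(class_center_order(single, 2), 2L)
  expect_error(class_center_order(single, 3), "no samples")

  # brute-force oracle on a random class
  set.seed(11)
  xr <- matrix(runif(10 * 4), ncol = 4)
  fmr <- feature_matrix(xr, rep(1, 10), n_bands = 4)
  rng <- apply(xr, 2, max) - apply(xr, 2, min)
  xs <- sweep(xr, 2, rng, "/")
  d <- rowSums(abs(sweep(xs, 2, colMeans(xs))))
  expect_equal(class_center_order(fmr, 1), order(d, 1:10))
})

test_that("iterrelcen eliminates in strictly nested steps of N", {
  fm <- random_fm(n = 30, f = 26, n_bands = 13, seed = 3, normalize = TRUE)
  tr <- iterrelcen(fm, relief_config(k = 5), N = 10)
  sizes <- vapply(tr$iterations, function(it) length(it$surviving), 0L)
  expect_equal(sizes, c(26L, 16L, 6L))
  expect_equal(length(tr$iterations), ceiling(26 / 10))
  for (i in seq_along(tr$iterations)[-1])
    expect_true(all(tr$iterations[[i]]$surviving %in%
                      tr$iterations[[i - 1]]$surviving))
  removed <- unlist(lapply(tr$iterations, function(it) it$removed))
  expect_equal(sort(removed), 1:26)   # final surviving set is empty
  expect_equal(lengths(lapply(tr$iterations, function(it) it$removed)),
               c(10L, 10L, 6L))
})

test_that("iterrelcen with N = n_features equals one relieff pass bit-for-bit", {
  fm <- random_fm(n = 24, f = 15, n_bands = 15, seed = 6, normalize = TRUE)
  tg <- c(3, 1, 17, 9, 22)
  tr <- iterrelcen(fm, relief_config(k = 4), N = 15, targets = tg)
  wv <- relieff_weights(fm, relief_config(k = 4), targets = tg)
  expect_equal(length(tr$iterations), 1L)
  expect_identical(tr$iterations[[1]]$weights$weights, wv$weights)
})

test_that("iterrelcen is deterministic and evaluates every surviving set", {
  fm <- random_fm(n = 20, f = 12, n_bands = 12, seed = 2, normalize = TRUE)
  calls <- list()
  evaluator <- function(ids) { calls[[length(calls) + 1]] <<- ids; 0.5 }
  tr1 <- iterrelcen(fm, relief_config(k = 3), N = 5, evaluator = evaluator)
  expect_equal(length(calls), 3L)
  expect_equal(calls[[1]], 1:12)      # full set evaluated before any removal
  expect_equal(calls[[2]], tr1$iterations[[2]]$surviving)
  tr2 <- iterrelcen(fm, relief_config(k = 3), N = 5)
  for (i in seq_along(tr1$iterations)) {
    expect_identical(tr1$iterations[[i]]$surviving, tr2$iterations[[i]]$surviving)
    expect_identical(tr1$iterations[[i]]$weights$weights,
                     tr2$iterations[[i]]$weights$weights)
  }
})

test_that("iterrelcen keeps planted features alive longer than noise", {
  informative <- 1:5
  survived_longer <- vapply(1:20, function(seed) {
    fm <- minmax_normalize(planted_fm(n_per_class = 20, f = 50,
                                      informative = informative,
                                      effect = 1.5, seed = seed))
    tr <- iterrelcen(fm, relief_config(k = 5), N = 5)
    # removal order: position at which each feature is dropped
    removal_rank <- integer(50)
    for (i in seq_along(tr$iterations))
      removal_rank[tr$iterations[[i]]$removed] <- i
    # all informative outlive at least 40 noise features
    min(removal_rank[informative]) > sort(removal_rank[-informative])[40]
  }, TRUE)
  expect_gte(mean(survived_longer), 0.9)
})

test_that("features_to_channels maps the channel-major layout", {
  expect_equal(features_to_channels(c(1, 14, 26), 13), c(1L, 2L))
  expect_equal(features_to_channels(integer(0)), integer(0))
  expect_equal(features_to_channels(1:767, 13), 1:59)
  expect_error(features_to_channels(0), "1-based")
})

test_that("channel weights sum the surviving band weights per channel", {
  wv <- structure(list(weights = c(0.001, 0.002, 0.003),
                       feature_ids = c(feature_index(2, 3), feature_index(2, 7),
                                       feature_index(4, 1))),
                  class = "WeightVector")
  cw <- channel_weight_map(wv, n_channels = 5)
  expect_equal(cw, c(0, 0.003, 0, 0.003, 0))
  # all features surviving with weight w -> every channel weight 13w
  wv2 <- structure(list(weights = rep(0.01, 26), feature_ids = 1:26),
                   class = "WeightVector")
  expect_equal(channel_weight_map(wv2, n_channels = 2), c(0.13, 0.13))
})
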
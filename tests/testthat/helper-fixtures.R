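# Shared fixtures, built in code at test time.

# sinusoidal trial set: one channel per entry of `freqs`, all trials equal
sine_trials <- function(freqs, rate = 200, dur = 2, n_trials = 2,
                        labels = NULL, amp = 1, phase = 0.3) {
  n <- round(dur * rate)
  t <- seq_len(n) / rate
  arr <- array(0, c(n_trials, length(freqs), n))
  for (ch in seq_along(freqs))
    for (tr in seq_len(n_trials))
      arr[tr, ch, ] <- amp * sin(2 * pi * freqs[ch] * t + phase)
  if (is.null(labels)) labels <- rep_len(1:2, n_trials)
  trial_set(arr, labels, rate)
}

random_trials <- function(n_trials = 4, n_channels = 3, n_samples = 200,
                          rate = 100, seed = 1) {
  set.seed(seed)
  trial_set(array(rnorm(n_trials * n_channels * n_samples),
                  c(n_trials, n_channels, n_samples)),
            rep_len(1:2, n_trials), rate)
}

# small random feature matrix, optionally normalized
random_fm <- function(n = 20, f = 13, n_bands = 13, seed = 1, classes = 2,
                      normalize = FALSE) {
  set.seed(seed)
  fm <- feature_matrix(matrix(rnorm(n * f), n), rep_len(seq_len(classes), n),
                       n_bands = n_bands)
  if (normalize) minmax_normalize(fm) else fm
}

# two well-separated Gaussian blobs in feature space
blob_fm <- function(n_per_class = 30, f = 5, sep = 6, seed = 1, n_bands = 1) {
  set.seed(seed)
  x <- rbind(matrix(rnorm(n_per_class * f), ncol = f),
             matrix(rnorm(n_per_class * f, mean = sep), ncol = f))
  feature_matrix(x, rep(1:2, each = n_per_class), n_bands = n_bands)
}

# feature matrix with planted informative columns: class means differ on
# `informative` columns, pure noise elsewhere
planted_fm <- function(n_per_class = 25, f = 50, informative = 1:5,
                       effect = 2, seed = 1, n_bands = 1) {
  set.seed(seed)
  x <- matrix(rnorm(2 * n_per_class * f), ncol = f)
  x[seq_len(n_per_class), informative] <-
    x[seq_len(n_per_class), informative] + effect
  feature_matrix(x, rep(1:2, each = n_per_class), n_bands = n_bands)
}

.subset_rows_for_test <- function(fm, rows) {
  feature_matrix(fm$values[rows, , drop = FALSE], fm$labels[rows], fm$n_bands,
                 feature_ids = fm$feature_ids)
}

# brute-force Relieff oracle: plain loops, no shared code with the package
oracle_relieff <- function(x, y, k, targets) {
  n <- nrow(x); f <- ncol(x)
  rng <- apply(x, 2, max) - apply(x, 2, min)
  d_pair <- function(a, b) {
    out <- abs(x[a, ] - x[b, ]) / rng
    out[rng <= 0] <- 0
    out
  }
  dist_pair <- function(a, b) sum(d_pair(a, b))
  priors <- table(y) / n
  w <- numeric(f)
  m <- length(targets)
  for (R in targets) {
    same <- setdiff(which(y == y[R]), R)
    ds <- vapply(same, function(s) dist_pair(R, s), 0)
    hits <- same[order(ds, same)][seq_len(k)]
    for (h in hits) w <- w - d_pair(R, h) / (m * k)
    for (cl in setdiff(sort(unique(y)), y[R])) {
      pool <- which(y == cl)
      ds <- vapply(pool, function(s) dist_pair(R, s), 0)
      misses <- pool[order(ds, pool)][seq_len(k)]
      fac <- priors[[as.character(cl)]] / (1 - priors[[as.character(y[R])]])
      for (mm in misses) w <- w + fac * d_pair(R, mm) / (m * k)
    }
  }
  unname(w)
}

# band power of one channel in [lo, hi] Hz via the raw periodogram
band_power <- function(ts, channel, lo, hi) {
  d <- dim(ts$data)
  freqs <- (seq_len(d[3]) - 1) * ts$rate / d[3]
  sel <- freqs >= lo & freqs <= hi
  mean(apply(ts$data[, channel, , drop = FALSE], 1, function(x) {
    p <- Mod(fft(as.numeric(x)))^2 / length(x)^2
    sum(p[sel])
  }))
}
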
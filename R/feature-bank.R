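# Constant-Q sub-band decomposition, Hilbert-envelope band power features,
# and min-max normalization.

#' Design a constant-Q (proportional-bandwidth) filter bank
#'
#' Builds `n_bands` overlapping sub-bands whose bandwidth is a fixed
#' fraction of their center frequency: center `k` is
#' `f_start_center * ratio^(k-1)` and band `k` spans
#' `center_k * (1 +/- frac_bw / 2)`. With the defaults the 13 bands tile
#' 5--35 Hz, the range carrying mu (8--12 Hz) and beta (18--26 Hz)
#' sensorimotor rhythms; consecutive bands overlap, each lower edge
#' coinciding with the previous center (because `ratio * (1 - frac_bw/2) = 1`
#' at the defaults).
#'
#' @param f_start_center Center frequency of the first band in Hz.
#' @param ratio Geometric ratio between consecutive centers.
#' @param frac_bw Fractional bandwidth `(high - low) / center`.
#' @param n_bands Number of bands.
#' @return A `FilterBank`: list with `bands` (`n_bands x 2` matrix of
#'   low/high edges in Hz), `centers`, and `frac_bw`.
#' @examples
#' fb <- design_constant_q_bank()
#' round(fb$bands[c(1, 13), ], 2)  # 5.25-6.75 and 26.07-33.51 Hz
#' @export
design_constant_q_bank <- function(f_start_center = 6.0, ratio = 8 / 7,
                                   frac_bw = 0.25, n_bands = 13L) {
  .assert_scalar_num(f_start_center, "f_start_center", lower = 0, strict = TRUE)
  .assert_scalar_num(ratio, "ratio", lower = 1, strict = TRUE)
  .assert_scalar_num(frac_bw, "frac_bw", lower = 0, strict = TRUE)
  if (frac_bw >= 2) stop("`frac_bw` must be below 2", call. = FALSE)
  n_bands <- .assert_count(n_bands, "n_bands")
  centers <- f_start_center * ratio^(seq_len(n_bands) - 1)
  bands <- cbind(low = centers * (1 - frac_bw / 2),
                 high = centers * (1 + frac_bw / 2))
  structure(list(bands = bands, centers = centers, frac_bw = frac_bw),
            class = "FilterBank")
}

#' @export
print.FilterBank <- function(x, ...) {
  cat(sprintf("FilterBank: %d constant-Q bands, %.3g--%.3g Hz (Q = %.3g)\n",
              length(x$centers), x$bands[1, 1], x$bands[nrow(x$bands), 2],
              1 / x$frac_bw))
  invisible(x)
}

.n_bands <- function(bank) length(bank$centers)

# |H|^2 of a digital Butterworth band-pass evaluated on the n-point FFT grid.
# Squaring matches a forward-backward (zero-phase) application.
.butter_bp_gain <- function(n, rate, low, high, order = 4L) {
  ba <- signal::butter(order, c(low, high) / (rate / 2), type = "pass")
  w <- 2 * pi * (seq_len(n) - 1L) / n
  hb <- exp(-1i * outer(w, seq_along(ba$b) - 1L)) %*% ba$b
  ha <- exp(-1i * outer(w, seq_along(ba$a) - 1L)) %*% ba$a
  as.numeric(Mod(hb / ha)^2)
}

# Even-reflection extension of the columns of x to twice their length; the
# extension is whole-sample symmetric, so any real symmetric spectral gain
# maps it to the even extension of the filtered signal -- circular filtering
# on the extension equals zero-phase filtering without wrap discontinuities.
.pad_even <- function(x) rbind(x, x[nrow(x):1L, , drop = FALSE])

# spectral weights turning an n-point FFT into the analytic signal
.analytic_h <- function(n) {
  h <- numeric(n)
  if (n %% 2L == 0L) {
    h[c(1L, n / 2L + 1L)] <- 1
    h[2L:(n / 2L)] <- 2
  } else {
    h[1L] <- 1
    h[2L:((n + 1L) / 2L)] <- 2
  }
  h
}

# Zero-phase filtering of the columns of [n x m] matrix X in the frequency
# domain, via the even extension.
.fd_filter_mat <- function(x, gain2n) {
  n <- nrow(x)
  f <- stats::mvfft(.pad_even(x)) * gain2n
  Re(stats::mvfft(f, inverse = TRUE))[seq_len(n), , drop = FALSE] / (2 * n)
}

#' Zero-phase band-pass filter a trial set
#'
#' Applies a zero-phase Butterworth band-pass (monotonic passband, i.e.
#' ripple-free; the squared magnitude response of the given order) to every
#' trial and channel independently. Realized in the frequency domain on
#' even-reflected trials, which is equivalent to forward-backward filtering
#' without start-up transients.
#'
#' @param ts A [trial_set()].
#' @param band Numeric pair `(low_hz, high_hz)`, `0 < low < high <` Nyquist.
#' @param order Butterworth prototype order (effective roll-off is doubled
#'   by the zero-phase squaring).
#' @return A filtered [trial_set()].
#' @export
bandpass <- function(ts, band, order = 4L) {
  stopifnot(is_trial_set(ts))
  if (length(band) != 2L || !is.numeric(band))
    stop("`band` must be a numeric pair (low, high) in Hz", call. = FALSE)
  if (band[1L] <= 0 || band[1L] >= band[2L])
    stop("band edges must satisfy 0 < low < high", call. = FALSE)
  if (band[2L] >= ts$rate / 2)
    stop(sprintf("band upper edge (%g Hz) reaches the Nyquist frequency (%g Hz)",
                 band[2L], ts$rate / 2), call. = FALSE)
  d <- dim(ts$data)
  flat <- matrix(aperm(ts$data, c(3L, 1L, 2L)), nrow = d[3L])
  gain <- .butter_bp_gain(2L * d[3L], ts$rate, band[1L], band[2L], order)
  out <- .fd_filter_mat(flat, gain)
  trial_set(aperm(array(out, c(d[3L], d[1L], d[2L])), c(2L, 3L, 1L)),
            ts$labels, ts$rate, ts$channel_names)
}

# analytic-signal magnitude for every column of [n x m] matrix; the plain
# circular transform is used on purpose -- reflection padding time-reverses
# the phase progression of an oscillation and distorts the envelope near
# the junction, whereas the circular wrap error stays confined to the ends
.envelope_mat <- function(x) {
  n <- nrow(x)
  h <- .analytic_h(n)
  Mod(stats::mvfft(stats::mvfft(x) * h, inverse = TRUE)) / n
}

#' Hilbert envelope of a real signal
#'
#' Magnitude of the analytic signal, computed via the FFT. For a
#' narrow-band signal the envelope tracks the instantaneous amplitude, so
#' its square tracks instantaneous band power.
#'
#' @param x Finite numeric vector, length >= 8.
#' @return Nonnegative numeric vector of the same length.
#' @examples
#' t <- seq(0, 2, by = 1 / 200)
#' summary(hilbert_envelope(sin(2 * pi * 10 * t)))
#' @export
hilbert_envelope <- function(x) {
  if (!is.numeric(x) || length(x) < 8L)
    stop("`x` must be a numeric signal of length >= 8", call. = FALSE)
  if (any(!is.finite(x)))
    stop("`x` contains non-finite values", call. = FALSE)
  as.numeric(.envelope_mat(matrix(x, ncol = 1L)))
}

# Feature matrix -------------------------------------------------------------

#' Construct a feature matrix
#'
#' Holds the `trials x features` table produced by [extract_features()],
#' with the map tying each column to its (channel, band) pair. Columns are
#' channel-major: feature `(ch - 1) * n_bands + b` is band `b` of channel
#' `ch`; `feature_ids` keeps the global column identities when the matrix
#' is subset during selection.
#'
#' @param values Numeric matrix `[n_trials, n_features]`.
#' @param labels Integer class label per trial.
#' @param n_bands Number of bands per channel.
#' @param channel_names Optional channel names (length `n_features / n_bands`
#'   when the matrix is complete).
#' @param feature_ids Global feature indices of the columns (default
#'   `1:n_features`).
#' @param norm_params Optional normalization record from
#'   [minmax_normalize()].
#' @return An object of class `FeatureMatrix`.
#' @export
feature_matrix <- function(values, labels, n_bands, channel_names = NULL,
                           feature_ids = NULL, norm_params = NULL) {
  values <- as.matrix(values)
  if (length(labels) != nrow(values))
    stop("label count must equal the number of trials (rows)", call. = FALSE)
  n_bands <- .assert_count(n_bands, "n_bands")
  if (is.null(feature_ids)) feature_ids <- seq_len(ncol(values))
  if (length(feature_ids) != ncol(values))
    stop("`feature_ids` length must equal the number of columns", call. = FALSE)
  structure(list(values = values, labels = as.integer(labels),
                 n_bands = n_bands, channel_names = channel_names,
                 feature_ids = as.integer(feature_ids),
                 norm_params = norm_params),
            class = "FeatureMatrix")
}

#' @export
print.FeatureMatrix <- function(x, ...) {
  cat(sprintf("FeatureMatrix: %d trials x %d features (%d bands/channel)%s\n",
              nrow(x$values), ncol(x$values), x$n_bands,
              if (is.null(x$norm_params)) "" else ", normalized"))
  invisible(x)
}

#' Map feature indices to (channel, band) pairs and back
#'
#' `feature_map()` tabulates the channel and band of each global feature
#' index under the channel-major layout; `feature_index()` is its inverse.
#'
#' @param n_channels,n_bands Layout dimensions.
#' @param channel,band 1-based channel and band indices.
#' @return `feature_map()`: a data.frame with columns `feature`, `channel`,
#'   `band`; `feature_index()`: integer feature indices.
#' @export
feature_map <- function(n_channels, n_bands = 13L) {
  f <- seq_len(n_channels * n_bands)
  data.frame(feature = f,
             channel = (f - 1L) %/% n_bands + 1L,
             band = (f - 1L) %% n_bands + 1L)
}

#' @rdname feature_map
#' @export
feature_index <- function(channel, band, n_bands = 13L) {
  as.integer((channel - 1L) * n_bands + band)
}

# subset columns, keeping global ids
.fm_subset <- function(fm, cols) {
  feature_matrix(fm$values[, cols, drop = FALSE], fm$labels, fm$n_bands,
                 fm$channel_names, fm$feature_ids[cols], fm$norm_params)
}

# subset rows (trials)
.fm_rows <- function(fm, rows) {
  feature_matrix(fm$values[rows, , drop = FALSE], fm$labels[rows], fm$n_bands,
                 fm$channel_names, fm$feature_ids, fm$norm_params)
}

#' Extract trial-averaged Hilbert-envelope band-power features
#'
#' For every trial, channel, and sub-band of `bank`, the channel signal is
#' band-pass filtered, its Hilbert envelope taken, and the envelope averaged
#' over the trial. Features are concatenated channel-major (all bands of
#' channel 1, then channel 2, ...), giving `n_channels * n_bands` columns --
#' e.g. 767 features for 59 channels or 806 for 62 channels with the
#' default 13-band bank.
#'
#' @param ts A [trial_set()].
#' @param bank A [design_constant_q_bank()] filter bank.
#' @param order Butterworth prototype order passed to the band-pass stage.
#' @return An unnormalized [feature_matrix()].
#' @export
extract_features <- function(ts, bank, order = 4L) {
  stopifnot(is_trial_set(ts), inherits(bank, "FilterBank"))
  d <- dim(ts$data)
  dur <- d[3L] / ts$rate
  cycles <- dur * bank$bands[1L, 1L]
  if (cycles < 2)
    stop(sprintf(
      "trial too short: %.3g s holds %.2g cycles of band 1 (%.4g-%.4g Hz); >= 2 required",
      dur, cycles, bank$bands[1L, 1L], bank$bands[1L, 2L]), call. = FALSE)
  if (bank$bands[.n_bands(bank), 2L] >= ts$rate / 2)
    stop(sprintf("highest band (%.4g Hz) reaches the Nyquist frequency (%g Hz)",
                 bank$bands[.n_bands(bank), 2L], ts$rate / 2), call. = FALSE)
  nb <- .n_bands(bank)
  flat <- matrix(aperm(ts$data, c(3L, 1L, 2L)), nrow = d[3L])  # cols: trial-major within channel
  values <- matrix(0, d[1L], d[2L] * nb)
  # the padded forward FFT is shared across bands; per band one inverse
  # transform filters, then the envelope is taken on the trial grid --
  # operation for operation what bandpass() + hilbert_envelope() compute
  n2 <- 2L * d[3L]
  fp <- stats::mvfft(.pad_even(flat))
  for (b in seq_len(nb)) {
    gain <- .butter_bp_gain(n2, ts$rate, bank$bands[b, 1L],
                            bank$bands[b, 2L], order)
    filtered <- Re(stats::mvfft(fp * gain,
                                inverse = TRUE))[seq_len(d[3L]), , drop = FALSE] / n2
    env <- .envelope_mat(filtered)
    feat <- matrix(colMeans(env), d[1L], d[2L])  # trials x channels
    values[, (seq_len(d[2L]) - 1L) * nb + b] <- feat
  }
  fm <- feature_matrix(values, ts$labels, nb, ts$channel_names)
  fm$bands <- bank$bands
  fm
}

#' Min--max normalization of a feature matrix
#'
#' Rescales each feature linearly so that its training minimum and maximum
#' map to `new_min` and `new_max`:
#' \deqn{X_N = (newMax - newMin)\frac{X - Min}{Max - Min} + newMin}
#' When `params` is omitted, per-feature `Min`/`Max` are taken from `fm`
#' itself (a training set); pass the `norm_params` of a normalized training
#' matrix to transform held-out data with the training ranges, in which case
#' values may fall outside `[new_min, new_max]` and are deliberately left
#' unclipped. A constant feature (`Max == Min`) maps to the midpoint with a
#' warning.
#'
#' @param fm A [feature_matrix()].
#' @param new_min,new_max Target range (default `-1` and `1`).
#' @param params Optional normalization record (`list(min, max, new_min,
#'   new_max)`) fitted on training data.
#' @return A [feature_matrix()] with transformed values and `norm_params`
#'   recording the parameters used.
#' @export
minmax_normalize <- function(fm, new_min = -1, new_max = 1, params = NULL) {
  stopifnot(inherits(fm, "FeatureMatrix"))
  if (is.null(params)) {
    params <- list(min = apply(fm$values, 2L, min),
                   max = apply(fm$values, 2L, max),
                   new_min = new_min, new_max = new_max)
  } else {
    if (!all(c("min", "max", "new_min", "new_max") %in% names(params)))
      stop("`params` must carry min, max, new_min, new_max", call. = FALSE)
    if (length(params$min) != ncol(fm$values))
      stop("`params` were fitted for a different number of features", call. = FALSE)
    new_min <- params$new_min
    new_max <- params$new_max
  }
  if (new_max <= new_min) stop("`new_max` must exceed `new_min`", call. = FALSE)
  rng <- params$max - params$min
  degenerate <- rng <= 0
  if (any(degenerate)) {
    warning(sprintf("%d constant feature(s) mapped to the midpoint of the range",
                    sum(degenerate)))
    rng[degenerate] <- 1
  }
  xn <- sweep(sweep(fm$values, 2L, params$min), 2L, rng, "/") *
    (new_max - new_min) + new_min
  xn[, degenerate] <- (new_min + new_max) / 2
  out <- fm
  out$values <- xn
  out$norm_params <- params
  out
}
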
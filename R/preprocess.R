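# Resampling, execution-window cropping, surface Laplacian spatial filter.

# Zero-phase FIR filtering of one signal with odd-reflection edge padding
# (the signal is continued by point reflection about its end samples, which
# suppresses the start/end transients of plain zero padding).
.filtfilt_fir <- function(b, x) {
  np <- min(length(x) - 1L, 3L * length(b))
  pre  <- 2 * x[1L] - x[(np + 1L):2L]
  post <- 2 * x[length(x)] - x[(length(x) - 1L):(length(x) - np)]
  y <- stats::filter(c(pre, x, post), b, method = "convolution", sides = 2L)
  y <- rev(stats::filter(rev(y), b, method = "convolution", sides = 2L))
  as.numeric(y[(np + 1L):(np + length(x))])
}

# Anti-aliased integer-factor decimation of one signal matrix [samples x k].
# Zero-phase FIR low-pass (Hamming fir1, forward-backward) with cutoff at
# 0.4 x target rate; the Hamming window gives > 50 dB stopband, comfortably
# above the 40 dB design floor.
.decimate_mat <- function(x, rate, target_rate) {
  factor <- rate / target_rate
  n <- nrow(x)
  # transition band 0.4..0.5 x target; Hamming needs ~3.3/df taps
  ord <- ceiling(3.3 * rate / (0.1 * target_rate))
  ord <- ord + ord %% 2L
  b <- as.numeric(signal::fir1(ord, 0.8 * target_rate / rate))
  y <- apply(x, 2L, function(col) .filtfilt_fir(b, col))
  y[seq(1L, n, by = factor), , drop = FALSE]
}

#' Downsample a trial set or recording by an integer factor
#'
#' Applies a zero-phase anti-aliasing low-pass filter (cutoff 0.4 x the
#' target rate, > 40 dB stopband attenuation) and keeps every
#' `rate / target_rate`-th sample. Only integer decimation factors are
#' supported.
#'
#' @param x A [trial_set()] or [recording()].
#' @param target_rate New sampling rate in Hz; must divide the current rate
#'   and be strictly smaller.
#' @return An object of the same class as `x` at `target_rate`; each trial
#'   of length `n` becomes length `ceiling(n / factor)`.
#' @examples
#' ts <- trial_set(array(rnorm(2 * 1 * 1000), c(2, 1, 1000)), c(1, 2), 1000)
#' dim(downsample(ts, 200)$data)  # 2 x 1 x 200
#' @export
downsample <- function(x, target_rate) UseMethod("downsample")

.check_downsample <- function(rate, target_rate) {
  .assert_scalar_num(target_rate, "target_rate", lower = 0, strict = TRUE)
  if (target_rate >= rate)
    stop(sprintf("target rate (%g Hz) must be below the current rate (%g Hz)",
                 target_rate, rate), call. = FALSE)
  factor <- rate / target_rate
  if (abs(factor - round(factor)) > 1e-9)
    stop(sprintf("unsupported resampling: %g -> %g Hz is not an integer factor",
                 rate, target_rate), call. = FALSE)
  as.integer(round(factor))
}

#' @export
downsample.TrialSet <- function(x, target_rate) {
  factor <- .check_downsample(x$rate, target_rate)
  d <- dim(x$data)
  flat <- matrix(aperm(x$data, c(3L, 1L, 2L)), nrow = d[3L])
  out <- .decimate_mat(flat, x$rate, target_rate)
  arr <- aperm(array(out, c(nrow(out), d[1L], d[2L])), c(2L, 3L, 1L))
  trial_set(arr, x$labels, target_rate, x$channel_names)
}

#' @export
downsample.Recording <- function(x, target_rate) {
  .check_downsample(x$rate, target_rate)
  out <- .decimate_mat(t(x$data), x$rate, target_rate)
  recording(t(out), target_rate, x$channel_names)
}

#' Crop each trial to the task-execution window
#'
#' Restricts every trial to the half-open interval `[start_s, end_s)`
#' relative to trial onset; the sample for time `t` is `floor(t * rate)`
#' (0-based time grid), so cropping `[0.5, 3)` at 200 Hz keeps exactly 500
#' samples. In cursor-control paradigms only the execution period (typically
#' 0.5--3 s) carries motor-imagery modulation, so analysis windows are cut
#' here before feature extraction.
#'
#' @param ts A [trial_set()].
#' @param start_s,end_s Window in seconds, `0 <= start_s < end_s <= ` trial
#'   duration.
#' @return A cropped [trial_set()].
#' @export
crop_execution <- function(ts, start_s, end_s) {
  stopifnot(is_trial_set(ts))
  .assert_scalar_num(start_s, "start_s", lower = 0)
  .assert_scalar_num(end_s, "end_s", lower = 0)
  dur <- n_samples(ts) / ts$rate
  if (start_s >= end_s)
    stop("`start_s` must be strictly less than `end_s`", call. = FALSE)
  if (end_s > dur + 1e-9)
    stop(sprintf("window [%g, %g) exceeds the trial duration (%g s)",
                 start_s, end_s, dur), call. = FALSE)
  idx <- (floor(start_s * ts$rate) + 1L):floor(end_s * ts$rate)
  trial_set(ts$data[, , idx, drop = FALSE], ts$labels, ts$rate, ts$channel_names)
}

#' Surface Laplacian spatial filter
#'
#' Sharpens localized cortical activity and reduces the spatial smearing of
#' volume conduction by re-expressing each channel relative to its
#' neighbors: for channel `j` with neighbor set `S_j` of size `n`,
#'
#' \deqn{V_j^{Lap} = V_j - \frac{1}{n} \sum_{k \in S_j} V_k}
#'
#' All channels are transformed simultaneously from the unfiltered input;
#' neighbor averages always use raw values, never already-filtered ones.
#'
#' @param ts A [trial_set()] whose channel names all appear in `montage`.
#' @param montage A [montage()] supplying the neighbor sets.
#' @return A [trial_set()] of the same shape.
#' @examples
#' m <- default_montage()
#' ts <- trial_set(array(rnorm(2 * 61 * 50), c(2, 61, 50)), c(1, 2), 100,
#'                 channel_names = m$channels)
#' lap <- laplacian_filter(ts, m)
#' @export
laplacian_filter <- function(ts, montage) {
  stopifnot(is_trial_set(ts), inherits(montage, "Montage"))
  missing_ch <- setdiff(ts$channel_names, montage$channels)
  if (length(missing_ch))
    stop("channel(s) missing from montage: ", paste(missing_ch, collapse = ", "),
         call. = FALSE)
  m <- montage_subset(montage, ts$channel_names)
  out <- ts$data
  for (j in seq_along(ts$channel_names)) {
    nb <- match(m$neighbors[[ts$channel_names[j]]], ts$channel_names)
    acc <- ts$data[, nb[1L], , drop = FALSE]
    for (k in nb[-1L]) acc <- acc + ts$data[, k, , drop = FALSE]
    out[, j, ] <- ts$data[, j, ] - acc[, 1L, ] / length(nb)
  }
  trial_set(out, ts$labels, ts$rate, ts$channel_names)
}
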
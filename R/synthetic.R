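# Synthetic motor-imagery-like EEG with planted class structure, so the
# whole selection pipeline is testable without any recordings.
#
# Every channel carries 1/f ("pink") background activity, white sensor
# noise, and an ongoing band-limited oscillation (the idling rhythm). At
# the informative channels of a class, that oscillation's amplitude is
# multiplied by an attenuation factor < 1 during trials of that class --
# event-related desynchronization (ERD) modeled as amplitude suppression of
# ongoing activity, the mechanism behind mu/beta band-power decreases over
# sensorimotor cortex during imagined movement.

#' Specification of a synthetic motor-imagery dataset
#'
#' @param n_channels Number of channels.
#' @param n_classes 2 or 4 balanced classes.
#' @param trials_per_class Trials per class.
#' @param rate Sampling rate in Hz.
#' @param trial_s Trial duration in seconds.
#' @param informative List of planted effects, one per entry:
#'   `list(class =, channels =, band = c(low, high), attenuation =)` with
#'   `attenuation` in `(0, 1)` (ERD is a power decrease). Every channel
#'   carries the baseline oscillation of each listed band; only the listed
#'   channels attenuate it for trials of the listed class.
#' @param background Pink-noise parameters: `list(exponent, amplitude)`
#'   (power spectral density proportional to `1/f^exponent`; `amplitude` is
#'   the RMS).
#' @param sensor_noise_sd White sensor-noise standard deviation.
#' @param osc_amplitude Baseline RMS of each planted-band oscillation.
#' @param seed Master RNG seed; generation is fully reproducible from it.
#' @return An object of class `SyntheticSpec`.
#' @export
synthetic_spec <- function(n_channels = 20L, n_classes = 2L,
                           trials_per_class = 100L, rate = 200, trial_s = 3,
                           informative = list(), background = list(exponent = 1,
                                                                   amplitude = 0.5),
                           sensor_noise_sd = 0.25, osc_amplitude = 1,
                           seed = 1L) {
  n_channels <- .assert_count(n_channels, "n_channels")
  if (!n_classes %in% c(2L, 4L))
    stop("`n_classes` must be 2 or 4", call. = FALSE)
  trials_per_class <- .assert_count(trials_per_class, "trials_per_class")
  .assert_scalar_num(rate, "rate", lower = 0, strict = TRUE)
  .assert_scalar_num(trial_s, "trial_s", lower = 0, strict = TRUE)
  .assert_scalar_num(sensor_noise_sd, "sensor_noise_sd", lower = 0)
  .assert_scalar_num(osc_amplitude, "osc_amplitude", lower = 0)
  for (inf in informative) {
    if (!all(c("class", "channels", "band", "attenuation") %in% names(inf)))
      stop("each informative entry needs class, channels, band, attenuation",
           call. = FALSE)
    if (inf$class < 1L || inf$class > n_classes)
      stop("informative class out of range", call. = FALSE)
    if (any(inf$channels < 1L) || any(inf$channels > n_channels))
      stop("informative channels out of range", call. = FALSE)
    if (inf$attenuation <= 0 || inf$attenuation >= 1)
      stop("`attenuation` must lie in (0, 1): ERD is a power decrease",
           call. = FALSE)
    if (trial_s * inf$band[1L] < 4)
      stop("trials must hold at least 4 cycles of every planted band",
           call. = FALSE)
    if (inf$band[2L] >= rate / 2)
      stop("planted band exceeds the Nyquist frequency", call. = FALSE)
  }
  structure(list(n_channels = n_channels, n_classes = n_classes,
                 trials_per_class = trials_per_class, rate = rate,
                 trial_s = trial_s, informative = informative,
                 background = background, sensor_noise_sd = sensor_noise_sd,
                 osc_amplitude = osc_amplitude, seed = seed),
            class = "SyntheticSpec")
}

# pink noise: spectrally shaped white noise, columns of an [n x m] matrix,
# unit RMS in expectation before external scaling
.pink_mat <- function(n, m, rate, exponent) {
  w <- matrix(rnorm(n * m), n, m)
  freqs <- (seq_len(n) - 1L) * rate / n
  f2 <- pmin(freqs, rate - freqs)          # two-sided frequency axis
  shape <- 1 / pmax(f2, 1)^(exponent / 2)  # flatten below 1 Hz, kill nothing
  shape[1L] <- 0                           # remove DC
  x <- Re(stats::mvfft(stats::mvfft(w) * shape, inverse = TRUE)) / n
  x / sqrt(mean(x^2))
}

#' Generate a synthetic trial set with known ground truth
#'
#' @param spec A [synthetic_spec()].
#' @param bank Filter bank used to express the ground truth as
#'   (channel, band-index) pairs (default the 13-band constant-Q bank).
#' @return A list: `trials` (a [trial_set()]), `truth` (list with
#'   `channels_by_class`, the union `channels`, and `feature_pairs`, a
#'   data.frame of informative (channel, band) pairs under `bank`), and
#'   `spec`.
#' @examples
#' out <- generate_synthetic(synthetic_spec(
#'   n_channels = 4, trials_per_class = 5, trial_s = 1,
#'   informative = list(list(class = 1, channels = 2, band = c(8, 12),
#'                           attenuation = 0.5))))
#' dim(out$trials$data)  # 10 x 4 x 200
#' @export
generate_synthetic <- function(spec, bank = design_constant_q_bank()) {
  stopifnot(inherits(spec, "SyntheticSpec"))
  set.seed(spec$seed)
  n_tr <- spec$n_classes * spec$trials_per_class
  ns <- as.integer(round(spec$trial_s * spec$rate))
  labels <- rep(seq_len(spec$n_classes), each = spec$trials_per_class)
  m <- n_tr * spec$n_channels  # signals, column index = (ch - 1) * n_tr + trial

  sig <- .pink_mat(ns, m, spec$rate, spec$background$exponent) *
    spec$background$amplitude
  sig <- sig + matrix(rnorm(ns * m, sd = spec$sensor_noise_sd), ns, m)

  planted_bands <- unique(lapply(spec$informative, `[[`, "band"))
  for (band in planted_bands) {
    gain <- .butter_bp_gain(2L * ns, spec$rate, band[1L], band[2L])
    osc <- .fd_filter_mat(matrix(rnorm(ns * m), ns, m), gain)
    osc <- osc / sqrt(mean(osc^2)) * spec$osc_amplitude
    att <- rep(1, m)
    for (inf in spec$informative) {
      if (!identical(inf$band, band)) next
      cols <- outer((inf$channels - 1L) * n_tr, which(labels == inf$class), "+")
      att[cols] <- att[cols] * inf$attenuation
    }
    sig <- sig + sweep(osc, 2L, att, "*")
  }

  arr <- aperm(array(sig, c(ns, n_tr, spec$n_channels)), c(2L, 3L, 1L))
  ts <- trial_set(arr, labels, spec$rate)

  by_class <- lapply(seq_len(spec$n_classes), function(cl) {
    sort(unique(unlist(lapply(spec$informative, function(inf)
      if (inf$class == cl) inf$channels else integer(0)))))
  })
  pairs <- unique(do.call(rbind, lapply(spec$informative, function(inf) {
    b <- which(bank$bands[, 2L] > inf$band[1L] & bank$bands[, 1L] < inf$band[2L])
    expand.grid(channel = inf$channels, band = b)
  })))
  truth <- list(channels_by_class = by_class,
                channels = sort(unique(unlist(by_class))),
                feature_pairs = pairs)
  list(trials = ts, truth = truth, spec = spec)
}

#' Canonical planted-channel benchmark
#'
#' The standard recovery fixture used throughout the test suite: 20
#' channels, 2 balanced classes of 100 trials, 200 Hz, 3-s trials. Four
#' channels are informative, mirroring contralateral sensorimotor ERD: mu
#' band (8--12 Hz) amplitude is halved at channels 6 and 8 during class-1
#' trials and at channels 13 and 15 during class-2 trials; the other 16
#' channels carry the same mu rhythm unmodulated, plus pink background and
#' sensor noise like every channel.
#'
#' @param seed Master RNG seed.
#' @return As [generate_synthetic()]; `truth$channels` is always
#'   `c(6, 8, 13, 15)`.
#' @export
default_benchmark <- function(seed = 1L) {
  generate_synthetic(synthetic_spec(
    n_channels = 20L, n_classes = 2L, trials_per_class = 100L,
    rate = 200, trial_s = 3,
    informative = list(
      list(class = 1L, channels = c(6L, 8L), band = c(8, 12), attenuation = 0.5),
      list(class = 2L, channels = c(13L, 15L), band = c(8, 12), attenuation = 0.5)),
    seed = seed))
}
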
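# Domain containers: TrialSet, Recording, Montage, FeatureMatrix.

#' Construct an epoched trial set
#'
#' A `TrialSet` holds epoched multichannel EEG as a 3-D numeric array
#' `[n_trials, n_channels, n_samples]` together with one integer class label
#' per trial, the sampling rate, and channel names. It is the common currency
#' of the preprocessing and feature-extraction stages.
#'
#' @param data Numeric 3-D array `[n_trials, n_channels, n_samples]`.
#' @param labels Integer class label per trial (coded `1..K`).
#' @param rate Sampling rate in Hz (> 0).
#' @param channel_names Optional character vector of channel names; defaults
#'   to `Ch01`, `Ch02`, ...
#' @return An object of class `TrialSet`.
#' @examples
#' ts <- trial_set(array(rnorm(2 * 3 * 100), c(2, 3, 100)),
#'                 labels = c(1, 2), rate = 100)
#' ts
#' @export
trial_set <- function(data, labels, rate, channel_names = NULL) {
  if (!is.array(data) || length(dim(data)) != 3L || !is.numeric(data))
    stop("`data` must be a numeric 3-D array [trials, channels, samples]",
         call. = FALSE)
  d <- dim(data)
  if (length(labels) != d[1L])
    stop(sprintf("label count (%d) must equal trial count (%d)",
                 length(labels), d[1L]), call. = FALSE)
  if (any(!is.finite(labels)) || any(labels != round(labels)))
    stop("`labels` must be finite integers", call. = FALSE)
  .assert_scalar_num(rate, "rate", lower = 0, strict = TRUE)
  if (is.null(channel_names)) channel_names <- sprintf("Ch%02d", seq_len(d[2L]))
  if (length(channel_names) != d[2L])
    stop("`channel_names` length must equal the number of channels", call. = FALSE)
  if (anyDuplicated(channel_names))
    stop("channel names must be unique", call. = FALSE)
  structure(list(data = data, labels = as.integer(labels), rate = rate,
                 channel_names = as.character(channel_names)),
            class = "TrialSet")
}

#' @export
print.TrialSet <- function(x, ...) {
  d <- dim(x$data)
  cat(sprintf("TrialSet: %d trials x %d channels x %d samples @ %g Hz\n",
              d[1L], d[2L], d[3L], x$rate))
  tab <- table(x$labels)
  cat("  classes:", paste(sprintf("%s (n=%d)", names(tab), tab), collapse = ", "),
      "\n")
  invisible(x)
}

#' @rdname trial_set
#' @param x Object to test.
#' @export
is_trial_set <- function(x) inherits(x, "TrialSet")

n_trials   <- function(ts) dim(ts$data)[1L]
n_channels <- function(ts) dim(ts$data)[2L]
n_samples  <- function(ts) dim(ts$data)[3L]

#' Construct a continuous multichannel recording
#'
#' A `Recording` is an un-epoched signal block (channels x samples) as read
#' from an EDF file. Use [epoch_recording()] to cut it into a [trial_set()].
#'
#' @param data Numeric matrix `[n_channels, n_samples]`.
#' @param rate Sampling rate in Hz.
#' @param channel_names Optional channel names.
#' @return An object of class `Recording`.
#' @export
recording <- function(data, rate, channel_names = NULL) {
  if (!is.matrix(data) || !is.numeric(data))
    stop("`data` must be a numeric matrix [channels, samples]", call. = FALSE)
  .assert_scalar_num(rate, "rate", lower = 0, strict = TRUE)
  if (is.null(channel_names)) channel_names <- sprintf("Ch%02d", seq_len(nrow(data)))
  if (length(channel_names) != nrow(data))
    stop("`channel_names` length must equal the number of channels", call. = FALSE)
  structure(list(data = data, rate = rate,
                 channel_names = as.character(channel_names)),
            class = "Recording")
}

#' @export
print.Recording <- function(x, ...) {
  cat(sprintf("Recording: %d channels x %d samples @ %g Hz (%.1f s)\n",
              nrow(x$data), ncol(x$data), x$rate, ncol(x$data) / x$rate))
  invisible(x)
}

#' Epoch a continuous recording into trials
#'
#' @param rec A [recording()].
#' @param onsets_s Trial onset times in seconds.
#' @param duration_s Trial duration in seconds (equal for all trials).
#' @param labels Integer class label per trial.
#' @return A [trial_set()].
#' @export
epoch_recording <- function(rec, onsets_s, duration_s, labels) {
  stopifnot(inherits(rec, "Recording"))
  .assert_scalar_num(duration_s, "duration_s", lower = 0, strict = TRUE)
  if (length(labels) != length(onsets_s))
    stop("one label per onset is required", call. = FALSE)
  len <- floor(duration_s * rec$rate)
  ns <- ncol(rec$data)
  arr <- array(0, c(length(onsets_s), nrow(rec$data), len))
  for (i in seq_along(onsets_s)) {
    from <- floor(onsets_s[i] * rec$rate) + 1L
    if (from < 1L || from + len - 1L > ns)
      stop(sprintf("trial %d [%g s + %g s] falls outside the recording",
                   i, onsets_s[i], duration_s), call. = FALSE)
    arr[i, , ] <- rec$data[, from:(from + len - 1L)]
  }
  trial_set(arr, labels, rec$rate, rec$channel_names)
}

# Montage --------------------------------------------------------------------

#' Construct an electrode montage
#'
#' A `Montage` carries the electrode names, their schematic 2-D positions,
#' and the neighbor sets used by the surface Laplacian filter. Interior
#' electrodes of the bundled 10--20 layout have 4 neighbors; electrodes at
#' the periphery of the cap have 2 or 3.
#'
#' @param channels Character vector of electrode names.
#' @param positions Numeric matrix `[n_channels, 2]` of schematic x/y
#'   coordinates (unitless head-plane coordinates).
#' @param neighbors Named list mapping each channel to a character vector of
#'   neighboring channel names.
#' @return An object of class `Montage`.
#' @seealso [default_montage()], [load_montage()], [laplacian_filter()]
#' @export
montage <- function(channels, positions, neighbors) {
  channels <- as.character(channels)
  if (anyDuplicated(channels)) stop("duplicate channel names", call. = FALSE)
  positions <- as.matrix(positions)
  if (nrow(positions) != length(channels) || ncol(positions) != 2L)
    stop("`positions` must be an [n_channels, 2] matrix", call. = FALSE)
  rownames(positions) <- channels
  if (!setequal(names(neighbors), channels))
    stop("`neighbors` must have exactly one entry per channel", call. = FALSE)
  neighbors <- neighbors[channels]
  for (ch in channels) {
    nb <- neighbors[[ch]]
    if (length(nb) < 1L)
      stop(sprintf("channel '%s' has no neighbors", ch), call. = FALSE)
    unknown <- setdiff(nb, channels)
    if (length(unknown))
      stop(sprintf("channel '%s' lists unknown neighbor(s): %s",
                   ch, paste(unknown, collapse = ", ")), call. = FALSE)
    if (ch %in% nb)
      stop(sprintf("channel '%s' lists itself as a neighbor", ch), call. = FALSE)
    if (anyDuplicated(nb))
      stop(sprintf("channel '%s' lists a duplicate neighbor", ch), call. = FALSE)
  }
  structure(list(channels = channels, positions = positions,
                 neighbors = neighbors),
            class = "Montage")
}

#' @export
print.Montage <- function(x, ...) {
  nn <- lengths(x$neighbors)
  cat(sprintf("Montage: %d channels; neighbor counts %s\n", length(x$channels),
              paste(sort(unique(nn)), collapse = "/")))
  invisible(x)
}

#' Load a montage from a YAML file
#'
#' The file must define `channels` (list of names), `positions` (mapping
#' name -> `[x, y]`), and `neighbors` (mapping name -> list of names). See
#' the bundled example `system.file("extdata", "montage_1020.yaml",
#' package = "relcen")`.
#'
#' @param path Path to a YAML montage description.
#' @return A [montage()].
#' @export
load_montage <- function(path) {
  if (!file.exists(path)) stop("montage file not found: ", path, call. = FALSE)
  spec <- yaml::read_yaml(path)
  for (field in c("channels", "positions", "neighbors"))
    if (is.null(spec[[field]]))
      stop(sprintf("montage file is missing the '%s' field: %s", field, path),
           call. = FALSE)
  channels <- unlist(spec$channels)
  pos <- t(vapply(channels, function(ch) {
    p <- spec$positions[[ch]]
    if (is.null(p) || length(p) != 2L)
      stop(sprintf("missing or malformed position for channel '%s'", ch),
           call. = FALSE)
    as.numeric(p)
  }, numeric(2)))
  nb <- lapply(spec$neighbors, function(v) as.character(unlist(v)))
  montage(channels, pos, nb)
}

#' Write a montage to a YAML file
#'
#' @param m A [montage()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_montage <- function(m, path) {
  stopifnot(inherits(m, "Montage"))
  pos <- lapply(seq_along(m$channels), function(i) as.numeric(m$positions[i, ]))
  names(pos) <- m$channels
  yaml::write_yaml(list(channels = as.list(m$channels),
                        positions = pos,
                        neighbors = lapply(m$neighbors, as.list)),
                   path)
  invisible(path)
}

#' Bundled 10--20 style montage
#'
#' A 61-electrode layout on the extended 10--20 grid. Neighbor sets follow
#' the grid adjacency rule used for surface Laplacian filtering: interior
#' electrodes take their 4 nearest grid neighbors (left/right/front/back)
#' and electrodes at the cap periphery take their available 2--3 neighbors.
#' Electrode positions are schematic head-plane coordinates (x: left
#' negative, y: front positive), suitable for topographic plotting.
#'
#' @param subset Optional character vector of channel names to keep; neighbor
#'   sets are pruned to the kept channels (a channel left without neighbors
#'   is an error). Lets recordings missing a few peripheral electrodes reuse
#'   the same layout.
#' @return A [montage()].
#' @examples
#' m <- default_montage()
#' lengths(m$neighbors)[c("C3", "Cz", "Fp1", "T7")]
#' @export
default_montage <- function(subset = NULL) {
  rows <- list(
    c("Fp1", "Fpz", "Fp2"),
    c("AF7", "AF3", "AFz", "AF4", "AF8"),
    c("F7", "F5", "F3", "F1", "Fz", "F2", "F4", "F6", "F8"),
    c("FT7", "FC5", "FC3", "FC1", "FCz", "FC2", "FC4", "FC6", "FT8"),
    c("T7", "C5", "C3", "C1", "Cz", "C2", "C4", "C6", "T8"),
    c("TP7", "CP5", "CP3", "CP1", "CPz", "CP2", "CP4", "CP6", "TP8"),
    c("P7", "P5", "P3", "P1", "Pz", "P2", "P4", "P6", "P8"),
    c("PO7", "PO3", "POz", "PO4", "PO8"),
    c("O1", "Oz", "O2"))
  # grid column of the first channel in each row (columns 0..8, center 4)
  offsets <- c(3L, 2L, 0L, 0L, 0L, 0L, 0L, 2L, 3L)
  grid <- do.call(rbind, lapply(seq_along(rows), function(r) {
    data.frame(channel = rows[[r]],
               col = offsets[r] + seq_along(rows[[r]]) - 1L,
               row = r - 1L, stringsAsFactors = FALSE)
  }))
  key <- paste(grid$col, grid$row)
  neighbors <- lapply(seq_len(nrow(grid)), function(i) {
    cand <- paste(c(grid$col[i] - 1L, grid$col[i] + 1L, grid$col[i], grid$col[i]),
                  c(grid$row[i], grid$row[i], grid$row[i] - 1L, grid$row[i] + 1L))
    grid$channel[match(cand[cand %in% key], key)]
  })
  names(neighbors) <- grid$channel
  pos <- cbind(x = grid$col - 4L, y = 4L - grid$row)
  m <- montage(grid$channel, pos, neighbors)
  if (is.null(subset)) m else montage_subset(m, subset)
}

#' Restrict a montage to a subset of channels
#'
#' @param m A [montage()].
#' @param keep Channel names to keep.
#' @return A [montage()] over `keep`, with neighbor sets pruned.
#' @export
montage_subset <- function(m, keep) {
  stopifnot(inherits(m, "Montage"))
  unknown <- setdiff(keep, m$channels)
  if (length(unknown))
    stop("unknown channel(s): ", paste(unknown, collapse = ", "), call. = FALSE)
  keep <- m$channels[m$channels %in% keep]  # preserve montage order
  nb <- lapply(m$neighbors[keep], function(v) intersect(v, keep))
  empty <- keep[lengths(nb) == 0L]
  if (length(empty))
    stop("subset leaves channel(s) without neighbors: ",
         paste(empty, collapse = ", "), call. = FALSE)
  montage(keep, m$positions[keep, , drop = FALSE], nb)
}

# Matrix + sidecar I/O -------------------------------------------------------

#' Write a trial set as a CSV matrix plus a YAML sidecar
#'
#' The CSV holds one sample per row with one column per channel; trials are
#' stacked in order. The sidecar records `rate`, `n_trials`, `n_samples`,
#' `labels` and `channel_names`, which is everything needed to rebuild the
#' 3-D array.
#'
#' @param ts A [trial_set()].
#' @param data_path Output CSV path.
#' @param meta_path Output YAML sidecar path.
#' @return `data_path`, invisibly.
#' @export
write_matrix <- function(ts, data_path, meta_path) {
  stopifnot(is_trial_set(ts))
  d <- dim(ts$data)
  # rows: sample-major within trial, trials stacked
  flat <- matrix(aperm(ts$data, c(3L, 1L, 2L)), nrow = d[1L] * d[3L])
  colnames(flat) <- ts$channel_names
  data.table::fwrite(data.table::as.data.table(flat), data_path)
  yaml::write_yaml(list(rate = ts$rate, n_trials = d[1L], n_samples = d[3L],
                        labels = as.list(as.integer(ts$labels)),
                        channel_names = as.list(ts$channel_names)),
                   meta_path)
  invisible(data_path)
}

#' Read a trial set from a CSV matrix plus a YAML sidecar
#'
#' Counterpart of [write_matrix()].
#'
#' @param data_path CSV file of stacked samples (one column per channel).
#' @param meta_path YAML sidecar with `rate`, `n_trials`, `n_samples`,
#'   `labels` and optionally `channel_names`.
#' @return A [trial_set()].
#' @export
read_matrix <- function(data_path, meta_path) {
  if (!file.exists(data_path)) stop("data file not found: ", data_path, call. = FALSE)
  if (!file.exists(meta_path)) stop("metadata file not found: ", meta_path, call. = FALSE)
  meta <- yaml::read_yaml(meta_path)
  if (is.null(meta$rate)) stop("sidecar is missing `rate`: ", meta_path, call. = FALSE)
  if (is.null(meta$labels)) stop("sidecar is missing `labels`: ", meta_path, call. = FALSE)
  if (is.null(meta$n_trials) || is.null(meta$n_samples))
    stop("sidecar must give `n_trials` and `n_samples`: ", meta_path, call. = FALSE)
  flat <- as.matrix(data.table::fread(data_path))
  nt <- as.integer(meta$n_trials); ns <- as.integer(meta$n_samples)
  labels <- as.integer(unlist(meta$labels))
  if (length(labels) != nt)
    stop(sprintf("sidecar lists %d labels for %d trials", length(labels), nt),
         call. = FALSE)
  if (nrow(flat) != nt * ns)
    stop(sprintf("data has %d rows; sidecar implies %d (n_trials x n_samples)",
                 nrow(flat), nt * ns), call. = FALSE)
  ch <- if (!is.null(meta$channel_names)) unlist(meta$channel_names) else colnames(flat)
  arr <- aperm(array(flat, c(ns, nt, ncol(flat))), c(2L, 3L, 1L))
  trial_set(arr, labels, meta$rate, ch)
}
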
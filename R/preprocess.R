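#' Band-pass filter specification
#'
#' @param low_hz,high_hz Band edges (Hz), `0 < low_hz < high_hz < fs/2`.
#' @param order Overall Butterworth order in the MATLAB/SciPy band-pass
#'   convention: `order` pole pairs, i.e. an `order`-th order roll-off on each
#'   skirt. The online chain uses order 6 between 0.1 and 8 Hz; the
#'   visualization variant order 6 between 0.1 and 45 Hz.
#' @param causal `TRUE` (default) for the online forward filter, which
#'   introduces group delay; `FALSE` for zero-phase forward-backward filtering
#'   as used for visualization.
#' @return A `filter_spec` list.
#' @export
filter_spec <- function(low_hz = 0.1, high_hz = 8, order = 6, causal = TRUE) {
  if (!(low_hz > 0 && low_hz < high_hz)) stop_bci("Need 0 < low_hz < high_hz.")
  if (order < 1) stop_bci("`order` must be at least 1.")
  structure(list(low_hz = low_hz, high_hz = high_hz, order = as.integer(order),
                 causal = isTRUE(causal)), class = "filter_spec")
}

# Design an order-n Butterworth band-pass as cascaded biquads (second-order
# sections). The 12-pole transfer-function form is numerically unstable at
# narrow normalized bands, so we transform the analog prototype pole by pole
# and bilinear-transform each section separately; every section is normalized
# to unit gain at the band's geometric center frequency.
design_bandpass_sos <- function(low_hz, high_hz, order, fs_hz) {
  if (high_hz >= fs_hz / 2) stop_bci("`high_hz` must be below the Nyquist frequency.")
  n <- order
  fs2 <- 2 * fs_hz
  wl <- fs2 * tan(pi * low_hz / fs_hz)   # prewarped analog edges
  wh <- fs2 * tan(pi * high_hz / fs_hz)
  bw <- wh - wl
  w0 <- sqrt(wl * wh)
  # analog lowpass prototype poles (left half plane, unit cutoff)
  k <- seq_len(n)
  proto <- exp(1i * pi * (2 * k + n - 1) / (2 * n))
  # keep one of each conjugate pair (upper half plane) plus any real pole
  upper <- proto[Im(proto) > 1e-12]
  real_p <- proto[abs(Im(proto)) <= 1e-12]
  # band transform: prototype pole p -> roots of s^2 - p*bw*s + w0^2 = 0
  bp_poles <- c()
  for (p in upper) {
    d <- sqrt((p * bw)^2 - 4 * w0^2)
    bp_poles <- c(bp_poles, (p * bw + d) / 2, (p * bw - d) / 2)
  }
  for (p in real_p) {
    d <- sqrt(as.complex((Re(p) * bw)^2 - 4 * w0^2))
    s1 <- (Re(p) * bw + d) / 2
    bp_poles <- c(bp_poles, s1) # conjugate handled below
  }
  # one biquad per band-pass pole (paired with its conjugate), one zero at 0
  z0 <- exp(2i * pi * sqrt(low_hz * high_hz) / fs_hz) # digital center frequency
  sos <- matrix(0, length(bp_poles), 5,
                dimnames = list(NULL, c("b0", "b1", "b2", "a1", "a2")))
  for (j in seq_along(bp_poles)) {
    s <- bp_poles[j]
    a1s <- -2 * Re(s)
    a0s <- Mod(s)^2
    # bilinear transform of H(s) = s / (s^2 + a1s*s + a0s)
    c1 <- fs2
    den0 <- c1^2 + a1s * c1 + a0s
    b <- c(c1, 0, -c1) / den0
    a <- c(1, (2 * a0s - 2 * c1^2) / den0, (c1^2 - a1s * c1 + a0s) / den0)
    # normalize to unit gain at the center frequency
    h <- sum(b * z0^(0:-2)) / sum(a * z0^(0:-2))
    b <- b / Mod(h)
    if (max(Mod(polyroot(rev(a)))) >= 1) {
      stop_bci("Unstable filter design: band too narrow for the requested order.")
    }
    sos[j, ] <- c(b, a[2], a[3])
  }
  sos
}

sos_filter_forward <- function(x, sos) {
  for (j in seq_len(nrow(sos))) {
    x <- signal::filter(sos[j, 1:3], c(1, sos[j, 4:5]), x)
  }
  as.numeric(x)
}

sos_filtfilt <- function(x, sos, fs_hz, low_hz) {
  n <- length(x)
  npad <- min(n - 1, 3L * ceiling(fs_hz / low_hz))
  # odd reflection padding at both ends
  xp <- c(2 * x[1] - rev(x[2:(npad + 1)]), x, 2 * x[n] - rev(x[(n - npad):(n - 1)]))
  y <- sos_filter_forward(xp, sos)
  y <- rev(sos_filter_forward(rev(y), sos))
  y[(npad + 1):(npad + n)]
}

#' Apply a series filter to a numeric vector
#'
#' Low-level entry point used by [bandpass()] and the gaze audit: filters one
#' series with the band-pass design of `spec` at rate `fs_hz`.
#'
#' @param x Numeric series.
#' @param spec A [filter_spec()].
#' @param fs_hz Sampling rate (Hz).
#' @return Filtered series of the same length.
#' @export
filter_series <- function(x, spec, fs_hz) {
  sos <- design_bandpass_sos(spec$low_hz, spec$high_hz, spec$order, fs_hz)
  if (spec$causal) sos_filter_forward(x, sos)
  else sos_filtfilt(x, sos, fs_hz, spec$low_hz)
}

#' Band-pass filter a recording
#'
#' Filters every channel with a Butterworth band-pass. In causal mode
#' (the online chain: 0.1-8 Hz, order 6) the filter runs forward only, with
#' state continuous across the whole recording, mimicking real-time operation;
#' group delay is therefore present. In zero-phase mode (the visualization
#' chain: 0.1-45 Hz) the filter runs forward-backward and introduces no phase
#' shift.
#'
#' @param recording A `bci_recording`.
#' @param spec A [filter_spec()].
#' @return The filtered `bci_recording`.
#' @export
bandpass <- function(recording, spec = filter_spec()) {
  sos <- design_bandpass_sos(spec$low_hz, spec$high_hz, spec$order, recording$fs_hz)
  out <- recording
  for (c in seq_len(nrow(recording$data))) {
    x <- recording$data[c, ]
    out$data[c, ] <- if (spec$causal) sos_filter_forward(x, sos)
                     else sos_filtfilt(x, sos, recording$fs_hz, spec$low_hz)
  }
  out
}

#' Common-average reference
#'
#' Subtracts the across-channel mean from every channel at each sample.
#'
#' @param recording A `bci_recording` with at least 2 channels.
#' @return The re-referenced recording.
#' @export
common_average_reference <- function(recording) {
  if (nrow(recording$data) < 2) {
    stop_bci("Common-average referencing needs at least 2 channels.")
  }
  recording$data <- sweep(recording$data, 2, colMeans(recording$data))
  recording
}

#' Extract stimulus-locked epochs
#'
#' Cuts one epoch per retained stimulus, starting at the stimulus-onset sample,
#' of length `floor(window_s * fs)` samples (the half-open window
#' `[onset, onset + window_s)`; 153 samples at 256 Hz). The first
#' `skip_per_stream` stimuli of each stream in each trial are disregarded, so a
#' fixed-phase trial yields 6 left-locked and 5 right-locked epochs.
#'
#' @param recording A `bci_recording` whose event table has `sample` indices.
#' @param window_s Epoch duration (s); default 0.6.
#' @param skip_per_stream Leading stimuli to drop per stream per trial;
#'   default 2.
#' @return A `bci_epochs`: list with `epochs` (epoch x channel x sample array),
#'   per-epoch `stream`, `trial_id`, `onset_sample`, plus `fs_hz`, `window_s`,
#'   `attended` labels and `channel_labels`.
#' @export
extract_epochs <- function(recording, window_s = 0.6, skip_per_stream = 2) {
  len <- floor(window_s * recording$fs_hz)
  ev <- dplyr::filter(recording$events, .data$index >= skip_per_stream)
  ev <- dplyr::arrange(ev, .data$trial_id, .data$sample)
  bad <- ev$sample + len - 1L > ncol(recording$data)
  if (any(bad)) {
    stop_bci(sprintf(
      "%d epoch(s) exceed the recording end (first offending event: trial %d, %s stream, index %d).",
      sum(bad), ev$trial_id[bad][1], ev$stream[bad][1], ev$index[bad][1]))
  }
  n_ep <- nrow(ev)
  n_ch <- nrow(recording$data)
  epochs <- array(0, dim = c(n_ep, n_ch, len))
  for (i in seq_len(n_ep)) {
    epochs[i, , ] <- recording$data[, ev$sample[i]:(ev$sample[i] + len - 1L), drop = FALSE]
  }
  structure(
    list(epochs = epochs, stream = ev$stream, trial_id = ev$trial_id,
         onset_sample = ev$sample, fs_hz = recording$fs_hz, window_s = window_s,
         attended = recording$attended, channel_labels = recording$channel_labels),
    class = "bci_epochs"
  )
}

#' @export
print.bci_epochs <- function(x, ...) {
  d <- dim(x$epochs)
  cat(sprintf("<bci_epochs> %d epochs x %d channels x %d samples @ %g Hz (%d trials)\n",
              d[1], d[2], d[3], x$fs_hz, length(unique(x$trial_id))))
  invisible(x)
}

# subset an epoch set by epoch indices
epochs_subset <- function(epochs, idx) {
  out <- epochs
  out$epochs <- epochs$epochs[idx, , , drop = FALSE]
  out$stream <- epochs$stream[idx]
  out$trial_id <- epochs$trial_id[idx]
  out$onset_sample <- epochs$onset_sample[idx]
  out$attended <- epochs$attended[epochs$attended$trial_id %in% out$trial_id, ]
  out
}

stream_mean <- function(epochs_arr, which_idx, n_ch, len) {
  if (length(which_idx) == 0) return(matrix(0, n_ch, len))
  m <- matrix(0, n_ch, len)
  for (i in which_idx) m <- m + epochs_arr[i, , ]
  m / length(which_idx)
}

#' Running difference-of-averages features for one trial
#'
#' Processes a trial's retained epochs in onset order; after each new epoch the
#' snapshot `x_delta = mean(right-locked so far) - mean(left-locked so far)` is
#' emitted. Until a stream has contributed its first epoch, its running mean is
#' a zero matrix, so one snapshot is produced per epoch (11 for a fixed-phase
#' trial), matching an online system that updates whenever a new epoch becomes
#' available.
#'
#' @param epochs A `bci_epochs`.
#' @param trial One `trial_id` to process (defaults to the only trial present).
#' @return Tibble with one row per snapshot: `step`, `stream` (of the epoch
#'   just added), `n_left`, `n_right`, and the `x_delta` matrix list-column.
#' @export
running_difference <- function(epochs, trial = NULL) {
  ids <- unique(epochs$trial_id)
  trial <- trial %||% (if (length(ids) == 1L) ids else
    stop_bci("Multiple trials present: specify `trial`."))
  idx <- which(epochs$trial_id == trial)
  idx <- idx[order(epochs$onset_sample[idx])]
  if (length(idx) == 0) stop_bci("No epochs for the requested trial.")
  d <- dim(epochs$epochs)
  n_ch <- d[2]; len <- d[3]
  sum_l <- matrix(0, n_ch, len); sum_r <- matrix(0, n_ch, len)
  n_l <- 0L; n_r <- 0L
  snaps <- vector("list", length(idx))
  meta <- tibble::tibble(step = seq_along(idx), stream = epochs$stream[idx],
                         n_left = 0L, n_right = 0L)
  for (k in seq_along(idx)) {
    e <- epochs$epochs[idx[k], , ]
    if (!is.matrix(e)) e <- matrix(e, n_ch, len)
    if (epochs$stream[idx[k]] == "left") { sum_l <- sum_l + e; n_l <- n_l + 1L }
    else { sum_r <- sum_r + e; n_r <- n_r + 1L }
    xl <- if (n_l > 0) sum_l / n_l else matrix(0, n_ch, len)
    xr <- if (n_r > 0) sum_r / n_r else matrix(0, n_ch, len)
    snaps[[k]] <- xr - xl
    meta$n_left[k] <- n_l; meta$n_right[k] <- n_r
  }
  meta$x_delta <- snaps
  meta
}

#' Final difference features for every trial
#'
#' Batch computation of the final `x_delta` (mean right-locked epoch minus mean
#' left-locked epoch over all retained epochs) per trial; equals the last
#' snapshot of [running_difference()].
#'
#' @param epochs A `bci_epochs`.
#' @return Tibble with `trial_id`, `attended`, `n_left`, `n_right`, and the
#'   `x_delta` matrix list-column.
#' @export
trial_features <- function(epochs) {
  d <- dim(epochs$epochs)
  ids <- unique(epochs$trial_id)
  rows <- purrr::map(ids, function(id) {
    il <- which(epochs$trial_id == id & epochs$stream == "left")
    ir <- which(epochs$trial_id == id & epochs$stream == "right")
    xd <- stream_mean(epochs$epochs, ir, d[2], d[3]) -
      stream_mean(epochs$epochs, il, d[2], d[3])
    list(n_left = length(il), n_right = length(ir), x_delta = xd)
  })
  out <- tibble::tibble(
    trial_id = ids,
    n_left = purrr::map_int(rows, "n_left"),
    n_right = purrr::map_int(rows, "n_right"),
    x_delta = purrr::map(rows, "x_delta")
  )
  dplyr::left_join(out, epochs$attended, by = "trial_id")[
    , c("trial_id", "attended", "n_left", "n_right", "x_delta")]
}
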
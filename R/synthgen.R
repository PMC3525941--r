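#' Default 16-electrode montage
#'
#' Channel labels of the extended 10-20 montage assumed by the synthetic
#' generator and the decoding examples.
#' @export
bci_montage <- c("F3", "Fz", "F4", "T7", "C3", "Cz", "C4", "T8",
                 "CP3", "CP4", "P3", "Pz", "P4", "PO7", "PO8", "Oz")

# fronto-central projection of the single ERP source onto the default montage
montage_gains <- c(F3 = 0.7, Fz = 0.9, F4 = 0.7, T7 = 0.3, C3 = 0.8, Cz = 1.0,
                   C4 = 0.8, T8 = 0.3, CP3 = 0.7, CP4 = 0.7, P3 = 0.5,
                   Pz = 0.6, P4 = 0.5, PO7 = 0.3, PO8 = 0.3, Oz = 0.3)

default_channel_gains <- function(n_channels) {
  if (n_channels == 16L) unname(montage_gains)
  else if (n_channels == 1L) 1
  else seq(1, 0.4, length.out = n_channels)
}

#' Event-related potential response model
#'
#' A single-source biphasic ERP: one cycle of a (possibly time-warped) negated
#' sine with a negative peak at `neg_peak_s` and a positive peak at
#' `pos_peak_s`, unit peak amplitude. The response to an attended stimulus is
#' `attended_gain` times larger than to an unattended one.
#'
#' @param wavelet_duration_s Total response duration (s); default 0.4.
#' @param neg_peak_s,pos_peak_s Latencies of the negative and positive peaks
#'   (s); defaults 0.1 and 0.3.
#' @param attended_gain Amplitude multiplier for attended stimuli (>= 1);
#'   default 1.2 (a 20% attention benefit).
#' @param channel_gains Optional per-channel projection of the single source;
#'   defaults to a fronto-central pattern over [bci_montage] (16 channels), a
#'   unit gain for 1 channel.
#' @param latency_jitter_sd_s SD of Gaussian per-stimulus latency jitter (s);
#'   default 0 (deterministic timing).
#' @return An `erp_model` list.
#' @export
erp_model <- function(wavelet_duration_s = 0.4, neg_peak_s = 0.1,
                      pos_peak_s = 0.3, attended_gain = 1.2,
                      channel_gains = NULL, latency_jitter_sd_s = 0) {
  if (!(0 < neg_peak_s && neg_peak_s < pos_peak_s && pos_peak_s < wavelet_duration_s)) {
    stop_bci("Peak latencies must satisfy 0 < neg_peak_s < pos_peak_s < wavelet_duration_s.")
  }
  if (attended_gain < 1) stop_bci("`attended_gain` must be >= 1.")
  structure(
    list(wavelet_duration_s = wavelet_duration_s, neg_peak_s = neg_peak_s,
         pos_peak_s = pos_peak_s, attended_gain = attended_gain,
         channel_gains = channel_gains, latency_jitter_sd_s = latency_jitter_sd_s),
    class = "erp_model"
  )
}

#' Additive noise model
#'
#' Pink (1/f power) noise whose standard deviation is `sd_ratio` times the SD
#' of the noiseless signal it is added to.
#'
#' @param sd_ratio Noise SD divided by noiseless-signal SD (> 0); default 2.
#' @param independent_per_channel Draw an independent noise series per channel
#'   (default `TRUE`).
#' @return A `noise_model` list.
#' @export
noise_model <- function(sd_ratio = 2, independent_per_channel = TRUE) {
  if (sd_ratio < 0) stop_bci("`sd_ratio` must be non-negative.")
  structure(list(kind = "pink", sd_ratio = sd_ratio,
                 independent_per_channel = independent_per_channel),
            class = "noise_model")
}

#' Gaze drift model
#'
#' Synthetic horizontal gaze that drifts exponentially toward the attended side
#' after the directional cue, emulating subjects who fail to hold fixation.
#'
#' @param drift_gain Asymptotic horizontal offset toward the attended side
#'   (screen units; 0 = perfect fixation).
#' @param time_constant_s Exponential approach time constant (s, > 0).
#' @param noise_sd Additive white-noise SD (screen units).
#' @return A `gaze_model` list.
#' @export
gaze_model <- function(drift_gain = 0.3, time_constant_s = 1.5, noise_sd = 0.05) {
  if (time_constant_s <= 0) stop_bci("`time_constant_s` must be positive.")
  structure(list(drift_gain = drift_gain, time_constant_s = time_constant_s,
                 noise_sd = noise_sd), class = "gaze_model")
}

#' Biphasic ERP wavelet
#'
#' Samples the model's one-cycle response at `fs_hz`. With the default peak
#' latencies (100 and 300 ms over a 400-ms cycle) this is exactly
#' `w(t) = -sin(2 pi t / 0.4)`; other latencies are obtained by a piecewise
#' linear phase warp through the stated peaks.
#'
#' @param model An [erp_model()].
#' @param fs_hz Sampling rate (Hz).
#' @return Numeric waveform of length `round(wavelet_duration_s * fs_hz)`,
#'   unit peak amplitude.
#' @export
biphasic_wavelet <- function(model = erp_model(), fs_hz = 256) {
  n <- round(model$wavelet_duration_s * fs_hz)
  if (n < 8) stop_bci("Wavelet too short: need at least 8 samples (fs_hz * duration >= 8).")
  t <- (seq_len(n) - 1) / fs_hz
  knots_t <- c(0, model$neg_peak_s, model$pos_peak_s, model$wavelet_duration_s)
  knots_phase <- c(0, pi / 2, 3 * pi / 2, 2 * pi)
  phase <- stats::approx(knots_t, knots_phase, xout = t)$y
  w <- -sin(phase)
  w / max(abs(w))
}

#' Pink-noise generator
#'
#' Spectrally shaped Gaussian noise with amplitude spectrum proportional to
#' 1/sqrt(f) (power ~ 1/f) above the lowest resolvable frequency, zero mean,
#' rescaled to exactly `target_sd`. Uses the session RNG.
#'
#' @param n_samples Series length (>= 2).
#' @param target_sd Standard deviation of the output.
#' @return Numeric vector of length `n_samples`.
#' @export
pink_noise <- function(n_samples, target_sd = 1) {
  if (n_samples < 2) stop_bci("`n_samples` must be at least 2.")
  n <- as.integer(n_samples)
  x <- rnorm(n)
  xf <- fft(x)
  # frequency index per FFT bin (cycles per record); floor at the first bin
  k <- c(0, seq_len(n - 1))
  k <- pmin(k, n - k) # fold negative frequencies
  amp <- 1 / sqrt(pmax(k, 1))
  amp[1] <- 0 # remove DC
  y <- Re(fft(xf * amp, inverse = TRUE)) / n
  y <- y - mean(y)
  s <- sd(y)
  if (s == 0) return(rep(0, n))
  y * (target_sd / s)
}

# segment layout used by simulate_recording: each trial occupies
# [-pre_s, sound_window_s) around its sound start
trial_segment <- function(fs_hz, pre_s = 0.5, sound_window_s = 5) {
  n <- round((pre_s + sound_window_s) * fs_hz)
  list(n = n, pre = round(pre_s * fs_hz))
}

#' Simulate a multichannel EEG-like recording
#'
#' For each trial in the schedule, an impulse train with amplitude
#' `attended_gain` at attended-stream stimulus onsets and 1 at
#' unattended-stream onsets is convolved with the biphasic ERP wavelet,
#' projected through the per-channel gains, and summed with pink noise whose
#' per-channel SD is `sd_ratio` times the SD of that channel's noiseless
#' signal, measured over the stimulation interval of the whole recording.
#' Trials are laid out consecutively, each in a segment spanning 0.5 s before
#' to 5 s after its sound start; events are recorded at nearest-sample onsets.
#'
#' @param trials Event tibble from [make_trial()]/[make_run()].
#' @param erp An [erp_model()].
#' @param noise A [noise_model()].
#' @param fs_hz Sampling rate (Hz); default 256.
#' @param n_channels Number of channels; default 16.
#' @param channel_labels Optional channel names (default [bci_montage] for 16
#'   channels).
#' @return A `bci_recording`: list with `data` (channels x samples matrix),
#'   `fs_hz`, `channel_labels`, `events` (event tibble with absolute `sample`
#'   indices), and `attended` (per-trial label tibble).
#' @export
simulate_recording <- function(trials, erp = erp_model(), noise = noise_model(),
                               fs_hz = 256, n_channels = 16,
                               channel_labels = NULL) {
  if (nrow(trials) == 0) stop_bci("`trials` must contain at least one event.")
  gains <- erp$channel_gains %||% default_channel_gains(n_channels)
  if (length(gains) != n_channels) {
    stop_bci("`channel_gains` length must equal `n_channels`.")
  }
  labels <- channel_labels %||%
    (if (n_channels == 16L) bci_montage else paste0("ch", seq_len(n_channels)))
  seg <- trial_segment(fs_hz)
  ids <- unique(trials$trial_id)
  n_total <- seg$n * length(ids)
  w <- biphasic_wavelet(erp, fs_hz)
  source_sig <- numeric(n_total)

  ev_list <- vector("list", length(ids))
  for (j in seq_along(ids)) {
    tr <- trials[trials$trial_id == ids[j], ]
    offset <- (j - 1L) * seg$n
    onset_eff <- tr$onset_s
    if (erp$latency_jitter_sd_s > 0) {
      onset_eff <- onset_eff + rnorm(nrow(tr), 0, erp$latency_jitter_sd_s)
    }
    amp <- ifelse(tr$stream == tr$attended, erp$attended_gain, 1)
    resp_start <- offset + seg$pre + round(onset_eff * fs_hz) + 1L
    for (i in seq_len(nrow(tr))) {
      idx <- resp_start[i]:(resp_start[i] + length(w) - 1L)
      source_sig[idx] <- source_sig[idx] + amp[i] * w
    }
    ev_list[[j]] <- dplyr::mutate(
      tr, sample = offset + seg$pre + round(.data$onset_s * fs_hz) + 1L
    )
  }
  events <- dplyr::bind_rows(ev_list)

  # stimulation interval: first onset to last onset + wavelet duration
  stim_mask <- rep(FALSE, n_total)
  for (j in seq_along(ids)) {
    ev <- events[events$trial_id == ids[j], ]
    stim_mask[min(ev$sample):min(n_total, max(ev$sample) + length(w) - 1L)] <- TRUE
  }

  data <- matrix(0, n_channels, n_total)
  shared <- if (!noise$independent_per_channel && noise$sd_ratio > 0) {
    pink_noise(n_total, 1)
  } else NULL
  for (c in seq_len(n_channels)) {
    sig <- gains[c] * source_sig
    data[c, ] <- sig
    if (noise$sd_ratio > 0) {
      target <- noise$sd_ratio * sd(sig[stim_mask])
      nse <- if (is.null(shared)) pink_noise(n_total, target) else shared * (target / sd(shared))
      data[c, ] <- sig + nse
    }
  }
  rownames(data) <- labels

  structure(
    list(data = data, fs_hz = fs_hz, channel_labels = labels, events = events,
         attended = dplyr::distinct(trials, .data$trial_id, .data$attended),
         pre_s = seg$pre / fs_hz, segment_samples = seg$n),
    class = "bci_recording"
  )
}

#' @export
print.bci_recording <- function(x, ...) {
  cat(sprintf("<bci_recording> %d channels x %d samples @ %g Hz, %d trials, %d events\n",
              nrow(x$data), ncol(x$data), x$fs_hz, nrow(x$attended), nrow(x$events)))
  invisible(x)
}

#' Simulate horizontal/vertical gaze traces for trials
#'
#' The horizontal component approaches `+drift_gain` (attend right) or
#' `-drift_gain` (attend left) exponentially with the model time constant,
#' starting at the visual cue (2.5 s before the trial sound), plus white noise.
#' The vertical component is noise only.
#'
#' @param trials Event tibble ([make_trial()]/[make_run()]).
#' @param gaze A [gaze_model()].
#' @param fs_hz Gaze sampling rate (Hz); default 256 so traces align with EEG
#'   samples.
#' @param cue_s Cue lead time before the sound start (s); default 2.5.
#' @return Tibble with columns `trial_id`, `attended`, `time_s` (0 = sound
#'   start), `x`, `y`.
#' @export
simulate_gaze <- function(trials, gaze = gaze_model(), fs_hz = 256, cue_s = 2.5) {
  info <- dplyr::distinct(trials, .data$trial_id, .data$attended)
  t <- seq(-cue_s, 5 - 1 / fs_hz, by = 1 / fs_hz)
  purrr::map_dfr(seq_len(nrow(info)), function(j) {
    sgn <- side_sign(info$attended[j])
    drift <- sgn * gaze$drift_gain * (1 - exp(-(t + cue_s) / gaze$time_constant_s))
    tibble::tibble(
      trial_id = info$trial_id[j], attended = info$attended[j], time_s = t,
      x = drift + rnorm(length(t), 0, gaze$noise_sd),
      y = rnorm(length(t), 0, gaze$noise_sd)
    )
  })
}

#' Simulate a multi-subject cohort
#'
#' Draws per-subject ERP gain, noise level, and gaze drift from the given
#' ranges, then generates runs of trials in each requested condition with a
#' recording (and optionally gaze traces) per run. This emulates a
#' within-subject comparison of the fixed-phase and drifting-phase designs.
#'
#' @param n_subjects Number of simulated subjects.
#' @param conditions Condition names (default `c("FP", "DP")`).
#' @param n_runs Runs per condition per subject (default 6).
#' @param trials_per_run Trials per run (even; default 20).
#' @param gain_range Range of per-subject `attended_gain` (default 1.1-1.3,
#'   centered on the nominal 20% attention benefit).
#' @param sd_ratio_range Range of per-subject noise-to-signal SD ratio
#'   (default 1.5-2.5, centered on 2).
#' @param drift_gain_range Range of per-subject gaze drift gain (default 0-0.4:
#'   from faithful fixation to clearly revealing gaze).
#' @param n_channels,fs_hz Recording geometry.
#' @param with_gaze Also simulate gaze traces per run (default `FALSE`).
#' @return A list of class `bci_cohort`: `subjects` (per-subject parameter
#'   tibble) and `runs` (tibble with `subject`, `condition`, `run`,
#'   `schedule`, `recording`, and optionally `gaze` list-columns).
#' @export
simulate_cohort <- function(n_subjects = 16, conditions = c("FP", "DP"),
                            n_runs = 6, trials_per_run = 20,
                            gain_range = c(1.1, 1.3),
                            sd_ratio_range = c(1.5, 2.5),
                            drift_gain_range = c(0, 0.4),
                            n_channels = 16, fs_hz = 256, with_gaze = FALSE) {
  subjects <- tibble::tibble(
    subject = seq_len(n_subjects),
    attended_gain = runif(n_subjects, gain_range[1], gain_range[2]),
    sd_ratio = runif(n_subjects, sd_ratio_range[1], sd_ratio_range[2]),
    drift_gain = runif(n_subjects, drift_gain_range[1], drift_gain_range[2])
  )
  runs <- tidyr::expand_grid(subject = seq_len(n_subjects),
                             condition = conditions, run = seq_len(n_runs))
  out <- purrr::pmap(runs, function(subject, condition, run) {
    p <- subjects[subjects$subject == subject, ]
    sched <- make_run(condition, trials_per_run,
                      first_trial_id = (run - 1L) * trials_per_run + 1L)
    rec <- simulate_recording(
      sched, erp = erp_model(attended_gain = p$attended_gain),
      noise = noise_model(sd_ratio = p$sd_ratio),
      fs_hz = fs_hz, n_channels = n_channels
    )
    gz <- if (with_gaze) {
      simulate_gaze(sched, gaze_model(drift_gain = p$drift_gain), fs_hz = fs_hz)
    } else NULL
    list(schedule = sched, recording = rec, gaze = gz)
  })
  runs$schedule <- purrr::map(out, "schedule")
  runs$recording <- purrr::map(out, "recording")
  if (with_gaze) runs$gaze <- purrr::map(out, "gaze")
  structure(list(subjects = subjects, runs = runs), class = "bci_cohort")
}
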
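#' Stream parameters for one dichotic tone stream
#'
#' Describes the periodic tone stream delivered to one ear: its fundamental
#' frequency, stimulus-onset asynchrony (SOA), onset of the first tone relative
#' to the start of the trial sound, number of stimuli, and the
#' amplitude-modulation (AM) frequency that distinguishes "rough" standards
#' from "smooth" (unmodulated) targets.
#'
#' @param ear `"left"` or `"right"`.
#' @param fundamental_hz Tone fundamental frequency (Hz).
#' @param soa_s Within-stream stimulus-onset asynchrony (s); must exceed the
#'   tone duration.
#' @param first_onset_s Onset of the stream's first stimulus relative to the
#'   trial sound start (s).
#' @param n_stimuli Number of stimuli in the stream per trial (at least 3).
#' @param am_hz AM frequency of standard stimuli (Hz, 100% depth).
#' @param tone_duration_s Tone duration (s); default 0.150.
#' @param ramp_s Raised-cosine rise/fall time (s); default 0.005.
#' @return A `stream_params` list.
#' @export
stream_params <- function(ear, fundamental_hz, soa_s, first_onset_s, n_stimuli,
                          am_hz, tone_duration_s = 0.150, ramp_s = 0.005) {
  match_stream(ear)
  check_number(fundamental_hz, "fundamental_hz", lower = 1)
  check_number(soa_s, "soa_s", lower = 0)
  check_number(first_onset_s, "first_onset_s", lower = 0)
  check_number(am_hz, "am_hz")
  if (am_hz <= 0) stop_bci("`am_hz` must be positive.")
  if (soa_s <= tone_duration_s) stop_bci("`soa_s` must exceed the tone duration.")
  if (n_stimuli < 3) stop_bci("`n_stimuli` must be at least 3.")
  structure(
    list(ear = ear, fundamental_hz = fundamental_hz, soa_s = soa_s,
         first_onset_s = first_onset_s, n_stimuli = as.integer(n_stimuli),
         am_hz = am_hz, tone_duration_s = tone_duration_s, ramp_s = ramp_s),
    class = "stream_params"
  )
}

#' Build a named stimulus condition
#'
#' Returns the stream parameters of the three supported dichotic stimulus
#' designs. In all of them the left stream carries 8 tones at 512 Hz
#' (standards AM-modulated at 256/6 Hz, i.e. a modulation period of exactly 6
#' samples at 256 Hz) and the right stream 7 tones at 768 Hz (AM at 256/7 Hz,
#' exactly 7 samples per period).
#'
#' * `"FP"` (fixed phase): both streams share a 492.2-ms SOA; the right stream
#'   starts half a period (246.1 ms) after the left, so the two streams keep a
#'   constant anti-phase relationship.
#' * `"DP"` (drifting phase): the left SOA is 492.2 ms but the right SOA is
#'   546.9 ms with an initial left-right lag of 109.4 ms, so the relative
#'   phase of the streams drifts by 54.7 ms per beat.
#' * `"FP500"`: fixed-phase variant with a round 500-ms SOA and 250-ms offset.
#'
#' @param name One of `"FP"`, `"DP"`, `"FP500"`.
#' @return A `stream_condition` list with elements `name`, `left`, `right`.
#' @examples
#' build_condition("FP")$right$first_onset_s # 0.2461
#' @export
build_condition <- function(name) {
  valid <- c("FP", "DP", "FP500")
  if (!is.character(name) || length(name) != 1L || !name %in% valid) {
    stop_bci(sprintf("Unknown condition %s; valid names are: %s.",
                     deparse(substitute(name)), paste(valid, collapse = ", ")))
  }
  # AM periods are exactly 6 and 7 samples at the 256-Hz EEG rate
  am_left <- 256 / 6
  am_right <- 256 / 7
  spec <- switch(
    name,
    FP = list(l_soa = 0.4922, r_soa = 0.4922, r_first = 0.2461),
    DP = list(l_soa = 0.4922, r_soa = 0.5469, r_first = 0.1094),
    FP500 = list(l_soa = 0.500, r_soa = 0.500, r_first = 0.250)
  )
  structure(
    list(
      name = name,
      left = stream_params("left", 512, spec$l_soa, 0, 8L, am_left),
      right = stream_params("right", 768, spec$r_soa, spec$r_first, 7L, am_right)
    ),
    class = "stream_condition"
  )
}

stream_onsets <- function(sp) sp$first_onset_s + sp$soa_s * (seq_len(sp$n_stimuli) - 1)

draw_targets <- function(n_stimuli, n_targets) {
  eligible <- 2:(n_stimuli - 1L) # 0-based indices >= 2
  if (n_targets > length(eligible)) {
    stop_bci("Requested more targets than eligible stimulus positions.")
  }
  sort(sample(eligible, n_targets))
}

#' Generate one cued-attention trial schedule
#'
#' Builds the ordered, timed stimulus events for one trial: 8 left-stream and 7
#' right-stream tones whose onsets follow the condition's SOAs. The first two
#' stimuli in each stream are always standards; among the remaining stimuli of
#' each stream, 1, 2, or 3 are targets, chosen uniformly at random (counts drawn
#' uniformly and independently per stream unless given). Uses the session RNG,
#' so results are reproducible under [set.seed()].
#'
#' @param cond A `stream_condition` from [build_condition()], or a condition name.
#' @param attended `"left"` or `"right"`: the cued stream.
#' @param n_targets_left,n_targets_right Optional fixed target counts (1-3).
#' @param trial_id Integer trial identifier stored in the event table.
#' @return A tibble with one row per stimulus event and columns `trial_id`,
#'   `condition`, `attended`, `stream`, `index` (0-based position within the
#'   stream), `onset_s` (from trial sound start), `kind` (`"standard"` or
#'   `"target"`), sorted by onset.
#' @examples
#' set.seed(1)
#' tr <- make_trial(build_condition("FP"), "left")
#' nrow(tr) # 15
#' @export
make_trial <- function(cond, attended, n_targets_left = NULL,
                       n_targets_right = NULL, trial_id = 1L) {
  if (is.character(cond)) cond <- build_condition(cond)
  match_stream(attended)
  counts <- list(left = n_targets_left, right = n_targets_right)
  ev <- purrr::map_dfr(c("left", "right"), function(side) {
    sp <- cond[[side]]
    n_t <- counts[[side]] %||% sample(1:3, 1)
    if (!n_t %in% 1:3) stop_bci("Target counts must be 1, 2, or 3.")
    idx <- draw_targets(sp$n_stimuli, n_t)
    tibble::tibble(
      stream = side,
      index = seq_len(sp$n_stimuli) - 1L,
      onset_s = stream_onsets(sp),
      kind = ifelse((seq_len(sp$n_stimuli) - 1L) %in% idx, "target", "standard")
    )
  })
  ev <- dplyr::arrange(ev, .data$onset_s, .data$stream)
  tibble::tibble(trial_id = as.integer(trial_id), condition = cond$name,
                 attended = attended, ev)
}

#' Generate a run of trials
#'
#' A run is a block of `n_trials` trials in one stimulus condition, half cued
#' left and half cued right, in random order.
#'
#' @inheritParams make_trial
#' @param n_trials Even number of trials (default 20).
#' @param first_trial_id Trial id of the first trial (ids are consecutive).
#' @return Event tibble as in [make_trial()], with `n_trials` distinct
#'   `trial_id` values.
#' @export
make_run <- function(cond, n_trials = 20, first_trial_id = 1L) {
  if (is.character(cond)) cond <- build_condition(cond)
  if (n_trials %% 2 != 0 || n_trials < 2) {
    stop_bci("`n_trials` must be an even number of trials (half left, half right).")
  }
  sides <- sample(rep(c("left", "right"), each = n_trials / 2))
  purrr::map_dfr(seq_len(n_trials), function(k) {
    make_trial(cond, sides[k], trial_id = first_trial_id + k - 1L)
  })
}

# band-limited sawtooth via additive synthesis up to Nyquist, unit peak approx
bandlimited_sawtooth <- function(freq_hz, t) {
  k_max <- max(1, floor((0.5 / (t[2] - t[1])) / freq_hz))
  s <- numeric(length(t))
  for (k in seq_len(k_max)) {
    s <- s + (-1)^(k + 1) * sin(2 * pi * k * freq_hz * t) / k
  }
  2 * s / pi
}

tone_envelope <- function(n, fs, ramp_s) {
  t <- (seq_len(n) - 1) / fs
  dur <- n / fs
  env <- rep(1, n)
  rise <- t < ramp_s
  env[rise] <- 0.5 * (1 - cos(pi * t[rise] / ramp_s))
  fall <- t > (dur - ramp_s)
  env[fall] <- 0.5 * (1 - cos(pi * (dur - t[fall]) / ramp_s))
  env
}

#' Synthesize the stereo audio of a trial
#'
#' Renders a trial schedule as a dichotic stereo waveform: left-stream tones
#' (512-Hz fundamental) only in the left channel, right-stream tones (768 Hz)
#' only in the right. Each tone is an anti-aliased (band-limited additive)
#' sawtooth lasting 150 ms with 5-ms raised-cosine rise/fall ramps. Standards
#' are amplitude-modulated to 100% depth by a raised sinusoidal envelope at the
#' stream's AM frequency; targets are unmodulated.
#'
#' @param trial Event tibble from [make_trial()] (a single trial).
#' @param sample_rate_hz Audio rate (Hz), at least 8000; default 44100.
#' @return A list with `wave` (samples x 2 matrix, columns left/right, in
#'   \[-1, 1\]), `markers` (integer vector, nonzero exactly at stimulus-onset
#'   samples: 1 = left-stream onset, 2 = right-stream onset), and `fs_hz`.
#' @export
synthesize_audio <- function(trial, sample_rate_hz = 44100) {
  if (sample_rate_hz < 8000) stop_bci("`sample_rate_hz` must be at least 8000.")
  stopifnot(length(unique(trial$trial_id)) == 1L)
  cond <- build_condition(trial$condition[1])
  fs <- sample_rate_hz
  dur <- max(trial$onset_s) + cond$left$tone_duration_s + 0.1
  n <- ceiling(dur * fs)
  wave <- matrix(0, n, 2, dimnames = list(NULL, c("left", "right")))
  markers <- integer(n)
  for (i in seq_len(nrow(trial))) {
    side <- trial$stream[i]
    sp <- cond[[side]]
    n_tone <- round(sp$tone_duration_s * fs)
    tt <- (seq_len(n_tone) - 1) / fs
    tone <- bandlimited_sawtooth(sp$fundamental_hz, tt)
    env <- tone_envelope(n_tone, fs, sp$ramp_s)
    if (trial$kind[i] == "standard") {
      env <- env * 0.5 * (1 - cos(2 * pi * sp$am_hz * tt))
    }
    s0 <- round(trial$onset_s[i] * fs) + 1L
    idx <- s0:(s0 + n_tone - 1L)
    col <- if (side == "left") 1L else 2L
    wave[idx, col] <- wave[idx, col] + tone * env
    markers[s0] <- if (side == "left") 1L else 2L
  }
  peak <- max(abs(wave))
  if (peak > 0) wave <- 0.9 * wave / peak
  list(wave = wave, markers = markers, fs_hz = fs)
}

#' Write / read a stimulus event table as TSV
#'
#' The event table format is fixed for reproducibility: columns `trial_id`,
#' `condition`, `attended`, `stream`, `index`, `onset_s`, `kind`, one row per
#' stimulus event, UTF-8, `.` decimal separator.
#'
#' @param events Event tibble ([make_trial()] / [make_run()]).
#' @param path Output file path.
#' @return `path`, invisibly (writer); the event tibble (reader).
#' @export
write_event_tsv <- function(events, path) {
  cols <- c("trial_id", "condition", "attended", "stream", "index", "onset_s", "kind")
  readr::write_tsv(events[cols], path)
  invisible(path)
}

#' @rdname write_event_tsv
#' @export
read_event_tsv <- function(path) {
  readr::read_tsv(path, col_types = readr::cols(
    trial_id = readr::col_integer(), condition = readr::col_character(),
    attended = readr::col_character(), stream = readr::col_character(),
    index = readr::col_integer(), onset_s = readr::col_double(),
    kind = readr::col_character()
  ))
}

#' Write a 16-bit PCM stereo WAV file
#'
#' Minimal canonical RIFF/WAVE writer for the synthesized stimulus audio.
#'
#' @param wave Samples x channels numeric matrix in \[-1, 1\].
#' @param fs_hz Sample rate (Hz).
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_wav <- function(wave, fs_hz, path) {
  wave <- as.matrix(wave)
  n_ch <- ncol(wave)
  pcm <- as.integer(round(pmax(pmin(t(wave), 1), -1) * 32767))
  data_bytes <- length(pcm) * 2L
  con <- file(path, "wb")
  on.exit(close(con))
  writeChar("RIFF", con, eos = NULL)
  writeBin(as.integer(36L + data_bytes), con, size = 4, endian = "little")
  writeChar("WAVEfmt ", con, eos = NULL)
  writeBin(16L, con, size = 4, endian = "little")
  writeBin(1L, con, size = 2, endian = "little")          # PCM
  writeBin(n_ch, con, size = 2, endian = "little")
  writeBin(as.integer(fs_hz), con, size = 4, endian = "little")
  writeBin(as.integer(fs_hz * n_ch * 2L), con, size = 4, endian = "little")
  writeBin(as.integer(n_ch * 2L), con, size = 2, endian = "little")
  writeBin(16L, con, size = 2, endian = "little")
  writeChar("data", con, eos = NULL)
  writeBin(as.integer(data_bytes), con, size = 4, endian = "little")
  writeBin(pcm, con, size = 2, endian = "little")
  invisible(path)
}
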
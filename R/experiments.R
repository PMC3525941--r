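#' Preprocess a recording into epochs
#'
#' Convenience wrapper for the online chain: band-pass filter (causal,
#' 0.1-8 Hz, order 6 by default), then stimulus-locked epoch extraction.
#'
#' @param recording A `bci_recording`.
#' @param spec A [filter_spec()].
#' @param window_s,skip_per_stream Passed to [extract_epochs()].
#' @return A `bci_epochs`.
#' @export
preprocess_recording <- function(recording, spec = filter_spec(),
                                 window_s = 0.6, skip_per_stream = 2) {
  extract_epochs(bandpass(recording, spec), window_s = window_s,
                 skip_per_stream = skip_per_stream)
}

#' Fixed-phase vs drifting-phase SNR simulation
#'
#' Single-channel simulation of the two stream designs: for each condition,
#' `n_instances` attend-left and `n_instances` attend-right trials are
#' generated (biphasic ERP convolved with the stimulus impulse train, 20%
#' larger when attended, plus pink noise at twice the signal SD), passed
#' through the online preprocessing chain, and reduced to final difference
#' features. The sensitivity index d_a is computed per epoch sample across
#' instances (attend-right as the "attended" group), and the summary ratio is
#' `max_t |d_a_FP| / max_t |d_a_DP|`.
#'
#' @param conditions Two condition names; default `c("FP", "DP")`.
#' @param n_instances Noise instances (trials) per class per condition;
#'   default 1000.
#' @param erp An [erp_model()] (default: 20% attention gain).
#' @param noise A [noise_model()] (default: pink, SD ratio 2).
#' @param fs_hz Sampling rate; default 256.
#' @param spec Band-pass [filter_spec()] for the online chain.
#' @return A `bci_snr`: list with `d_a` (tibble: `condition`, `time_s`, `d_a`),
#'   `peaks` (per-condition max |d_a|), `summary_ratio`, and `n_instances`.
#' @export
snr_simulation <- function(conditions = c("FP", "DP"), n_instances = 1000,
                           erp = erp_model(), noise = noise_model(),
                           fs_hz = 256, spec = filter_spec()) {
  if (n_instances < 2) stop_bci("`n_instances` must be at least 2.")
  per_cond <- purrr::map(conditions, function(cond) {
    sides <- rep(c("left", "right"), each = n_instances)
    sched <- purrr::map_dfr(seq_along(sides), function(k) {
      make_trial(cond, sides[k], trial_id = k)
    })
    rec <- simulate_recording(sched, erp = erp, noise = noise,
                              fs_hz = fs_hz, n_channels = 1)
    feats <- trial_features(preprocess_recording(rec, spec))
    m <- t(vapply(feats$x_delta, function(x) as.numeric(x),
                  numeric(length(feats$x_delta[[1]]))))
    right <- m[feats$attended == "right", , drop = FALSE]
    left <- m[feats$attended == "left", , drop = FALSE]
    vapply(seq_len(ncol(m)), function(j) {
      sensitivity_index(right[, j], left[, j])
    }, numeric(1))
  })
  len <- length(per_cond[[1]])
  d_a <- purrr::map_dfr(seq_along(conditions), function(i) {
    tibble::tibble(condition = conditions[i],
                   time_s = (seq_len(len) - 1) / fs_hz, d_a = per_cond[[i]])
  })
  peaks <- vapply(per_cond, function(v) max(abs(v)), numeric(1))
  names(peaks) <- conditions
  structure(
    list(d_a = d_a, peaks = peaks,
         summary_ratio = if (length(peaks) >= 2) peaks[[1]] / peaks[[2]] else NA_real_,
         n_instances = n_instances),
    class = "bci_snr"
  )
}

#' @export
print.bci_snr <- function(x, ...) {
  cat(sprintf("<bci_snr> peak |d_a|: %s; ratio %s/%s = %.2f (n = %d per class)\n",
              paste(sprintf("%s %.3f", names(x$peaks), x$peaks), collapse = ", "),
              names(x$peaks)[1], names(x$peaks)[2], x$summary_ratio, x$n_instances))
  invisible(x)
}

#' Synthetic within-subject comparison of the two stream designs
#'
#' Simulates a cohort (or takes one), runs the incremental retraining protocol
#' per subject and condition, and compares per-subject accuracies between the
#' two conditions with the exact Wilcoxon signed-rank test.
#'
#' @param cohort A `bci_cohort` from [simulate_cohort()], or `NULL` to
#'   simulate one with the remaining arguments.
#' @param lambda,ridge Decoder settings ([train_decoder()], [fit_whitener()]).
#' @param spec Band-pass [filter_spec()] for the online chain.
#' @param ... Passed to [simulate_cohort()] when `cohort` is `NULL`.
#' @return A `bci_experiment`: list with `accuracies` (tibble: `subject`,
#'   `condition`, `accuracy`, `n_scored`), `comparison` (Wilcoxon tibble for
#'   condition 1 minus condition 2), `n_superior` (subjects where condition 1
#'   beat condition 2), and the cohort's `subjects` parameters.
#' @export
experiment1_analog <- function(cohort = NULL, lambda = 1, ridge = NULL,
                               spec = filter_spec(), ...) {
  cohort <- cohort %||% simulate_cohort(...)
  runs <- cohort$runs
  acc <- dplyr::group_by(runs, .data$subject, .data$condition)
  acc <- dplyr::summarise(acc, result = {
    eps <- purrr::map(.data$recording[order(.data$run)], preprocess_recording, spec = spec)
    pr <- incremental_protocol(eps, lambda = lambda, ridge = ridge)
    list(tibble::tibble(accuracy = pr$accuracy, n_scored = pr$n_scored))
  }, .groups = "drop")
  acc <- tidyr::unnest(acc, "result")
  conds <- unique(cohort$runs$condition)
  wide <- tidyr::pivot_wider(acc[, c("subject", "condition", "accuracy")],
                             names_from = "condition", values_from = "accuracy")
  diffs <- wide[[conds[1]]] - wide[[conds[2]]]
  structure(
    list(accuracies = acc,
         comparison = wilcoxon_signed_rank(diffs),
         n_superior = sum(diffs > 0), n_subjects = length(diffs),
         subjects = cohort$subjects),
    class = "bci_experiment"
  )
}

#' @export
print.bci_experiment <- function(x, ...) {
  cat(sprintf("<bci_experiment> %d subjects; condition 1 superior for %d; Wilcoxon p = %.4g\n",
              x$n_subjects, x$n_superior, x$comparison$p_value))
  invisible(x)
}

#' Reverse a recording in time (backward playback)
#'
#' Reverses the sample order of every channel while keeping the original event
#' table, destroying any meaningful relationship between the stimulus events
#' and the signal. Classifying backward-played recordings estimates
#' chance-level performance.
#'
#' @param recording A `bci_recording`.
#' @return The time-reversed `bci_recording`.
#' @export
backward_playback <- function(recording) {
  recording$data <- recording$data[, rev(seq_len(ncol(recording$data))), drop = FALSE]
  recording
}

#' Train-test accuracy of the full decoding chain
#'
#' Generates independent training and test runs of one condition, trains the
#' whitened logistic decoder on the training trials, and reports the percent of
#' test trials whose final difference feature is classified correctly. With
#' `reversed = TRUE` the test recording is played backward before
#' preprocessing, which estimates chance performance.
#'
#' @param n_train,n_test Even numbers of training and test trials.
#' @param condition Condition name; default `"FP"`.
#' @param erp,noise Generator models ([erp_model()], [noise_model()]).
#' @param n_channels,fs_hz Recording geometry.
#' @param lambda,ridge Decoder settings.
#' @param spec Band-pass [filter_spec()].
#' @param reversed Play the test recording backward (default `FALSE`).
#' @return Tibble with `accuracy` (%), `n_correct`, `n_test`.
#' @export
holdout_accuracy <- function(n_train, n_test, condition = "FP",
                             erp = erp_model(), noise = noise_model(),
                             n_channels = 16, fs_hz = 256, lambda = 1,
                             ridge = NULL, spec = filter_spec(),
                             reversed = FALSE) {
  train_rec <- simulate_recording(make_run(condition, n_train), erp = erp,
                                  noise = noise, fs_hz = fs_hz,
                                  n_channels = n_channels)
  test_rec <- simulate_recording(make_run(condition, n_test), erp = erp,
                                 noise = noise, fs_hz = fs_hz,
                                 n_channels = n_channels)
  if (reversed) test_rec <- backward_playback(test_rec)
  train_ep <- preprocess_recording(train_rec, spec)
  wh <- fit_whitener(train_ep, ridge = ridge)
  model <- train_decoder(trial_features(train_ep), whitener = wh, lambda = lambda)
  pred <- predict(model, trial_features(preprocess_recording(test_rec, spec)))
  n_correct <- sum(pred$predicted == pred$attended)
  tibble::tibble(accuracy = 100 * n_correct / nrow(pred),
                 n_correct = n_correct, n_test = nrow(pred))
}

# assemble gaze traces into a single-channel recording aligned with the
# schedule's segment layout, so the EEG preprocessing chain applies unchanged
gaze_recording <- function(gaze_tbl, schedule, fs_hz = 256) {
  seg <- trial_segment(fs_hz)
  ids <- unique(schedule$trial_id)
  data <- matrix(0, 1, seg$n * length(ids))
  ev_list <- vector("list", length(ids))
  for (j in seq_along(ids)) {
    g <- gaze_tbl[gaze_tbl$trial_id == ids[j] &
                    gaze_tbl$time_s >= -(seg$pre + 0.5) / fs_hz, ]
    x <- g$x[seq_len(seg$n)]
    if (anyNA(x)) stop_bci("Gaze trace does not cover the recording segment.")
    data[1, ((j - 1) * seg$n + 1):(j * seg$n)] <- x
    tr <- schedule[schedule$trial_id == ids[j], ]
    ev_list[[j]] <- dplyr::mutate(
      tr, sample = (j - 1L) * seg$n + seg$pre + round(.data$onset_s * fs_hz) + 1L)
  }
  structure(
    list(data = data, fs_hz = fs_hz, channel_labels = "gaze_x",
         events = dplyr::bind_rows(ev_list),
         attended = dplyr::distinct(schedule, .data$trial_id, .data$attended),
         pre_s = seg$pre / fs_hz, segment_samples = seg$n),
    class = "bci_recording"
  )
}

# per-sample signed r^2 of a trials x samples matrix against labels
r2_time_course <- function(m, labels) {
  vapply(seq_len(ncol(m)), function(j) {
    if (sd(m[, j]) == 0) 0 else signed_r2(m[, j], labels)
  }, numeric(1))
}

#' Gaze dependence audit
#'
#' For each subject (one condition of a cohort simulated with gaze traces),
#' computes three single-feature separability summaries: the peak signed-r^2
#' magnitude of raw horizontal gaze position across trial time, of gaze after
#' the full preprocessing chain (band-pass, epoching, difference of averages -
#' gaze treated as if it were an EEG channel), and of the preprocessed EEG
#' decoding channel (Cz by default). Each summary is then rank-correlated with
#' per-subject decoding accuracy to ask whether the decoder could be relying on
#' gaze.
#'
#' @param cohort A `bci_cohort` simulated with `with_gaze = TRUE`.
#' @param accuracies Tibble with `subject` and `accuracy` (e.g. from
#'   [experiment1_analog()]`$accuracies`, one condition).
#' @param condition Condition to audit; default `"FP"`.
#' @param channel EEG channel for the reference feature; default `"Cz"`.
#' @param spec Band-pass [filter_spec()].
#' @return A `bci_gaze_audit`: list with `subjects` (tibble: `subject`,
#'   `peak_r2_gaze_raw`, `peak_r2_gaze_preprocessed`, `peak_r2_eeg`,
#'   `accuracy`) and `correlations` (Spearman tibble per feature).
#' @export
gaze_audit <- function(cohort, accuracies, condition = "FP", channel = "Cz",
                       spec = filter_spec()) {
  runs <- cohort$runs[cohort$runs$condition == condition, ]
  if (!"gaze" %in% names(runs)) stop_bci("Cohort was simulated without gaze traces.")
  per_subj <- purrr::map_dfr(unique(runs$subject), function(s) {
    rs <- runs[runs$subject == s, ]
    # raw gaze: per time sample across trials
    gz <- dplyr::bind_rows(purrr::map2(rs$gaze, seq_len(nrow(rs)), function(g, k) {
      dplyr::mutate(g, trial_uid = paste(k, .data$trial_id))
    }))
    gm <- tidyr::pivot_wider(gz[, c("trial_uid", "time_s", "x")],
                             names_from = "time_s", values_from = "x")
    labels <- gz$attended[!duplicated(gz$trial_uid)]
    raw_r2 <- r2_time_course(as.matrix(gm[, -1]), labels)
    # preprocessed gaze: through the EEG chain
    pre_feats <- purrr::map2_dfr(rs$gaze, rs$schedule, function(g, sched) {
      rec <- gaze_recording(g, sched)
      trial_features(preprocess_recording(rec, spec))
    })
    pre_m <- t(vapply(pre_feats$x_delta, as.numeric,
                      numeric(length(pre_feats$x_delta[[1]]))))
    pre_r2 <- r2_time_course(pre_m, pre_feats$attended)
    # preprocessed EEG at the reference channel
    eeg_feats <- purrr::map_dfr(rs$recording, function(rec) {
      trial_features(preprocess_recording(rec, spec))
    })
    ch <- match(channel, rs$recording[[1]]$channel_labels)
    if (is.na(ch)) stop_bci(sprintf("Channel %s not found in the recording montage.", channel))
    eeg_m <- t(vapply(eeg_feats$x_delta, function(x) x[ch, ],
                      numeric(ncol(eeg_feats$x_delta[[1]]))))
    eeg_r2 <- r2_time_course(eeg_m, eeg_feats$attended)
    tibble::tibble(subject = s,
                   peak_r2_gaze_raw = max(abs(raw_r2)),
                   peak_r2_gaze_preprocessed = max(abs(pre_r2)),
                   peak_r2_eeg = max(abs(eeg_r2)))
  })
  per_subj <- dplyr::left_join(per_subj, accuracies[, c("subject", "accuracy")],
                               by = "subject")
  correlations <- purrr::map_dfr(
    c("peak_r2_gaze_raw", "peak_r2_gaze_preprocessed", "peak_r2_eeg"),
    function(v) {
      dplyr::mutate(spearman_rank(per_subj[[v]], per_subj$accuracy),
                    feature = v, .before = 1)
    })
  structure(list(subjects = per_subj, correlations = correlations),
            class = "bci_gaze_audit")
}
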
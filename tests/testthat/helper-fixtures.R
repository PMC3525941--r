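# shared fixtures: all synthetic, built in code at test time

# tiny noiseless recording of `n_trials` FP trials (alternating attention)
noiseless_recording <- function(n_trials = 2, n_channels = 1, gain = 1.2,
                                condition = "FP") {
  sides <- rep(c("left", "right"), length.out = n_trials)
  sched <- purrr::map_dfr(seq_len(n_trials), function(k) {
    make_trial(condition, sides[k], n_targets_left = 1, n_targets_right = 1,
               trial_id = k)
  })
  simulate_recording(sched, erp = erp_model(attended_gain = gain),
                     noise = noise_model(sd_ratio = 0), n_channels = n_channels)
}

# epoch set with hand-chosen epoch matrices (bypasses the generator)
manual_epochs <- function(mats, stream, trial_id = rep(1L, length(mats)),
                          attended = "right", fs_hz = 256) {
  n_ch <- nrow(mats[[1]]); len <- ncol(mats[[1]])
  arr <- array(0, dim = c(length(mats), n_ch, len))
  for (i in seq_along(mats)) arr[i, , ] <- mats[[i]]
  structure(
    list(epochs = arr, stream = stream, trial_id = trial_id,
         onset_sample = seq_along(mats), fs_hz = fs_hz, window_s = len / fs_hz,
         attended = tibble::tibble(trial_id = unique(trial_id),
                                   attended = attended),
         channel_labels = paste0("ch", seq_len(n_ch))),
    class = "bci_epochs"
  )
}
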
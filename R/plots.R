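#' @importFrom ggplot2 autoplot ggplot aes geom_line geom_point geom_hline
#'   geom_abline geom_vline labs facet_wrap theme_minimal
#' @export
ggplot2::autoplot

#' Plot the per-sample sensitivity-index time courses
#'
#' One d_a trace per condition over the difference-feature epoch.
#'
#' @param object A `bci_snr` from [snr_simulation()].
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.bci_snr <- function(object, ...) {
  ggplot(object$d_a, aes(x = .data$time_s * 1000, y = .data$d_a,
                         colour = .data$condition)) +
    geom_hline(yintercept = 0, colour = "grey70") +
    geom_line() +
    labs(x = "Time after stimulus onset (ms)", y = expression(d[a]),
         colour = "Condition",
         title = "Sensitivity of difference features, per epoch sample") +
    theme_minimal()
}

#' Plot per-subject accuracies of the two stream designs
#'
#' Scatter of condition-1 vs condition-2 accuracy, one point per subject, with
#' the identity line and the 50% chance level.
#'
#' @param object A `bci_experiment` from [experiment1_analog()].
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.bci_experiment <- function(object, ...) {
  conds <- unique(object$accuracies$condition)
  wide <- tidyr::pivot_wider(
    object$accuracies[, c("subject", "condition", "accuracy")],
    names_from = "condition", values_from = "accuracy")
  ggplot(wide, aes(x = .data[[conds[2]]], y = .data[[conds[1]]])) +
    geom_abline(slope = 1, intercept = 0, colour = "grey60") +
    geom_hline(yintercept = 50, linetype = 2, colour = "grey70") +
    geom_vline(xintercept = 50, linetype = 2, colour = "grey70") +
    geom_point() +
    labs(x = paste0(conds[2], " accuracy (%)"), y = paste0(conds[1], " accuracy (%)"),
         title = "Per-subject decoding accuracy by stimulus design") +
    theme_minimal()
}

#' Plot grand-average traces for selected channels
#'
#' @param epochs A `bci_epochs`.
#' @param channels Channel labels to plot (default `c("Cz", "Fz")` when
#'   present, else the first channel).
#' @param groups Optional per-epoch grouping (see [grand_average()]).
#' @return A ggplot of group-mean traces per channel.
#' @export
plot_grand_average <- function(epochs, channels = NULL, groups = NULL) {
  ga <- grand_average(epochs, groups)
  channels <- channels %||%
    intersect(c("Cz", "Fz"), epochs$channel_labels) %||% epochs$channel_labels[1]
  if (length(channels) == 0) channels <- epochs$channel_labels[1]
  df <- purrr::map_dfr(names(ga), function(g) {
    purrr::map_dfr(channels, function(ch) {
      tibble::tibble(group = g, channel = ch,
                     time_ms = (seq_len(ncol(ga[[g]])) - 1) / epochs$fs_hz * 1000,
                     value = ga[[g]][match(ch, epochs$channel_labels), ])
    })
  })
  ggplot(df, aes(x = .data$time_ms, y = .data$value, colour = .data$group)) +
    geom_hline(yintercept = 0, colour = "grey70") +
    geom_line() +
    facet_wrap(~channel) +
    labs(x = "Time after stimulus onset (ms)", y = "Amplitude (a.u.)",
         colour = NULL, title = "Grand-average stimulus-locked response") +
    theme_minimal()
}

#' Plot gaze-audit relationships
#'
#' Decoding accuracy against each per-subject peak r-squared summary.
#'
#' @param object A `bci_gaze_audit`.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.bci_gaze_audit <- function(object, ...) {
  long <- tidyr::pivot_longer(object$subjects,
                              cols = dplyr::starts_with("peak_r2"),
                              names_to = "feature", values_to = "peak_r2")
  ggplot(long, aes(x = .data$peak_r2, y = .data$accuracy)) +
    geom_point() +
    facet_wrap(~feature, scales = "free_x") +
    labs(x = expression("Peak " * r^2), y = "Accuracy (%)",
         title = "Decoding accuracy vs single-feature separability") +
    theme_minimal()
}
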
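#' @importFrom generics tidy glance
#' @export
generics::tidy

#' @export
generics::glance

#' Tidy a fitted decoder
#'
#' One row per (channel, sample) weight in whitened feature space.
#'
#' @param x A `bci_decoder`.
#' @param ... Unused.
#' @return Tibble with `channel`, `sample` (1-based epoch sample), `weight`.
#' @export
tidy.bci_decoder <- function(x, ...) {
  w <- x$weights
  labels <- x$channel_labels %||% paste0("ch", seq_len(nrow(w)))
  tibble::tibble(channel = rep(labels, times = ncol(w)),
                 sample = rep(seq_len(ncol(w)), each = nrow(w)),
                 weight = as.numeric(w))
}

#' @export
glance.bci_decoder <- function(x, ...) {
  tibble::tibble(lambda = x$lambda, bias = x$bias,
                 feature_scale = x$feature_scale, n_train = x$n_train,
                 ridge = x$whitener$ridge, converged = x$convergence == 0)
}

#' @export
tidy.bci_snr <- function(x, ...) x$d_a

#' @export
glance.bci_snr <- function(x, ...) {
  tibble::tibble(condition_1 = names(x$peaks)[1], condition_2 = names(x$peaks)[2],
                 peak_1 = x$peaks[[1]], peak_2 = x$peaks[[2]],
                 summary_ratio = x$summary_ratio, n_instances = x$n_instances)
}

#' @export
tidy.bci_experiment <- function(x, ...) x$accuracies

#' @export
glance.bci_experiment <- function(x, ...) {
  tibble::tibble(n_subjects = x$n_subjects, n_superior = x$n_superior,
                 statistic = x$comparison$statistic,
                 p_value = x$comparison$p_value)
}

#' @export
tidy.bci_protocol <- function(x, ...) x$trials

#' @export
glance.bci_protocol <- function(x, ...) {
  tibble::tibble(accuracy = x$accuracy, n_scored = x$n_scored)
}

#' @export
tidy.bci_gaze_audit <- function(x, ...) x$subjects

#' @export
glance.bci_gaze_audit <- function(x, ...) {
  tidyr::pivot_wider(x$correlations[, c("feature", "rho", "p_value")],
                     names_from = "feature",
                     values_from = c("rho", "p_value"))
}
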
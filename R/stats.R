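#' Sensitivity index d_a
#'
#' The separation between attended and unattended feature distributions:
#' `d_a = (mu_att - mu_unatt) / sqrt((var_att + var_unatt) / 2)` - the mean
#' difference divided by the RMS of the two group SDs (sample SDs, n-1
#' denominator).
#'
#' @param attended,unattended Numeric vectors of per-trial feature values,
#'   each of length at least 2.
#' @return Scalar d_a. Zero pooled variance yields a signed infinity with a
#'   warning.
#' @export
sensitivity_index <- function(attended, unattended) {
  if (length(attended) < 2 || length(unattended) < 2) {
    stop_bci("Each group needs at least 2 observations.")
  }
  if (any(!is.finite(c(attended, unattended)))) stop_bci("Values must be finite.")
  num <- mean(attended) - mean(unattended)
  pooled <- sqrt((var(attended) + var(unattended)) / 2)
  if (pooled == 0) {
    rlang::warn("Zero pooled variance: d_a is infinite.")
    return(sign(num) * Inf)
  }
  num / pooled
}

#' Signed coefficient of determination (signed r-squared)
#'
#' The squared point-biserial correlation between a feature and a binary class
#' label, carrying the sign of the correlation. The positive class is
#' `"right"` (or the larger of two numeric/logical label values), so a
#' positive value means the feature is larger on attend-right trials.
#'
#' @param values Numeric feature vector.
#' @param labels Binary labels: `"left"`/`"right"`, logical, or two-valued.
#' @return Scalar in \[-1, 1\]. Constant `values` return 0 with a warning.
#' @export
signed_r2 <- function(values, labels) {
  y <- if (is.character(labels) || is.factor(labels)) {
    as.numeric(as.character(labels) == "right")
  } else as.numeric(labels)
  if (length(unique(y)) != 2) stop_bci("Both classes must be present.")
  if (sd(values) == 0) {
    rlang::warn("Constant values: signed r-squared is 0.")
    return(0)
  }
  r <- cor(values, y)
  sign(r) * r^2
}

#' Regions of interest of the attention-modulated ERP
#'
#' Named latency windows (ms after stimulus onset) used for grand-average and
#' difference-wave summaries: the grand-average components N1 (70-125 ms),
#' P2 (150-240 ms), P3 (250-310 ms), and the difference-wave ranges
#' delta1 (50-90 ms), delta2 (120-190 ms), delta3 (200-265 ms).
#'
#' @return Tibble with columns `name`, `start_ms`, `end_ms`.
#' @export
roi_windows <- function() {
  tibble::tibble(
    name = c("N1", "P2", "P3", "delta1", "delta2", "delta3"),
    start_ms = c(70, 150, 250, 50, 120, 200),
    end_ms = c(125, 240, 310, 90, 190, 265)
  )
}

#' Grand-average epochs by group
#'
#' Arithmetic mean over epochs within each group, giving one channels x samples
#' matrix per group.
#'
#' @param epochs A `bci_epochs`.
#' @param groups Per-epoch grouping vector; defaults to whether each epoch's
#'   stream was the attended one (`"attended"` vs `"unattended"`).
#' @return Named list of channels x samples matrices.
#' @export
grand_average <- function(epochs, groups = NULL) {
  if (is.null(groups)) {
    att <- epochs$attended$attended[match(epochs$trial_id, epochs$attended$trial_id)]
    groups <- ifelse(epochs$stream == att, "attended", "unattended")
  }
  d <- dim(epochs$epochs)
  out <- lapply(split(seq_len(d[1]), groups), function(idx) {
    m <- stream_mean(epochs$epochs, idx, d[2], d[3])
    rownames(m) <- epochs$channel_labels
    m
  })
  if (any(vapply(split(seq_len(d[1]), groups), length, integer(1)) == 0)) {
    stop_bci("Every group must contain at least one epoch.")
  }
  out
}

#' Mean over a latency window
#'
#' Averages a channels x samples matrix (e.g. a grand average or d_a time
#' course) over the samples falling in `[start_ms, end_ms]`.
#'
#' @param avg Channels x samples matrix, sample 1 at latency 0.
#' @param start_ms,end_ms Window bounds (ms).
#' @param fs_hz Sampling rate (Hz).
#' @return Named per-channel vector of window means.
#' @export
roi_mean <- function(avg, start_ms, end_ms, fs_hz = 256) {
  if (end_ms <= start_ms) stop_bci("Need start_ms < end_ms.")
  t_ms <- (seq_len(ncol(avg)) - 1) / fs_hz * 1000
  idx <- which(t_ms >= start_ms & t_ms <= end_ms)
  if (length(idx) == 0) stop_bci("Window contains no samples within the epoch.")
  rowMeans(avg[, idx, drop = FALSE])
}

# exact null distribution of the signed-rank statistic W+ over all 2^n sign
# assignments, via the subset-sum generating polynomial on doubled mid-ranks
signed_rank_distribution <- function(ranks2) {
  total <- sum(ranks2)
  counts <- numeric(total + 1)
  counts[1] <- 1
  for (r in ranks2) {
    shifted <- c(numeric(r), counts[seq_len(total + 1 - r)])
    counts <- counts + shifted
  }
  counts # counts[s + 1] = number of assignments with doubled W+ == s
}

#' Exact Wilcoxon signed-rank test
#'
#' Two-sided test of symmetry about zero for paired differences. Zero
#' differences are dropped; ties receive mid-ranks. For up to 25 informative
#' pairs the p-value is exact, from the full null distribution over all 2^n
#' sign assignments; beyond that, a normal approximation with tie correction
#' and continuity correction is used.
#'
#' @param differences Numeric vector of paired differences.
#' @return Tibble with `statistic` (W+, sum of positive-difference ranks),
#'   `n` (informative pairs), `p_value`, and `method`.
#' @export
wilcoxon_signed_rank <- function(differences) {
  if (any(!is.finite(differences))) stop_bci("Differences must be finite.")
  d <- differences[differences != 0]
  n <- length(d)
  if (n == 0) {
    rlang::warn("All differences are zero; p = 1.")
    return(tibble::tibble(statistic = 0, n = 0L, p_value = 1, method = "exact"))
  }
  r <- rank(abs(d))
  w <- sum(r[d > 0])
  if (n <= 25) {
    ranks2 <- as.integer(round(2 * r))
    counts <- signed_rank_distribution(ranks2)
    support <- (seq_along(counts) - 1) # doubled W+
    mu <- sum(ranks2) / 2
    dev <- abs(round(2 * w) - mu)
    p <- sum(counts[abs(support - mu) >= dev - 1e-9]) / 2^n
    method <- "exact"
  } else {
    mu <- n * (n + 1) / 4
    ties <- table(r)
    sig2 <- n * (n + 1) * (2 * n + 1) / 24 - sum(ties^3 - ties) / 48
    z <- (abs(w - mu) - 0.5) / sqrt(sig2)
    p <- 2 * pnorm(-z)
    method <- "normal approximation"
  }
  tibble::tibble(statistic = w, n = as.integer(n), p_value = min(p, 1), method = method)
}

#' Fisher's exact test (two-sided, probability-mass rule)
#'
#' Exact test of independence in a 2x2 table. The two-sided p-value is the sum
#' of hypergeometric probabilities, over all tables with the observed margins,
#' that do not exceed the probability of the observed table.
#'
#' @param table_2x2 2x2 matrix of non-negative integer counts.
#' @return Tibble with `p_value` and `odds_ratio` (sample OR).
#' @export
fisher_exact <- function(table_2x2) {
  t <- as.matrix(table_2x2)
  if (!all(dim(t) == 2) || any(t < 0) || sum(t) == 0) {
    stop_bci("`table_2x2` must be a 2x2 table of non-negative counts with positive total.")
  }
  x <- t[1, 1]; r1 <- sum(t[1, ]); c1 <- sum(t[, 1]); n <- sum(t)
  supp <- max(0, r1 + c1 - n):min(r1, c1)
  probs <- dhyper(supp, c1, n - c1, r1)
  p_obs <- dhyper(x, c1, n - c1, r1)
  p <- sum(probs[probs <= p_obs * (1 + 1e-7)])
  or <- (t[1, 1] * t[2, 2]) / (t[1, 2] * t[2, 1])
  tibble::tibble(p_value = min(p, 1), odds_ratio = or)
}

# all permutations of 1..n as an n!-row matrix
all_permutations <- function(n) {
  p <- matrix(1L, 1, 1)
  for (m in 2:n) {
    p <- do.call(rbind, lapply(seq_len(m), function(i) {
      cbind(i, p + (p >= i))
    }))
  }
  p
}

#' Spearman rank correlation with exact permutation p-value
#'
#' Rho is the Pearson correlation of mid-ranks. For n <= 9 the two-sided
#' p-value is exact, by enumeration of all n! permutations; for larger n a
#' t-distribution approximation is used.
#'
#' @param x,y Numeric vectors of equal length, n >= 4, neither constant.
#' @return Tibble with `rho`, `n`, `p_value`, `method`.
#' @export
spearman_rank <- function(x, y) {
  n <- length(x)
  if (n < 4 || length(y) != n) stop_bci("Need vectors of equal length, n >= 4.")
  if (sd(x) == 0 || sd(y) == 0) stop_bci("Inputs must not be constant.")
  rx <- rank(x); ry <- rank(y)
  rho <- cor(rx, ry)
  if (n <= 9) {
    perms <- all_permutations(n)
    rxs <- as.numeric(scale(rx)); rys <- as.numeric(scale(ry))
    rho_perm <- (matrix(rxs[perms], nrow(perms), n) %*% rys) / (n - 1)
    p <- mean(abs(rho_perm) >= abs(rho) - 1e-12)
    method <- "exact permutation"
  } else {
    tt <- rho * sqrt((n - 2) / max(1 - rho^2, .Machine$double.eps))
    p <- 2 * stats::pt(-abs(tt), df = n - 2)
    method <- "t approximation"
  }
  tibble::tibble(rho = rho, n = as.integer(n), p_value = min(p, 1), method = method)
}

#' Hit rate as a percentage
#'
#' @param hits,misses Non-negative counts with positive total.
#' @return Percentage `100 * hits / (hits + misses)`, reported to one decimal.
#' @export
hit_rate <- function(hits, misses) {
  if (hits + misses <= 0) stop_bci("`hits + misses` must be positive.")
  round(100 * hits / (hits + misses), 1)
}
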
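test_that("sensitivity index follows its defining formula and antisymmetry", {
  expect_equal(sensitivity_index(c(1, 1.5, 0.5), c(0.2, 0.8, 1.1, 0.9)),
               {
                 a <- c(1, 1.5, 0.5); u <- c(0.2, 0.8, 1.1, 0.9)
                 (mean(a) - mean(u)) / sqrt((var(a) + var(u)) / 2)
               })
  expect_equal(sensitivity_index(c(0, 1, 2), c(0, 1, 2)), 0)
  # mu_att = 1, mu_unatt = 0, sd = sd = 1 -> d_a = 1
  a <- c(0, 1, 2) / sd(c(0, 1, 2)) # sd exactly 1
  expect_equal(sensitivity_index(a + (1 - mean(a)), a - mean(a)), 1,
               tolerance = 1e-12)
  set.seed(1)
  x <- rnorm(20); y <- rnorm(25, 0.3)
  expect_equal(sensitivity_index(x, y), -sensitivity_index(y, x))
  expect_warning(d <- sensitivity_index(c(1, 1), c(0, 0)), "infinite")
  expect_identical(d, Inf)
  expect_error(sensitivity_index(1, c(0, 1)), "at least 2")
})

test_that("signed r-squared matches the point-biserial oracle and its invariances", {
  labels <- rep(c("left", "right"), each = 10)
  set.seed(2)
  v <- rnorm(20) + (labels == "right")
  r <- cor(v, as.numeric(labels == "right"))
  expect_equal(signed_r2(v, labels), sign(r) * r^2, tolerance = 1e-12)
  # perfectly separated constant groups -> +/-1
  expect_equal(signed_r2(rep(c(0, 1), each = 5), rep(c("left", "right"), each = 5)), 1)
  expect_equal(signed_r2(rep(c(1, 0), each = 5), rep(c("left", "right"), each = 5)), -1)
  # invariant to positive affine rescaling; sign flips under negation
  expect_equal(signed_r2(3 * v + 7, labels), signed_r2(v, labels), tolerance = 1e-12)
  expect_equal(signed_r2(-v, labels), -signed_r2(v, labels), tolerance = 1e-12)
  # independent labels, larger n -> near zero
  set.seed(3)
  big <- rnorm(4000)
  expect_lt(abs(signed_r2(big, rep(c("left", "right"), 2000))), 0.01)
  expect_warning(z <- signed_r2(rep(1, 10), rep(c("left", "right"), 5)), "Constant")
  expect_identical(z, 0)
})

test_that("grand averages and ROI means match a nested-loop oracle", {
  set.seed(4)
  mats <- lapply(1:6, function(i) matrix(rnorm(2 * 12), 2, 12))
  ep <- manual_epochs(mats, stream = rep(c("left", "right"), 3),
                      trial_id = rep(1L, 6), attended = "right")
  ga <- grand_average(ep, groups = rep(c("g1", "g2"), 3))
  oracle <- Reduce(`+`, mats[c(1, 3, 5)]) / 3
  expect_equal(unname(ga$g1), unname(oracle), tolerance = 1e-12)
  # all-equal epochs: grand average equals any single epoch
  same <- manual_epochs(rep(mats[1], 3), stream = c("left", "right", "left"))
  expect_equal(unname(grand_average(same, groups = rep("all", 3))$all),
               unname(mats[[1]]), tolerance = 1e-12)
  # ROI mean of a constant channel is that constant
  const <- matrix(1, 1, 256)
  expect_equal(unname(roi_mean(const, 70, 125, fs_hz = 256)), 1)
  # oracle for a random window
  m <- matrix(rnorm(2 * 256), 2, 256)
  t_ms <- (0:255) / 256 * 1000
  idx <- which(t_ms >= 150 & t_ms <= 240)
  expect_equal(unname(roi_mean(m, 150, 240, 256)), rowMeans(m[, idx]),
               tolerance = 1e-12)
  expect_error(roi_mean(m, 240, 150), "start_ms < end_ms")
  expect_true(all(roi_windows()$start_ms < roi_windows()$end_ms))
})

test_that("exact Wilcoxon signed-rank p-values match brute-force enumeration", {
  # all five differences positive: two-sided p = 2/32
  res <- wilcoxon_signed_rank(c(0.3, 1, 2, 0.5, 4))
  expect_equal(res$p_value, 0.0625)
  expect_equal(res$statistic, 15)
  # mirrored data: perfectly symmetric, p = 1
  expect_equal(wilcoxon_signed_rank(c(-2, -1, 1, 2))$p_value, 1)
  # zeros are dropped
  expect_equal(wilcoxon_signed_rank(c(0, 0.3, 1, 2, 0.5, 4, 0))$n, 5L)
  expect_warning(res0 <- wilcoxon_signed_rank(c(0, 0)), "zero")
  expect_equal(res0$p_value, 1)
  # n = 10 random data vs full 2^10 enumeration oracle
  set.seed(5)
  d <- rnorm(10, 0.4)
  r <- rank(abs(d)); w_obs <- sum(r[d > 0])
  signs <- as.matrix(expand.grid(rep(list(c(0, 1)), 10)))
  w_all <- as.numeric(signs %*% r)
  mu <- sum(r) / 2
  p_oracle <- mean(abs(w_all - mu) >= abs(w_obs - mu) - 1e-9)
  expect_equal(wilcoxon_signed_rank(d)$p_value, p_oracle, tolerance = 1e-12)
  # and against the base-R exact test on tie-free data
  expect_equal(wilcoxon_signed_rank(d)$p_value,
               wilcox.test(d, exact = TRUE)$p.value, tolerance = 1e-12)
  # large-n normal approximation stays within 0.01 of exact at n = 25
  set.seed(6)
  d25 <- rnorm(25, 0.2)
  exact <- wilcoxon_signed_rank(d25)$p_value
  r25 <- rank(abs(d25)); w25 <- sum(r25[d25 > 0])
  mu25 <- 25 * 26 / 4; sig <- sqrt(25 * 26 * 51 / 24)
  approx_p <- 2 * pnorm(-(abs(w25 - mu25) - 0.5) / sig)
  expect_lt(abs(exact - approx_p), 0.01)
})

test_that("Fisher's exact test matches the hypergeometric-sum oracle", {
  expect_equal(fisher_exact(matrix(1, 2, 2))$p_value, 1)
  # zero margin: only one table possible
  expect_equal(fisher_exact(matrix(c(0, 0, 3, 5), 2))$p_value, 1)
  # probability-mass rule vs base R on assorted tables
  tables <- list(matrix(c(55, 33, 35, 161), 2), matrix(c(3, 1, 1, 3), 2),
                 matrix(c(10, 2, 3, 15), 2), matrix(c(2, 7, 8, 2), 2))
  for (tb in tables) {
    expect_equal(fisher_exact(tb)$p_value, fisher.test(tb)$p.value,
                 tolerance = 1e-10)
    p <- fisher_exact(tb)$p_value
    expect_true(p > 0 && p <= 1)
    # invariant under transpose and under swapping both rows and columns
    expect_equal(fisher_exact(t(tb))$p_value, p, tolerance = 1e-12)
    expect_equal(fisher_exact(tb[2:1, 2:1])$p_value, p, tolerance = 1e-12)
  }
  expect_error(fisher_exact(matrix(-1, 2, 2)), "non-negative")
})

test_that("Spearman correlation has exact permutation p-values for small n", {
  x <- 1:6
  expect_equal(spearman_rank(x, 2 * x + 3)$rho, 1)
  expect_equal(spearman_rank(x, rev(x))$rho, -1)
  set.seed(7)
  x8 <- rnorm(8); y8 <- rnorm(8)
  res <- spearman_rank(x8, y8)
  ct <- suppressWarnings(cor.test(x8, y8, method = "spearman", exact = TRUE))
  expect_equal(res$rho, unname(ct$estimate), tolerance = 1e-12)
  expect_equal(res$p_value, ct$p.value, tolerance = 1e-12)
  expect_error(spearman_rank(rep(1, 8), y8), "constant")
  expect_error(spearman_rank(1:3, 1:3), "n >= 4")
})

test_that("hit rates reproduce the printed game statistics", {
  expect_equal(hit_rate(55, 35), 61.1)
  expect_equal(hit_rate(33, 161), 17.0)
  expect_equal(hit_rate(0, 10), 0)
  expect_error(hit_rate(0, 0), "positive")
})
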
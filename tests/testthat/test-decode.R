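# small balanced feature set with a separable spatial pattern
toy_features <- function(n_per_class = 6, n_ch = 3, len = 8, sep = 1, sd = 0.2) {
  pattern <- outer(seq_len(n_ch), seq_len(len), function(i, j) sin(i + j / 2))
  labels <- rep(c("left", "right"), each = n_per_class)
  mats <- lapply(seq_along(labels), function(i) {
    s <- if (labels[i] == "right") sep else -sep
    s * pattern + matrix(rnorm(n_ch * len, 0, sd), n_ch, len)
  })
  tibble::tibble(trial_id = seq_along(labels), attended = labels,
                 n_left = 6L, n_right = 5L, x_delta = mats)
}

identity_whitener <- function(n_ch) {
  structure(list(matrix = diag(n_ch), sigma = diag(n_ch), ridge = 0),
            class = "bci_whitener")
}

test_that("whitener recovers closed forms and whitens the training epochs", {
  # per-epoch covariance exactly 4*I -> W = 0.5*I
  p1 <- sqrt(3) * c(1, -1, 1, -1)
  p2 <- sqrt(3) * c(1, 1, -1, -1)
  ep <- manual_epochs(list(rbind(p1, p2), rbind(p1, p2)), stream = c("left", "right"))
  wh <- fit_whitener(ep, ridge = 0)
  expect_equal(wh$sigma, diag(c(4, 4)), tolerance = 1e-12)
  expect_equal(wh$matrix, diag(c(0.5, 0.5)), tolerance = 1e-12)

  # whitened epochs of a random set have identity mean spatial covariance
  set.seed(101)
  rec <- simulate_recording(make_run("FP", 4), n_channels = 4)
  eps <- preprocess_recording(rec)
  wh2 <- fit_whitener(eps, ridge = 0)
  expect_equal(wh2$matrix, t(wh2$matrix), tolerance = 1e-12)
  # matrix-power oracle: W %*% W %*% Sigma = I
  expect_equal(wh2$matrix %*% wh2$matrix %*% wh2$sigma, diag(4), tolerance = 1e-8)
  expect_equal(wh2$matrix %*% wh2$sigma %*% wh2$matrix, diag(4), tolerance = 1e-6)

  # singular covariance without ridge is rejected, with ridge it works
  flat <- manual_epochs(list(rbind(p1, p1), rbind(p1, p1)), stream = c("left", "right"))
  expect_error(fit_whitener(flat, ridge = 0), "ridge")
  expect_s3_class(fit_whitener(flat, ridge = 0.1), "bci_whitener")
})

test_that("logistic training is symmetric, separates separable data, and shrinks", {
  set.seed(102)
  ft <- toy_features()
  wh <- identity_whitener(3)
  m <- train_decoder(ft, whitener = wh, lambda = 0.01)
  pred <- predict(m, ft)
  expect_equal(mean(pred$predicted == pred$attended), 1)
  # swapping all labels negates weights and bias
  ft_swap <- dplyr::mutate(ft, attended = ifelse(attended == "left", "right", "left"))
  m_swap <- train_decoder(ft_swap, whitener = wh, lambda = 0.01)
  expect_equal(m_swap$weights, -m$weights, tolerance = 1e-6)
  expect_equal(m_swap$bias, -m$bias, tolerance = 1e-6)
  # huge penalty drives weights to zero and outputs to the bias
  m_big <- train_decoder(ft, whitener = wh, lambda = 1e8)
  expect_lt(max(abs(m_big$weights)), 1e-4)
  out <- decoder_output(m_big, ft$x_delta[[1]])
  expect_equal(out, m_big$bias, tolerance = 1e-3)
  expect_error(train_decoder(ft[ft$attended == "left", ], whitener = wh),
               "both")
})

test_that("training matches an independent penalized-regression solver", {
  skip_if_not_installed("glmnet")
  set.seed(103)
  rec <- simulate_recording(make_run("FP", 20),
                            erp = erp_model(attended_gain = 1.3), n_channels = 3)
  ep <- preprocess_recording(rec)
  wh <- fit_whitener(ep)
  ft <- trial_features(ep)
  lambda <- 2
  m <- train_decoder(ft, whitener = wh, lambda = lambda)
  z <- do.call(rbind, lapply(ft$x_delta, function(x) as.numeric(wh$matrix %*% x)))
  z <- z / m$feature_scale
  y <- as.numeric(ft$attended == "right")
  g <- glmnet::glmnet(z, y, family = "binomial", alpha = 0,
                      lambda = lambda / nrow(z), standardize = FALSE,
                      thresh = 1e-14, maxit = 1e6)
  cf <- as.numeric(glmnet::coef.glmnet(g))
  expect_equal(m$bias, cf[1], tolerance = 1e-4)
  expect_equal(as.numeric(m$weights), cf[-1], tolerance = 1e-4)
})

test_that("scoring is the weighted feature sum and behaves linearly", {
  set.seed(104)
  ft <- toy_features()
  wh <- identity_whitener(3)
  m <- train_decoder(ft, whitener = wh, lambda = 1)
  x <- ft$x_delta[[4]]
  # brute-force elementwise sum oracle
  v <- (wh$matrix %*% x) / m$feature_scale
  oracle <- sum(m$weights * v) + m$bias
  expect_equal(decoder_output(m, x), oracle, tolerance = 1e-12)
  expect_equal(decoder_output(m, 0 * x), m$bias, tolerance = 1e-12)
  expect_equal(decoder_output(m, -x) - m$bias, -(decoder_output(m, x) - m$bias),
               tolerance = 1e-10)
  expect_error(decoder_output(m, x[1:2, ]), "dimensions")
})

test_that("whitening makes trial scores equivariant to channel mixing", {
  set.seed(105)
  rec <- simulate_recording(make_run("FP", 8),
                            erp = erp_model(attended_gain = 1.3), n_channels = 3)
  ep <- preprocess_recording(rec)
  ft <- trial_features(ep)
  fit_scores <- function(ep, ft) {
    wh <- fit_whitener(ep, ridge = 0)
    m <- train_decoder(ft, whitener = wh, lambda = 1)
    vapply(ft$x_delta, function(x) decoder_output(m, x), numeric(1))
  }
  s1 <- fit_scores(ep, ft)
  a <- matrix(c(1.2, 0.4, -0.1, 0.3, 0.9, 0.2, -0.2, 0.1, 1.1), 3, 3)
  ep2 <- ep
  for (i in seq_len(dim(ep$epochs)[1])) {
    ep2$epochs[i, , ] <- a %*% ep$epochs[i, , ]
  }
  ft2 <- dplyr::mutate(ft, x_delta = purrr::map(x_delta, ~ a %*% .x))
  s2 <- fit_scores(ep2, ft2)
  expect_equal(s1, s2, tolerance = 1e-4)
})

test_that("trial classification emits one output per snapshot and flips with sign", {
  set.seed(106)
  rec <- noiseless_recording(n_trials = 2, gain = 1.2)
  ep <- preprocess_recording(rec)
  ft <- trial_features(ep)
  wh <- fit_whitener(ep, ridge = 1e-8)
  m <- train_decoder(ft, whitener = wh, lambda = 1)
  snaps <- running_difference(ep, trial = 1)
  cl <- classify_trial(m, snaps)
  expect_length(cl$outputs, 11L)
  # noiseless trial with a 20% attention gain is decoded correctly
  expect_equal(cl$label, ft$attended[ft$trial_id == 1])
  neg <- dplyr::mutate(snaps, x_delta = purrr::map(x_delta, ~ -.x))
  m0 <- m; m0$bias <- 0
  cl_neg <- classify_trial(m0, neg)
  cl0 <- classify_trial(m0, snaps)
  expect_true(cl_neg$label != cl0$label ||
                abs(tail(cl0$outputs, 1)) < 1e-12)
})

test_that("incremental retraining scores 100 trials over 6 runs of 20", {
  set.seed(107)
  runs <- lapply(1:6, function(k) {
    rec <- simulate_recording(make_run("FP", 20, first_trial_id = (k - 1) * 20 + 1),
                              erp = erp_model(attended_gain = 1.3),
                              noise = noise_model(sd_ratio = 1.5), n_channels = 2)
    preprocess_recording(rec)
  })
  pr <- incremental_protocol(runs)
  expect_equal(pr$n_scored, 100L)
  expect_setequal(unique(pr$trials$run), 2:6)
  expect_gt(pr$accuracy, 60) # clear effect at this SNR
  pr2 <- incremental_protocol(runs)
  expect_identical(pr$trials, pr2$trials) # convex training is deterministic
  expect_error(incremental_protocol(runs[1]), "at least one completed run")
})

test_that("the control chain has unit DC gain and halves an impulse per step", {
  ema <- suppressWarnings(control_signal(c(1, 0, 0, 0, 0), update_rate_hz = 4))
  expect_equal(ema, c(0.5, 0.25, 0.125, 0.0625, 0.03125), tolerance = 1e-12)
  expect_warning(control_signal(c(1, 0), update_rate_hz = 4), "bypassed")
  const <- control_signal(rep(2, 400), update_rate_hz = 20)
  expect_equal(tail(const, 1), 2, tolerance = 1e-3)
  zero <- control_signal(rep(0, 50), update_rate_hz = 20)
  expect_true(all(zero == 0))
  off <- suppressWarnings(control_signal(rep(1, 200), control_spec(gain = 3, offset = -1),
                                         update_rate_hz = 4))
  expect_equal(tail(off, 1), 3 * 1 - 1, tolerance = 1e-3)
})

test_that("decoder models round-trip through JSON", {
  set.seed(108)
  ft <- toy_features()
  m <- train_decoder(ft, whitener = identity_whitener(3), lambda = 1)
  path <- withr::local_tempfile(fileext = ".json")
  write_decoder(m, path)
  back <- read_decoder(path)
  expect_equal(back$weights, m$weights, tolerance = 1e-12)
  expect_equal(back$bias, m$bias, tolerance = 1e-12)
  expect_equal(back$whitener$matrix, m$whitener$matrix, tolerance = 1e-12)
  x <- ft$x_delta[[2]]
  expect_equal(decoder_output(back, x), decoder_output(m, x), tolerance = 1e-12)
})
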
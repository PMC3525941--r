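#' Fit a symmetric spatial whitener
#'
#' Computes the mean spatial covariance over training epochs (per-epoch
#' channels x channels covariance across time samples, with each epoch's
#' time mean removed per channel) and returns its inverse matrix square root
#' `W = (Sigma + ridge I)^(-1/2)` via symmetric eigendecomposition. Whitened
#' training epochs then have identity mean spatial covariance.
#'
#' @param epochs A `bci_epochs`, or an epoch x channel x sample array.
#' @param ridge Diagonal loading added to Sigma before inversion. Default
#'   `NULL` uses `1e-6 * trace(Sigma) / n_channels`; pass 0 for exact
#'   whitening of a full-rank covariance.
#' @return A `bci_whitener`: list with `matrix` (W, symmetric), `sigma`, and
#'   `ridge`.
#' @export
fit_whitener <- function(epochs, ridge = NULL) {
  arr <- if (inherits(epochs, "bci_epochs")) epochs$epochs else epochs
  d <- dim(arr)
  if (is.null(d) || length(d) != 3) stop_bci("`epochs` must be a 3-d epoch array.")
  n_ep <- d[1]; n_ch <- d[2]; len <- d[3]
  sigma <- matrix(0, n_ch, n_ch)
  for (i in seq_len(n_ep)) {
    x <- matrix(arr[i, , ], n_ch, len)
    x <- x - rowMeans(x)
    sigma <- sigma + tcrossprod(x) / (len - 1)
  }
  sigma <- sigma / n_ep
  ridge <- ridge %||% (1e-6 * sum(diag(sigma)) / n_ch)
  eg <- eigen(sigma, symmetric = TRUE)
  if (ridge == 0 && min(eg$values) <= max(eg$values) * 1e-12) {
    stop_bci("Training covariance is singular; supply a positive `ridge`.")
  }
  w <- eg$vectors %*% diag(1 / sqrt(eg$values + ridge), n_ch) %*% t(eg$vectors)
  structure(list(matrix = (w + t(w)) / 2, sigma = sigma, ridge = ridge),
            class = "bci_whitener")
}

whiten_flat <- function(whitener, x_delta) as.numeric(whitener$matrix %*% x_delta)

logistic_objective <- function(par, z, y, lambda) {
  p <- ncol(z)
  w <- par[seq_len(p)]; b <- par[p + 1]
  f <- drop(z %*% w) + b
  val <- sum(log1p(exp(-y * f))) + lambda / 2 * sum(w^2)
  g <- -y * plogis(-y * f)
  grad <- c(drop(crossprod(z, g)) + lambda * w, sum(g))
  list(value = val, grad = grad)
}

#' Train the whitened L2 logistic-regression decoder
#'
#' Classifies attend-left vs attend-right trials from their difference features
#' `x_delta`. Each feature matrix is premultiplied by the whitening transform,
#' flattened, and divided by one global RMS scale computed on the training set
#' (so the default penalty `lambda = 1` acts on standardized whitened
#' features). The weights minimize the L2-penalized logistic loss (label +1 =
#' attend right); the bias is not penalized. The objective is convex, so the
#' optimum is deterministic.
#'
#' @param features Tibble from [trial_features()] (columns `attended` and
#'   `x_delta`), or a list of feature matrices.
#' @param labels Per-trial labels (`"left"`/`"right"`); taken from `features`
#'   if omitted.
#' @param whitener A [fit_whitener()] result.
#' @param lambda L2 regularization strength (default 1).
#' @return A `bci_decoder`: list with `whitener`, `weights` (channels x samples
#'   matrix in whitened space), `bias`, `lambda`, `feature_scale`, and
#'   `n_train`.
#' @export
train_decoder <- function(features, labels = NULL, whitener, lambda = 1) {
  if (is.data.frame(features)) {
    labels <- labels %||% features$attended
    features <- features$x_delta
  }
  if (is.null(labels)) stop_bci("`labels` are required.")
  labels <- vapply(labels, match_stream, character(1))
  if (length(unique(labels)) < 2) {
    stop_bci("Training data must contain both attend-left and attend-right trials.")
  }
  v <- lapply(features, function(x) whiten_flat(whitener, x))
  z <- do.call(rbind, v)
  if (any(!is.finite(z))) stop_bci("Features must be finite.")
  scale <- sqrt(mean(z^2))
  z <- z / scale
  y <- side_sign(labels)
  p <- ncol(z)
  obj <- function(par) logistic_objective(par, z, y, lambda)$value
  grd <- function(par) logistic_objective(par, z, y, lambda)$grad
  fit <- optim(rep(0, p + 1), obj, grd, method = "L-BFGS-B",
               control = list(maxit = 2000, factr = 1e1, pgtol = 1e-10))
  dims <- dim(features[[1]])
  structure(
    list(whitener = whitener, weights = matrix(fit$par[seq_len(p)], dims[1], dims[2]),
         bias = fit$par[p + 1], lambda = lambda, feature_scale = scale,
         n_train = length(y), convergence = fit$convergence,
         channel_labels = rownames(features[[1]])),
    class = "bci_decoder"
  )
}

#' Decoder output for one difference feature
#'
#' The un-thresholded classifier output: the sum of the whitened, scaled
#' feature values weighted by the classifier weights, plus the bias. Positive
#' output means attend-right by convention.
#'
#' @param model A `bci_decoder`.
#' @param x_delta Channels x samples feature matrix.
#' @return Scalar output.
#' @export
decoder_output <- function(model, x_delta) {
  if (!identical(dim(x_delta), dim(model$weights))) {
    stop_bci("Feature dimensions do not match the decoder weights.")
  }
  v <- whiten_flat(model$whitener, x_delta) / model$feature_scale
  sum(model$weights * matrix(v, nrow(x_delta), ncol(x_delta))) + model$bias
}

#' Classify a trial from its running feature snapshots
#'
#' Produces one decoder output per snapshot (the online system updates roughly
#' 4 times per second in the fixed-phase design) and takes the sign of the
#' final output as the predicted attended side. An exact zero is tie-broken to
#' `"right"`.
#'
#' @param model A `bci_decoder`.
#' @param snapshots Tibble from [running_difference()], or a list of feature
#'   matrices in onset order.
#' @return List with `outputs` (numeric vector, one per snapshot) and `label`
#'   (`"left"` or `"right"`).
#' @export
classify_trial <- function(model, snapshots) {
  if (is.data.frame(snapshots)) snapshots <- snapshots$x_delta
  if (length(snapshots) == 0) stop_bci("Need at least one snapshot.")
  outputs <- vapply(snapshots, function(x) decoder_output(model, x), numeric(1))
  label <- if (tail(outputs, 1) >= 0) "right" else "left"
  list(outputs = outputs, label = label)
}

#' @export
predict.bci_decoder <- function(object, features, ...) {
  stopifnot(is.data.frame(features))
  scores <- vapply(features$x_delta, function(x) decoder_output(object, x), numeric(1))
  dplyr::mutate(features[setdiff(names(features), "x_delta")],
                score = scores,
                predicted = ifelse(scores >= 0, "right", "left"))
}

#' Incremental retraining protocol over the runs of one condition
#'
#' Emulates the online session: the classifier for run `k >= 2` is trained on
#' all runs gathered so far (runs `1..k-1`), with the whitener fit on the
#' training epochs. Run 1 has no trained classifier yet and is excluded from
#' the accuracy, so 6 runs of 20 trials yield 100 scored trials.
#'
#' @param run_epochs List of `bci_epochs`, one per run, in session order.
#' @param lambda L2 strength passed to [train_decoder()].
#' @param ridge Whitener ridge (see [fit_whitener()]).
#' @return A `bci_protocol`: list with `trials` (tibble: `run`, `trial_id`,
#'   `attended`, `score`, `predicted`, `correct`), `accuracy` (% correct over
#'   scored trials), and `n_scored`.
#' @export
incremental_protocol <- function(run_epochs, lambda = 1, ridge = NULL) {
  if (length(run_epochs) < 2) {
    stop_bci("Need at least one completed run before any run can be scored.")
  }
  feats <- lapply(run_epochs, trial_features)
  res <- vector("list", length(run_epochs))
  for (k in 2:length(run_epochs)) {
    train_arr <- abind_epochs(run_epochs[seq_len(k - 1)])
    wh <- fit_whitener(train_arr, ridge = ridge)
    model <- train_decoder(dplyr::bind_rows(feats[seq_len(k - 1)]),
                           whitener = wh, lambda = lambda)
    pred <- predict(model, feats[[k]])
    res[[k]] <- dplyr::mutate(pred, run = k, correct = .data$predicted == .data$attended)
  }
  trials <- dplyr::bind_rows(res)[, c("run", "trial_id", "attended", "score",
                                      "predicted", "correct")]
  structure(list(trials = trials, accuracy = 100 * mean(trials$correct),
                 n_scored = nrow(trials)),
            class = "bci_protocol")
}

# stack the epoch arrays of several runs along the epoch dimension
abind_epochs <- function(epoch_list) {
  arrs <- lapply(epoch_list, function(e) e$epochs)
  d <- dim(arrs[[1]])
  total <- sum(vapply(arrs, function(a) dim(a)[1], integer(1)))
  out <- array(0, dim = c(total, d[2], d[3]))
  at <- 1L
  for (a in arrs) {
    n <- dim(a)[1]
    out[at:(at + n - 1L), , ] <- a
    at <- at + n
  }
  out
}

#' @export
print.bci_protocol <- function(x, ...) {
  cat(sprintf("<bci_protocol> %d scored trials, accuracy %.1f%%\n",
              x$n_scored, x$accuracy))
  invisible(x)
}

#' Continuous-control signal specification
#'
#' @param ema_decay Exponential-moving-average decay factor in (0, 1);
#'   default 0.5. The EMA uses the convex-combination recursion
#'   `y_k = (1 - decay) x_k + decay y_(k-1)` (unit DC gain).
#' @param lowpass_order,lowpass_cutoff_hz Butterworth low-pass smoothing stage;
#'   defaults order 8, cutoff 3 Hz.
#' @param gain,offset Affine mapping of the smoothed output to a device
#'   velocity (application-specific; defaults 1 and 0).
#' @return A `control_spec` list.
#' @export
control_spec <- function(ema_decay = 0.5, lowpass_order = 8,
                         lowpass_cutoff_hz = 3, gain = 1, offset = 0) {
  if (!(ema_decay > 0 && ema_decay < 1)) stop_bci("`ema_decay` must be in (0, 1).")
  structure(list(ema_decay = ema_decay, lowpass_order = as.integer(lowpass_order),
                 lowpass_cutoff_hz = lowpass_cutoff_hz, gain = gain,
                 offset = offset), class = "control_spec")
}

#' Smooth classifier outputs into a continuous control signal
#'
#' The un-thresholded decoder outputs are smoothed by an exponential moving
#' average (decay 0.5), then by a causal 8th-order Butterworth low-pass at
#' 3 Hz, then mapped affinely (`gain * y + offset`) to a velocity. If the
#' update rate is not above twice the low-pass cutoff the low-pass stage is
#' bypassed with a warning (it cannot be designed below Nyquist).
#'
#' @param outputs Time-ordered numeric classifier outputs.
#' @param spec A [control_spec()].
#' @param update_rate_hz Rate at which outputs arrive (Hz).
#' @return Numeric control-signal series, same length as `outputs`.
#' @export
control_signal <- function(outputs, spec = control_spec(), update_rate_hz) {
  check_number(update_rate_hz, "update_rate_hz", lower = 1e-6)
  d <- spec$ema_decay
  y <- numeric(length(outputs))
  prev <- 0
  for (k in seq_along(outputs)) {
    prev <- (1 - d) * outputs[k] + d * prev
    y[k] <- prev
  }
  if (update_rate_hz > 2 * spec$lowpass_cutoff_hz) {
    bf <- signal::butter(spec$lowpass_order,
                         spec$lowpass_cutoff_hz / (update_rate_hz / 2),
                         type = "low")
    y <- as.numeric(signal::filter(bf, y))
  } else {
    rlang::warn("Update rate is not above twice the low-pass cutoff; smoothing stage bypassed.")
  }
  spec$gain * y + spec$offset
}

#' Serialize / load a decoder model as JSON
#'
#' Writes the whitening matrix, weights, bias, regularization strength,
#' montage, and a configuration hash to a JSON file for audit and reuse.
#'
#' @param model A `bci_decoder`.
#' @param path Output path (reader: input path).
#' @return `path` invisibly (writer); a `bci_decoder` (reader).
#' @export
write_decoder <- function(model, path) {
  payload <- list(
    whitener = list(matrix = model$whitener$matrix, ridge = model$whitener$ridge,
                    sigma = model$whitener$sigma),
    weights = model$weights, bias = model$bias, lambda = model$lambda,
    feature_scale = model$feature_scale, n_train = model$n_train,
    channel_labels = model$channel_labels
  )
  payload$config_hash <- config_hash(payload[c("bias", "lambda", "feature_scale", "n_train")])
  jsonlite::write_json(payload, path, digits = NA, auto_unbox = TRUE)
  invisible(path)
}

#' @rdname write_decoder
#' @export
read_decoder <- function(path) {
  p <- jsonlite::read_json(path, simplifyVector = TRUE)
  wh <- structure(list(matrix = as.matrix(p$whitener$matrix),
                       sigma = as.matrix(p$whitener$sigma),
                       ridge = p$whitener$ridge), class = "bci_whitener")
  structure(
    list(whitener = wh, weights = as.matrix(p$weights), bias = p$bias,
         lambda = p$lambda, feature_scale = p$feature_scale,
         n_train = p$n_train, channel_labels = p$channel_labels),
    class = "bci_decoder"
  )
}

# small deterministic hash of a config list (djb2 over its JSON text)
config_hash <- function(x) {
  txt <- jsonlite::toJSON(x, digits = 10, auto_unbox = TRUE)
  h <- 5381
  for (b in utf8ToInt(as.character(txt))) h <- (h * 33 + b) %% 2^31
  sprintf("%08x", h)
}
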
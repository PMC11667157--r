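#' Frequency band-scan optimization
#'
#' Scans contiguous frequency bands of fixed width (5-35 Hz in 5 Hz
#' steps by default), builds the spatial-spectral feature tensors for
#' each band, pre-classifies them with the supplied classifier under the
#' seeded 75-25 split protocol, and reports mean and standard deviation
#' of the held-out accuracy per band. The selected band maximizes the
#' mean accuracy; ties break towards the lower band.
#'
#' @param segments list of [eeg_segment()] with both classes present.
#' @param scan_low,scan_high scan range in Hz; `scan_high - scan_low`
#'   must be a multiple of `width`.
#' @param width band width in Hz.
#' @param eval_fn classifier protocol: a
#'   `function(x_train, y_train, x_test, y_test)` returning the held-out
#'   accuracy as a fraction. Defaults to a reduced pseudo-3D network;
#'   [bandscan_linear_classifier()] is a fast alternative.
#' @param n_subbands sub-bands (tensor frames) per scanned band.
#' @param n_repeats repeated splits per band (seeds
#'   `shuffle_seed + 0:(n_repeats-1)`).
#' @param split a [split_spec()] template.
#' @param welch a [welch_config()].
#' @param layout a [montage_layout()].
#' @param target_shape per-frame lattice shape, see [interp_topomap()].
#' @param normalize tensor normalization, see [assemble_tensor()].
#' @return A `band_scan_result`: data.frame `bands` with per-band mean
#'   and sd accuracy (percent), and `selected_band`.
#' @export
band_scan <- function(segments, scan_low = 5, scan_high = 35, width = 5,
                      eval_fn = p3dcnn_classifier(),
                      n_subbands = 10L, n_repeats = 3L,
                      split = split_spec(), welch = welch_config(),
                      layout = default_montage(),
                      target_shape = c(110L, 100L),
                      normalize = "zscore") {
  n_bands <- (scan_high - scan_low) / width
  if (abs(n_bands - round(n_bands)) > 1e-9)
    stop("scan range must be divisible by the band width")
  n_bands <- as.integer(round(n_bands))
  labels <- vapply(segments, `[[`, "", "class_label")
  if (length(unique(labels)) < 2)
    stop("band scan needs at least two classes")
  lows <- scan_low + width * (seq_len(n_bands) - 1L)
  mean_acc <- numeric(n_bands); sd_acc <- numeric(n_bands)
  for (b in seq_len(n_bands)) {
    band <- c(lows[b], lows[b] + width)
    feats <- tensorize_segments(segments, band, n_subbands, welch, layout,
                                target_shape, normalize)
    accs <- vapply(seq_len(n_repeats), function(r) {
      sp <- train_test_split(feats$y,
                             split_spec(split$train_fraction,
                                        split$shuffle_seed + r - 1L,
                                        split$stratified))
      if (min(table(feats$y[sp$train])) < 1) stop("too few trials to split")
      eval_fn(feats$x[sp$train, , , , drop = FALSE], feats$y[sp$train],
              feats$x[sp$test, , , , drop = FALSE], feats$y[sp$test])
    }, numeric(1))
    mean_acc[b] <- mean(accs) * 100
    sd_acc[b] <- stats::sd(accs) * 100
  }
  best <- which.max(mean_acc)               # which.max takes the first tie
  structure(list(bands = data.frame(low_hz = lows, high_hz = lows + width,
                                    mean_accuracy = mean_acc,
                                    std_accuracy = sd_acc),
                 selected_band = c(lows[best], lows[best] + width)),
            class = "band_scan_result")
}

#' @export
print.band_scan_result <- function(x, ...) {
  cat("<band_scan_result>\n")
  print(x$bands)
  cat(sprintf("selected band: %g-%g Hz\n",
              x$selected_band[1], x$selected_band[2]))
  invisible(x)
}

#' Fast linear classifier for band pre-classification
#'
#' Average-pools each topographic frame down to a coarse grid, then fits
#' a ridge-regularized logistic regression. Orders of magnitude faster
#' than the network and sufficient to rank frequency bands.
#'
#' @param pool_to `c(nx, ny)` coarse pooled frame size.
#' @param lambda ridge penalty.
#' @return A classifier `function(x_train, y_train, x_test, y_test)`
#'   returning held-out accuracy.
#' @export
bandscan_linear_classifier <- function(pool_to = c(11L, 10L), lambda = 1) {
  pool_frames <- function(x) {
    d <- dim(x)                              # n, nx, ny, bands
    gx <- as.integer(cut(seq_len(d[2]), pool_to[1]))
    gy <- as.integer(cut(seq_len(d[3]), pool_to[2]))
    out <- matrix(0, d[1], pool_to[1] * pool_to[2] * d[4])
    k <- 0L
    for (b in seq_len(d[4])) for (j in seq_len(pool_to[2])) {
      cols_y <- which(gy == j)
      for (i in seq_len(pool_to[1])) {
        k <- k + 1L
        out[, k] <- apply(x[, gx == i, cols_y, b, drop = FALSE], 1, mean)
      }
    }
    out
  }
  function(x_train, y_train, x_test, y_test) {
    xt <- pool_frames(x_train); xs <- pool_frames(x_test)
    fit <- glmnet::glmnet(xt, y_train, family = "binomial", alpha = 0,
                          lambda = lambda, standardize = TRUE)
    pred <- stats::predict(fit, xs, type = "class")
    mean(pred == as.character(y_test))
  }
}

#' Pseudo-3D network classifier for the band scan
#'
#' Classifier-protocol wrapper around [build_p3dcnn()] /
#' [train_p3dcnn()], defaulting to the reduced preset with a short
#' training schedule.
#'
#' @param config a [p3dcnn_config()]; the input shape is adapted to the
#'   data at call time.
#' @param train a [train_config()].
#' @return A classifier `function(x_train, y_train, x_test, y_test)`.
#' @export
p3dcnn_classifier <- function(config = NULL,
                              train = train_config(epochs = 25L,
                                                   learning_rate = 0.001,
                                                   batch_size = 16L,
                                                   momentum = 0.9)) {
  function(x_train, y_train, x_test, y_test) {
    d <- dim(x_train)[-1]
    cfg <- config %||% p3dcnn_config_reduced(input_shape = d)
    model <- build_p3dcnn(cfg, seed = train$seed)
    model <- train_p3dcnn(model, x_train, y_train, train)
    pred <- predict(model, x_test, type = "class")
    mean(as.character(pred) == as.character(y_test))
  }
}
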
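# Shared fixtures: everything is generated in code at test time.

# Small network configuration that exercises every layer type quickly.
tiny_model_config <- function(dropout_p = 0) {
  p3dcnn_config(input_shape = c(14L, 12L, 8L), n_filters_block1 = 2L,
                n_filters_block2 = 3L, fc_units = 8L,
                spatial_kernel = c(3L, 3L, 1L),
                spectral_kernel = c(1L, 1L, 3L),
                dropout_p = dropout_p)
}

# Trivially separable two-class tensors (constant offset + noise).
separable_tensors <- function(n = 24, shape = c(14, 12, 8), seed = 2) {
  set.seed(seed)
  x <- array(0, c(n, shape))
  y <- rep(c("left_fist", "right_fist"), each = n / 2)
  for (i in seq_len(n))
    x[i, , , ] <- stats::rnorm(prod(shape),
                               mean = ifelse(y[i] == "left_fist", 1, -1),
                               sd = 0.5)
  list(x = x, y = factor(y))
}

# Direct evaluation of the windowed periodogram (no FFT), used as the
# independent oracle for the Welch estimator.
direct_periodogram <- function(x, w, sampling_rate) {
  M <- length(x)
  U <- mean(w^2)
  nb <- M %/% 2L + 1L
  out <- numeric(nb)
  n <- 0:(M - 1)
  for (k in seq_len(nb)) {
    ph <- exp(-2i * pi * (k - 1) * n / M)
    s <- sum(x * w * ph)
    scale <- if (k == 1 || (M %% 2 == 0 && k == nb)) 1 else 2
    out[k] <- scale * Mod(s)^2 / (sampling_rate * M * U)
  }
  out
}

# A recording whose channels follow the default montage order.
synthetic_recording <- function(n_samples = 1600, events = c(0L, 800L),
                                labels = c("left_fist", "right_fist"),
                                fs = 160, seed = 5) {
  set.seed(seed)
  mont <- default_montage()
  eeg_recording(matrix(stats::rnorm(64 * n_samples, sd = 20),
                       64, n_samples),
                fs, montage_channels(mont),
                data.frame(onset_sample = events, label = labels),
                subject_id = "S001")
}
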
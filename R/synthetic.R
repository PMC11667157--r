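#' Configuration of the synthetic motor-imagery EEG generator
#'
#' The generator emulates the statistical structure the decoding method
#' relies on: every channel carries spatially correlated 1/f^alpha
#' background noise, and the sensorimotor regions around C3 (left
#' hemisphere) and C4 (right hemisphere) additionally carry narrowband
#' mu-rhythm oscillations (band-limited Gaussian noise, 10-15 Hz by
#' default). Imagining a fist movement desynchronizes the mu rhythm over
#' the contralateral hemisphere: for a left-fist trial the C4-side mu
#' power is scaled by `1 - erd_effect`, and symmetrically for right-fist
#' trials.
#'
#' Amplitude defaults (6 uV mu at the bump center over 4 uV broadband
#' background) put roughly four fifths of the 10-15 Hz band power into
#' the mu component over the motor channels, so the measured band-power
#' ratio between classes tracks `1 - erd_effect` closely.
#'
#' @param n_trials_per_class trials per class.
#' @param sampling_rate Hz.
#' @param duration_s trial length, seconds.
#' @param mu_band `c(low_hz, high_hz)` of the mu oscillation.
#' @param erd_effect fractional contralateral power reduction, in `[0, 1)`.
#' @param noise_exponent spectral slope alpha of the 1/f^alpha background.
#' @param mu_amplitude_uv RMS amplitude of the mu source at the bump
#'   center, microvolts.
#' @param noise_rms_uv RMS of the background noise per channel,
#'   microvolts.
#' @param spatial_sigma width (grid units) of the Gaussian spatial
#'   profile of each mu source.
#' @param mixing_sigma width (grid units) of the common-source mixing
#'   that correlates neighboring background channels.
#' @param left_motor_channels,right_motor_channels electrode names of the
#'   C3 / C4 neighborhoods used to center the mu sources and to define
#'   the evaluation channel sets.
#' @param layout a [montage_layout()].
#' @param seed integer seed; generation is bit-reproducible given the
#'   seed.
#' @return A `synthetic_mi_config`.
#' @export
synthetic_mi_config <- function(n_trials_per_class = 100L,
                                sampling_rate = 160,
                                duration_s = 4,
                                mu_band = c(10, 15),
                                erd_effect = 0.6,
                                noise_exponent = 1,
                                mu_amplitude_uv = 6,
                                noise_rms_uv = 4,
                                spatial_sigma = 2,
                                mixing_sigma = 1.5,
                                left_motor_channels = c("FC3", "C5", "C3",
                                                        "C1", "CP3"),
                                right_motor_channels = c("FC4", "C6", "C4",
                                                         "C2", "CP4"),
                                layout = default_montage(),
                                seed = 1L) {
  if (erd_effect < 0 || erd_effect >= 1)
    stop("erd_effect must be in [0, 1)")
  if (n_trials_per_class < 1) stop("n_trials_per_class must be >= 1")
  chn <- montage_channels(layout)
  bad <- setdiff(c(left_motor_channels, right_motor_channels), chn)
  if (length(bad))
    stop("unknown channel names: ", paste(bad, collapse = ", "))
  if (length(intersect(left_motor_channels, right_motor_channels)))
    stop("left and right motor channel sets must be disjoint")
  structure(as.list(environment()), class = "synthetic_mi_config")
}

# Column-wise colored / band-limited Gaussian noise via spectral synthesis.
# Returns an N x n matrix of unit-RMS series.
spectral_noise <- function(N, n, fs, shape_fun) {
  stopifnot(N %% 2 == 0)
  nb <- N %/% 2L
  f <- (1:nb) * fs / N
  a <- shape_fun(f)
  spec <- matrix(0 + 0i, N, n)
  re <- matrix(stats::rnorm(nb * n), nb, n)
  im <- matrix(stats::rnorm(nb * n), nb, n)
  spec[2:(nb + 1L), ] <- a * (re + 1i * im)
  spec[nb + 1L, ] <- Re(spec[nb + 1L, ])          # Nyquist bin real
  spec[N:(nb + 2L), ] <- Conj(spec[2:nb, ])
  x <- Re(stats::mvfft(spec, inverse = TRUE)) / N
  rms <- sqrt(colMeans(x^2))
  rms[rms == 0] <- 1
  sweep(x, 2L, rms, `/`)
}

#' Generate labeled synthetic motor-imagery trials
#'
#' @param config a [synthetic_mi_config()].
#' @return List of `2 * n_trials_per_class` [eeg_segment()] objects with
#'   alternating `left_fist` / `right_fist` labels, each
#'   `64 x round(duration_s * sampling_rate)` at the defaults.
#' @export
simulate_mi_segments <- function(config = synthetic_mi_config()) {
  stopifnot(inherits(config, "synthetic_mi_config"))
  old_seed <- if (exists(".Random.seed", globalenv()))
    get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old_seed))
    assign(".Random.seed", old_seed, globalenv()))
  set.seed(config$seed)

  lay <- config$layout$placement
  fs <- config$sampling_rate
  N <- round(config$duration_s * fs)
  n_ch <- nrow(lay)
  pos <- cbind(lay$row, lay$col)
  d2 <- function(p) (pos[, 1] - p[1])^2 + (pos[, 2] - p[2])^2
  # background mixing: distance-decaying common sources at electrode sites
  D2 <- as.matrix(stats::dist(pos))^2
  Mmix <- exp(-D2 / (2 * config$mixing_sigma^2))
  Mmix <- Mmix / sqrt(rowSums(Mmix^2))
  # mu spatial profiles centered on C3 and C4
  c3 <- pos[match("C3", lay$name), ]
  c4 <- pos[match("C4", lay$name), ]
  wL <- exp(-d2(c3) / (2 * config$spatial_sigma^2))
  wR <- exp(-d2(c4) / (2 * config$spatial_sigma^2))
  alpha <- config$noise_exponent
  f_floor <- 0.5
  bg_shape <- function(f) pmax(f, f_floor)^(-alpha / 2)
  mu_shape <- function(f) as.numeric(f >= config$mu_band[1] &
                                     f <= config$mu_band[2])
  atten <- sqrt(1 - config$erd_effect)

  labels <- rep(c("left_fist", "right_fist"), config$n_trials_per_class)
  lapply(seq_along(labels), function(i) {
    z <- spectral_noise(N, n_ch, fs, bg_shape)       # N x ch unit RMS
    bg <- config$noise_rms_uv * Mmix %*% t(z)        # ch x N
    mu <- spectral_noise(N, 2L, fs, mu_shape)        # sources: L, R
    gain <- if (labels[i] == "left_fist") c(1, atten) else c(atten, 1)
    mu_field <- config$mu_amplitude_uv *
      (gain[1] * outer(wL, mu[, 1]) + gain[2] * outer(wR, mu[, 2]))
    eeg_segment(bg + mu_field, labels[i], "synthetic", fs)
  })
}

#' Mean band power over a channel set, averaged across trials
#'
#' Welch band power in `band` averaged over the named channels and over
#' all supplied segments; used to verify the generator's event-related
#' desynchronization contract.
#'
#' @param segments list of [eeg_segment()].
#' @param channels electrode names.
#' @param band `c(low_hz, high_hz)`.
#' @param layout a [montage_layout()].
#' @param welch a [welch_config()].
#' @return Mean power density (uV^2/Hz) over channels, bins and trials.
#' @export
mean_band_power <- function(segments, channels, band = c(10, 15),
                            layout = default_montage(),
                            welch = welch_config()) {
  idx <- match(channels, montage_channels(layout))
  if (anyNA(idx)) stop("unknown channel names")
  vals <- vapply(segments, function(seg) {
    psd <- welch_psd(seg$samples[idx, , drop = FALSE], welch,
                     seg$sampling_rate)
    inb <- psd$frequencies >= band[1] & psd$frequencies <= band[2]
    mean(psd$power[, inb])
  }, numeric(1))
  mean(vals)
}
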
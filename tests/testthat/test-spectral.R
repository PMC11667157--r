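test_that("zero input gives an identically zero PSD", {
  psd <- welch_psd(numeric(640), welch_config(), 160)
  expect_true(all(psd$power == 0))
  expect_length(psd$frequencies, 161)
  expect_equal(psd$n_segments, 2)
})

test_that("blocks are contiguous and non-overlapping: [0,320) and [320,640)", {
  set.seed(4)
  x1 <- rnorm(320); x2 <- rnorm(320)
  cfg <- welch_config(segment_length = 320)
  full <- welch_psd(c(x1, x2), cfg, 160)
  # the two-block estimate is exactly the mean of the single-block ones
  p1 <- welch_psd(x1, cfg, 160)
  p2 <- welch_psd(x2, cfg, 160)
  expect_equal(full$power, (p1$power + p2$power) / 2)
  expect_equal(full$n_segments, 2)
})

test_that("L-block Welch equals the arithmetic mean of L single blocks", {
  set.seed(6)
  M <- 160; L <- 4
  x <- rnorm(M * L)
  cfg <- welch_config(segment_length = M)
  full <- welch_psd(x, cfg, 160)
  parts <- sapply(seq_len(L), function(i)
    welch_psd(x[(i - 1) * M + seq_len(M)], cfg, 160)$power)
  expect_equal(as.numeric(full$power), rowMeans(parts))
})

test_that("rectangular single-block PSD matches the direct DFT oracle", {
  fs <- 160; M <- 320
  k0 <- 21                                  # an exact-bin sinusoid
  x <- sin(2 * pi * k0 * (0:(M - 1)) / M)
  cfg <- welch_config(segment_length = M, window = "rectangular")
  psd <- welch_psd(x, cfg, fs)
  oracle <- direct_periodogram(x, rep(1, M), fs)
  expect_lt(max(abs(psd$power[1, ] - oracle)), 1e-10)
  # the same equivalence holds for a windowed block of noise
  set.seed(9)
  xn <- rnorm(M)
  cfgh <- welch_config(segment_length = M, window = "hamming")
  w <- mi3dnet:::welch_window(cfgh)
  expect_lt(max(abs(welch_psd(xn, cfgh, fs)$power[1, ] -
                    direct_periodogram(xn, w, fs))), 1e-10)
})

test_that("Parseval: integrated PSD matches the mean square within 5%", {
  set.seed(12)
  x <- rnorm(640)
  psd <- welch_psd(x, welch_config(window = "rectangular"), 160)
  df <- diff(psd$frequencies[1:2])
  expect_lt(abs(sum(psd$power) * df - mean(x^2)) / mean(x^2), 0.05)
})

test_that("averaging over blocks reduces the PSD estimator variance", {
  set.seed(13)
  M <- 160
  vals1 <- vals4 <- numeric(200)
  bin <- 21
  for (r in 1:200) {
    x <- rnorm(4 * M)
    vals1[r] <- welch_psd(x, welch_config(M, n_segments = 1), 160)$power[bin]
    vals4[r] <- welch_psd(x, welch_config(M, n_segments = 4), 160)$power[bin]
  }
  expect_lt(var(vals4), var(vals1))
})

test_that("input shorter than L * M is rejected", {
  expect_error(welch_psd(numeric(300), welch_config(320), 160), "too short")
  expect_error(welch_psd(numeric(640),
                         welch_config(320, n_segments = 3), 160),
               "too short")
})

test_that("the 10-15 Hz band splits into ten 0.5 Hz sub-bands", {
  set.seed(3)
  psd <- welch_psd(rnorm(640), welch_config(), 160)
  sbp <- subband_power(psd, c(10, 15), 10)
  expect_equal(sbp$band_edges$low, seq(10, 14.5, by = 0.5))
  expect_equal(sbp$band_edges$high, seq(10.5, 15, by = 0.5))
  expect_equal(ncol(sbp$power), 10)
})

test_that("sub-band values are means of the member bins", {
  # flat spectrum: every sub-band equals the constant
  flat <- structure(list(frequencies = seq(0, 80, by = 0.5),
                         power = matrix(3.7, 1, 161), n_segments = 1),
                    class = "psd_estimate")
  sbp <- subband_power(flat, c(10, 15), 10)
  expect_true(all(abs(sbp$power - 3.7) < 1e-12))
  # power in a single bin lands in exactly one sub-band ([low, high) rule)
  fr <- seq(0, 80, by = 0.2)
  pw <- matrix(0, 1, length(fr))
  pw[1, which.min(abs(fr - 10.2))] <- 5
  spiky <- structure(list(frequencies = fr, power = pw, n_segments = 1),
                     class = "psd_estimate")
  sbp2 <- subband_power(spiky, c(10, 15), 10)
  expect_true(sbp2$power[1, 1] > 0)
  expect_true(all(sbp2$power[1, -1] == 0))
})

test_that("sub-bands below the frequency resolution are rejected", {
  psd <- welch_psd(numeric(640), welch_config(160), 160)  # df = 1 Hz
  expect_error(subband_power(psd, c(10, 15), 10), "resolution")
  expect_error(subband_power(psd, c(10, 200), 10), "range")
})

test_that("band scan enumerates 5 Hz bands and breaks ties downward", {
  # geometry only: 6 bands over 5-35 Hz
  segs <- simulate_mi_segments(synthetic_mi_config(n_trials_per_class = 8,
                                                   seed = 3))
  trivial <- function(x_train, y_train, x_test, y_test) 0.5
  res <- band_scan(segs, 5, 35, 5, eval_fn = trivial, n_repeats = 1,
                   target_shape = c(22L, 20L))
  expect_equal(res$bands$low_hz, c(5, 10, 15, 20, 25, 30))
  expect_equal(res$bands$high_hz, c(10, 15, 20, 25, 30, 35))
  # all-tied accuracies select the lowest band
  expect_equal(res$selected_band, c(5, 10))
  expect_error(band_scan(segs, 5, 33, 5, eval_fn = trivial), "divisible")
})
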
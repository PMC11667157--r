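test_that("EDF round-trip preserves samples, channel order and events", {
  rec <- synthetic_recording(n_samples = 480, events = c(0L, 160L))
  coded <- rec
  coded$annotations$label <- c("T1", "T2")
  path <- tempfile(fileext = ".edf")
  write_edf(path, coded)
  back <- read_edf(path)
  expect_equal(nrow(back$samples), 64)
  expect_equal(back$sampling_rate, 160)
  # 16-bit quantization: relative error bounded by the digitization step
  step <- max(abs(rec$samples)) / 32767
  expect_lt(max(abs(back$samples[, 1:480] - rec$samples)), step)
  expect_equal(nrow(back$annotations), 2)
  expect_equal(back$annotations$onset_sample, c(0L, 160L))
  expect_equal(back$annotations$label, c("left_fist", "right_fist"))
})

test_that("channels are reordered to the montage and T0 events dropped", {
  rec <- synthetic_recording(n_samples = 320, events = c(0L, 160L))
  perm <- sample(64)
  shuffled <- eeg_recording(rec$samples[perm, ], 160,
                            rec$channel_names[perm],
                            data.frame(onset_sample = c(0L, 100L, 160L),
                                       label = c("T1", "T0", "T2")))
  path <- tempfile(fileext = ".edf")
  write_edf(path, shuffled)
  back <- read_edf(path)
  expect_equal(back$channel_names, montage_channels(default_montage()))
  expect_equal(max(abs(back$samples[1, ] - rec$samples[1, 1:320])) <
               max(abs(rec$samples)) / 32767, TRUE)
  expect_equal(back$annotations$label, c("left_fist", "right_fist"))
})

test_that("missing montage channels raise a montage error", {
  rec <- synthetic_recording(n_samples = 320, events = 0L,
                             labels = "left_fist")
  short <- eeg_recording(rec$samples[1:60, ], 160,
                         rec$channel_names[1:60],
                         data.frame(onset_sample = 0L, label = "T1"))
  path <- tempfile(fileext = ".edf")
  write_edf(path, short)
  expect_error(read_edf(path), "missing")
  expect_error(read_edf(tempfile(fileext = ".edf")), "cannot read")
})

test_that("annotation onsets outside the recording are rejected", {
  rec <- synthetic_recording(n_samples = 320, events = 0L,
                             labels = "left_fist")
  expect_error(
    eeg_recording(rec$samples, 160, rec$channel_names,
                  data.frame(onset_sample = 320L, label = "left_fist")),
    "outside")
})

test_that("segmentation yields 640-sample trials at 4 s / 160 Hz", {
  rec <- synthetic_recording(n_samples = 1600, events = c(0L, 800L))
  segs <- segment_trials(rec, 4)
  expect_length(segs, 2)
  for (s in segs) {
    expect_equal(ncol(s$samples), 640)
    expect_equal(nrow(s$samples), 64)
  }
  expect_equal(segs[[1]]$class_label, "left_fist")
  expect_equal(segs[[1]]$samples, rec$samples[, 1:640])
})

test_that("segmentation boundary cases behave as specified", {
  rec <- synthetic_recording(n_samples = 640, events = 0L,
                             labels = "left_fist")
  expect_length(segment_trials(rec, 4), 1)      # exact fit
  expect_error(segment_trials(rec, 0), "window")
  rec2 <- synthetic_recording(n_samples = 700, events = c(0L, 100L),
                              labels = c("left_fist", "right_fist"))
  expect_error(segment_trials(rec2, 4), "overruns")
})

test_that("band-pass attenuates out-of-band and passes in-band tones", {
  fs <- 160
  t <- seq_len(640) / fs
  mk_seg <- function(f) eeg_segment(matrix(sin(2 * pi * f * t), 1), "left_fist",
                                    "x", fs)
  spec <- filter_spec(5, 35)
  out50 <- bandpass(mk_seg(50), spec)
  rms <- function(x) sqrt(mean(x^2))
  expect_lt(rms(out50$samples), 0.01 * rms(mk_seg(50)$samples))
  out20 <- bandpass(mk_seg(20), spec)
  gain_db <- 20 * log10(rms(out20$samples) / rms(mk_seg(20)$samples))
  expect_gt(gain_db, -3)
  zero <- bandpass(eeg_segment(matrix(0, 2, 640), "left_fist", "x", fs), spec)
  expect_true(all(zero$samples == 0))
})

test_that("filtering is linear and the segment shape is preserved", {
  fs <- 160
  set.seed(8)
  a <- matrix(rnorm(2 * 640), 2); b <- matrix(rnorm(2 * 640), 2)
  spec <- filter_spec(5, 35)
  f <- function(m) bandpass(eeg_segment(m, "left_fist", "x", fs),
                            spec)$samples
  lhs <- f(2 * a - 3 * b)
  rhs <- 2 * f(a) - 3 * f(b)
  expect_lt(max(abs(lhs - rhs)) / max(abs(lhs)), 1e-6)
  expect_equal(dim(lhs), c(2L, 640L))
})

test_that("frequency response meets the stopband and passband targets", {
  fs <- 160
  b <- fir_coefficients(filter_spec(5, 35), fs)
  nfft <- 4096
  H <- abs(fft(c(b, numeric(nfft - length(b)))))
  freq <- (seq_len(nfft) - 1) * fs / nfft
  db <- 20 * log10(pmax(H, 1e-12))
  expect_lt(db[which.min(abs(freq - 2))], -40)
  expect_gt(db[which.min(abs(freq - 20))], -3 - 1)
  expect_error(fir_coefficients(filter_spec(5, 90), fs), "Nyquist")
})
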
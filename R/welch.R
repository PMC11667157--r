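#' Configuration for the Welch power spectral density estimator
#'
#' The estimator divides each N-sample channel into `n_segments`
#' contiguous, non-overlapping blocks of `segment_length` samples,
#' windows each block, averages the windowed periodograms, and returns a
#' one-sided density. The normalization factor `U = mean(w(n)^2)` is
#' computed from the actual window so results are window-consistent.
#'
#' The defaults (`segment_length = 320`, two blocks of a 640-sample
#' trial, Hamming window) give a 0.5 Hz bin spacing at 160 Hz - exactly
#' one bin per 0.5 Hz sub-band of the 10-15 Hz decomposition.
#'
#' @param segment_length block length M in samples.
#' @param n_segments number of blocks L, or `NULL` to use as many full
#'   blocks as fit the data.
#' @param window window name: `"hamming"`, `"hann"` or `"rectangular"`.
#' @param overlap fractional overlap between blocks; the printed
#'   segmentation rule is non-overlapping, so the default is 0 (0.5 is
#'   accepted as a common variant).
#' @return A `welch_config`.
#' @export
welch_config <- function(segment_length = 320L, n_segments = NULL,
                         window = c("hamming", "hann", "rectangular"),
                         overlap = 0) {
  window <- match.arg(window)
  if (segment_length < 2) stop("segment_length must be >= 2")
  if (!overlap %in% c(0, 0.5)) stop("overlap must be 0 or 0.5")
  structure(list(segment_length = as.integer(segment_length),
                 n_segments = if (!is.null(n_segments)) as.integer(n_segments),
                 window = window, overlap = overlap),
            class = "welch_config")
}

welch_window <- function(config) {
  M <- config$segment_length
  n <- seq_len(M) - 1L
  switch(config$window,
         rectangular = rep(1, M),
         hamming = 0.54 - 0.46 * cos(2 * pi * n / (M - 1)),
         hann = 0.5 - 0.5 * cos(2 * pi * n / (M - 1)))
}

#' Welch power spectral density estimate
#'
#' Computes the one-sided Welch PSD of one channel (vector) or of every
#' channel of a trial (channels x time matrix). Blocks are contiguous:
#' block i covers samples `[(i-1)*step, (i-1)*step + M)`. Each block is
#' windowed, Fourier transformed, scaled by `1 / (fs * M * U)` with
#' `U = mean(w^2)` (density convention; interior bins additionally carry
#' the one-sided factor 2), and the block periodograms are averaged.
#' With this scaling `sum(power) * df` approximates the signal mean
#' square (Parseval).
#'
#' @param x numeric vector (one channel) or channels x time matrix.
#' @param config a [welch_config()].
#' @param sampling_rate sampling rate in Hz.
#' @return A `psd_estimate`: list with `frequencies` (Hz, length
#'   `M/2 + 1`) and `power` (channels x bins matrix, uV^2/Hz).
#' @export
welch_psd <- function(x, config = welch_config(), sampling_rate) {
  if (is.null(dim(x))) x <- matrix(x, nrow = 1)
  stopifnot(sampling_rate > 0)
  M <- config$segment_length
  if (M < 1) stop("segment length must be positive")
  N <- ncol(x)
  step <- if (config$overlap == 0) M else M %/% 2L
  L <- config$n_segments
  if (is.null(L)) L <- max(0L, (N - M) %/% step + 1L)
  if (L < 1 || (L - 1L) * step + M > N)
    stop(sprintf("signal too short: need %d samples for L=%d blocks of M=%d",
                 (L - 1L) * step + M, L, M))
  w <- welch_window(config)
  U <- mean(w^2)
  nb <- M %/% 2L + 1L
  scale <- rep(2 / (sampling_rate * M * U), nb)
  scale[1] <- scale[1] / 2
  if (M %% 2L == 0L) scale[nb] <- scale[nb] / 2
  acc <- matrix(0, nrow(x), nb)
  for (i in seq_len(L)) {
    blk <- x[, (i - 1L) * step + seq_len(M), drop = FALSE]
    blk <- sweep(blk, 2L, w, `*`)
    sp <- t(stats::mvfft(t(blk)))[, seq_len(nb), drop = FALSE]
    acc <- acc + sweep(Mod(sp)^2, 2L, scale, `*`)
  }
  structure(list(frequencies = (seq_len(nb) - 1L) * sampling_rate / M,
                 power = acc / L,
                 n_segments = L, config = config,
                 sampling_rate = sampling_rate),
            class = "psd_estimate")
}

#' @export
print.psd_estimate <- function(x, ...) {
  cat(sprintf("<psd_estimate> %d channel(s), %d bins, df = %.4g Hz, L = %d\n",
              nrow(x$power), length(x$frequencies),
              diff(x$frequencies[1:2]), x$n_segments))
  invisible(x)
}

#' Average PSD bins into contiguous equal-width sub-bands
#'
#' Splits `band` into `n_subbands` equal-width sub-bands and averages,
#' for each channel, the PSD bins whose center frequency falls in
#' `[low, high)` of each sub-band. The mean (not the sum) is used so the
#' feature is insensitive to the number of bins per sub-band.
#'
#' @param psd a [welch_psd()] result.
#' @param band `c(low_hz, high_hz)`.
#' @param n_subbands number of sub-bands (10 for the default 10-15 Hz
#'   decomposition, giving 0.5 Hz sub-bands).
#' @return A `subband_power`: list with `band_edges` (data.frame low/high)
#'   and `power` (channels x n_subbands matrix).
#' @export
subband_power <- function(psd, band = c(10, 15), n_subbands = 10L) {
  stopifnot(inherits(psd, "psd_estimate"), length(band) == 2, band[1] < band[2])
  freqs <- psd$frequencies
  if (band[1] < min(freqs) || band[2] > max(freqs))
    stop("band outside the PSD frequency range")
  edges <- seq(band[1], band[2], length.out = n_subbands + 1L)
  df <- diff(freqs[1:2])
  if ((band[2] - band[1]) / n_subbands < df - 1e-9)
    stop(sprintf(paste0("sub-band width %.3g Hz is below the frequency ",
                        "resolution %.3g Hz; increase the Welch segment ",
                        "length"), (band[2] - band[1]) / n_subbands, df))
  pw <- matrix(0, nrow(psd$power), n_subbands)
  for (b in seq_len(n_subbands)) {
    inb <- freqs >= edges[b] - 1e-9 & freqs < edges[b + 1L] - 1e-9
    if (!any(inb))
      stop(sprintf("sub-band [%.3g, %.3g) contains no frequency bin",
                   edges[b], edges[b + 1L]))
    pw[, b] <- rowMeans(psd$power[, inb, drop = FALSE])
  }
  structure(list(band_edges = data.frame(low = edges[-length(edges)],
                                         high = edges[-1]),
                 power = pw),
            class = "subband_power")
}

#' @export
print.subband_power <- function(x, ...) {
  cat(sprintf("<subband_power> %d channel(s) x %d bands (%g-%g Hz)\n",
              nrow(x$power), ncol(x$power), x$band_edges$low[1],
              x$band_edges$high[nrow(x$band_edges)]))
  invisible(x)
}
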
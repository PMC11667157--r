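#' Place per-channel values on the scalp topology grid
#'
#' Arranges one sub-band's 64 channel powers into the coarse 2D matrix
#' representing the spatial layout of the electrodes (the "topology
#' matrix"). Grid cells without an electrode are exactly zero and take
#' part in the subsequent interpolation, so the map fades towards the
#' border of the head just as in the source imagery.
#'
#' @param values numeric vector, one value per montage channel (channel
#'   order of the layout).
#' @param layout a [montage_layout()].
#' @param band_index optional integer tag identifying which sub-band the
#'   matrix represents.
#' @return A `topology_matrix`: a rows x cols numeric matrix (10 x 11 for
#'   the default montage) with attributes `band_index` and `layout`.
#' @export
build_topology <- function(values, layout = default_montage(),
                           band_index = NA_integer_) {
  stopifnot(inherits(layout, "montage_layout"))
  n_ch <- nrow(layout$placement)
  if (length(values) != n_ch)
    stop(sprintf("expected %d channel values, got %d", n_ch, length(values)))
  if (!all(is.finite(values)))
    stop("channel values must be finite")
  tm <- matrix(0, layout$grid_shape[1], layout$grid_shape[2])
  tm[cbind(layout$placement$row, layout$placement$col)] <- values
  structure(tm, band_index = band_index, layout = layout,
            class = c("topology_matrix", "matrix"))
}

#' Upsample a topology matrix by Clough-Tocher interpolation
#'
#' Interpolates the coarse electrode grid onto a dense uniform lattice
#' using the reduced Hsieh-Clough-Tocher C1 piecewise-cubic element over
#' the triangulated grid (see `ct_operator`). With the default montage the
#' 10 x 11 grid becomes a 110 x 100 image: the first output axis runs
#' along the 11-wide left-right direction of the scalp (110 uniformly
#' spaced points), the second along the 10-deep front-back direction
#' (100 points). Lattice points that coincide with source nodes reproduce
#' the source values.
#'
#' @param tm a `topology_matrix` (or plain matrix).
#' @param target_shape `c(nx, ny)`: lattice sizes along the column (x) and
#'   row (y) axes of the source grid. Both must be at least the matching
#'   source dimension.
#' @return An `nx x ny` numeric matrix.
#' @export
interp_topomap <- function(tm, target_shape = c(110L, 100L)) {
  if (!all(is.finite(tm))) stop("topology matrix contains non-finite values")
  nr <- nrow(tm); nc <- ncol(tm)
  nx <- as.integer(target_shape[1]); ny <- as.integer(target_shape[2])
  if (nx < nc || ny < nr)
    stop("target lattice must be at least as fine as the source grid")
  A <- ct_operator(nr, nc, nx, ny)
  matrix(A %*% as.vector(tm), nx, ny)
}

#' Assemble the spatial-spectral feature tensor of one trial
#'
#' Builds one interpolated topographic frame per sub-band and stacks the
#' frames along the third axis in ascending band order, yielding the
#' 110 x 100 x 10 input tensor of the pseudo-3D network.
#'
#' @param sbp a [subband_power()] result (channels x bands matrix with
#'   band edges), or a plain channels x bands matrix.
#' @param layout a [montage_layout()].
#' @param target_shape per-frame lattice shape, see [interp_topomap()].
#' @param n_bands expected number of frames; an error is raised if the
#'   sub-band count differs.
#' @param normalize `"none"` (default), `"log10"` (log10 of powers, with
#'   a small floor), or `"zscore"` (standardize the whole tensor to zero
#'   mean, unit sd). Applied to the channel powers before imaging.
#' @return A `feature_tensor`: numeric array `nx x ny x n_bands`.
#' @export
assemble_tensor <- function(sbp, layout = default_montage(),
                            target_shape = c(110L, 100L),
                            n_bands = ncol(power_matrix(sbp)),
                            normalize = c("none", "log10", "zscore")) {
  normalize <- match.arg(normalize)
  pw <- power_matrix(sbp)
  if (ncol(pw) != n_bands)
    stop(sprintf("expected %d sub-bands, got %d", n_bands, ncol(pw)))
  if (normalize == "log10") pw <- log10(pmax(pw, 1e-12))
  out <- array(0, dim = c(target_shape[1], target_shape[2], ncol(pw)))
  for (b in seq_len(ncol(pw)))
    out[, , b] <- interp_topomap(build_topology(pw[, b], layout,
                                                band_index = b),
                                 target_shape)
  if (normalize == "zscore") {
    s <- stats::sd(out)
    out <- (out - mean(out)) / if (s > 0) s else 1
  }
  structure(out, class = c("feature_tensor", "array"))
}

power_matrix <- function(x) {
  if (inherits(x, "subband_power")) x$power else as.matrix(x)
}

#' Convert labeled segments to stacked feature tensors
#'
#' Runs the full per-trial feature pipeline (Welch PSD, sub-band powers,
#' topographic imaging) over a list of segments and stacks the results
#' into one array for model training.
#'
#' @param segments list of `eeg_segment` (see [segment_trials()] or
#'   [simulate_mi_segments()]).
#' @param band `c(low_hz, high_hz)` analysis band.
#' @param n_subbands number of equal-width sub-bands (frames).
#' @param welch a [welch_config()].
#' @param layout a [montage_layout()].
#' @param target_shape per-frame lattice shape.
#' @param normalize passed to [assemble_tensor()].
#' @return list with `x` (array `n x nx x ny x n_bands`) and `y`
#'   (factor of class labels).
#' @export
tensorize_segments <- function(segments, band = c(10, 15), n_subbands = 10L,
                               welch = welch_config(),
                               layout = default_montage(),
                               target_shape = c(110L, 100L),
                               normalize = "none") {
  stopifnot(length(segments) >= 1)
  n <- length(segments)
  x <- array(0, dim = c(n, target_shape[1], target_shape[2], n_subbands))
  y <- character(n)
  for (i in seq_len(n)) {
    seg <- segments[[i]]
    psd <- welch_psd(seg$samples, welch, seg$sampling_rate)
    sbp <- subband_power(psd, band, n_subbands)
    x[i, , , ] <- assemble_tensor(sbp, layout, target_shape,
                                  normalize = normalize)
    y[i] <- seg$class_label
  }
  list(x = x, y = factor(y))
}
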
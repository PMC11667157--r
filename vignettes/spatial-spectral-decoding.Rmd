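---
title: "Spatial-spectral tensor decoding of motor imagery EEG"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Spatial-spectral tensor decoding of motor imagery EEG}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
library(mi3dnet)
```

## The decoding problem

Imagining a left- or right-fist movement desynchronizes the mu rhythm
(~8-15 Hz) over the contralateral sensorimotor cortex (event-related
desynchronization, ERD). `mi3dnet` decodes this binary contrast from
64-channel EEG by re-expressing each 4-s trial as a stack of scalp
*power images* and classifying the stack with a small factorized 3D
convolutional network. The pipeline is:

1. **Trials** — EDF recordings are cut into 4-s windows at the event
   onsets (640 samples at 160 Hz) and band-pass filtered to 5-35 Hz.
2. **Spectra** — each channel's Welch power spectral density is
   estimated from two non-overlapping 320-sample blocks (0.5 Hz bins).
3. **Sub-band powers** — the 10-15 Hz band is split into ten 0.5 Hz
   sub-bands; each channel contributes one mean power per sub-band.
4. **Topographic frames** — the 64 per-channel values of one sub-band
   are placed on a 10 x 11 scalp grid and upsampled by
   triangulation-based Clough-Tocher interpolation to a 110 x 100
   image; the ten frames are stacked into a 110 x 100 x 10 tensor.
5. **Network** — two pseudo-3D blocks (spatial 5x5x1 kernel, spectral
   1x1x5 kernel, then square -> strided 2x2x2 conv-pool -> log),
   batch normalization, dropout, a 256-unit fully connected layer and
   a 2-way softmax, trained by mini-batch SGD on the negative
   log-likelihood.

## The Welch estimator

For a channel of `N` samples, the estimator splits the signal into `L`
contiguous, non-overlapping blocks of `M` samples, multiplies each
block by a window `w(n)`, and averages the block periodograms
`|DFT(x_i w)|^2 / U` with the normalization `U = mean(w^2)` computed
from the actual window. Powers are one-sided densities scaled by
`1 / (fs * M * U)` (factor 2 on interior bins), so `sum(power) * df`
recovers the signal mean square - the Parseval identity the tests
check. Defaults: `M = 320` (the smallest block resolving 0.5 Hz
sub-bands at 160 Hz, giving `L = 2` per trial), Hamming window, no
overlap (the block definition is contiguous; 50% overlap is available
as a config variant). Sub-band values are means (not sums) of member
bins - `[low, high)` membership - so they do not depend on how many
bins a sub-band happens to contain.

## The topographic grid and its interpolation

The 64 electrodes of the 10-10 montage occupy a 10-row x 11-column
grid (row 1: Fp1 Fpz Fp2; row 5 is the full temporal row T9 T7 C5 ...
C6 T8 T10). The grid ships as an editable CSV
(`inst/extdata/montage_64_1010.csv`) so users can remap montages
without code changes. Cells without an electrode are exact zeros and
*participate* in the interpolation, so maps fade toward the head
border; masking them instead would change edge behavior and is
deliberately not the default.

Upsampling uses the reduced Hsieh-Clough-Tocher element: each grid
cell is split into two triangles, each triangle into three cubic
Bezier patches meeting with C1 continuity, with the closure that the
normal derivative varies linearly along outer edges. Vertex gradients
come from central (interior) / one-sided (boundary) finite
differences. Because the gradients are linear in the grid values, the
whole interpolant is a fixed linear operator; it is assembled once per
(grid, lattice) pair by solving the Bezier constraint system and
cached, making per-frame interpolation a single matrix-vector
product. The element reproduces constants and planes exactly (tested
at 1e-9 / 1e-8) and grid nodes by construction. The first tensor axis
(110 points) runs along the 11-wide left-right direction, the second
(100 points) along the 10-deep front-back direction.

## The network, numerically

Within a block the order is: spatial conv -> ReLU -> spectral conv ->
square -> conv-pool -> log, taking the stated sequence of squaring,
convolution-pooling and log literally; with an *averaging* pool this
is exactly a smoothed log-power feature, which the tests verify by
direct arithmetic. Three numerical choices matter:

* **Padding.** Spatial 5x5x1 kernels and the 2x2x2 stride-2 conv-pool
  are unpadded; the spectral 1x1x5 kernels are same-padded along depth
  only. Fully unpadded spectral kernels are geometrically impossible
  here: depth 10 becomes 6 after one spectral kernel and 3 after
  pooling, too thin for the second 1x1x5 kernel. Depth-preserving
  spectral convolution is the standard pseudo-3D factorization choice.
* **Batch normalization** follows conv layers 2 and 6 (numbering the
  six conv layers across both blocks), i.e. after the block-1 spectral
  conv (before the square) and after the block-2 conv-pool (before the
  log); the attachment rule is generic (`bn_after_layers`), so either
  reading of "after the k-th convolutional layer" can be configured.
* **Initialization.** Glorot-uniform everywhere, except: conv-pool
  weights are non-negative Glorot-uniform, so each square -> pool ->
  log block starts as a genuine log-power extractor (a signed pool
  would feed `log(max(x, 1e-6))` mostly saturated values at
  initialization); and the output layer starts at zero, so an
  untrained model predicts exactly (0.5, 0.5) and balanced-class
  training starts at `ln 2`. The log activation is floored at
  `eps = 1e-6` with zero gradient below the floor.

Training is plain mini-batch SGD with optional classical momentum and
no learning-rate schedule or early stopping. On this architecture the
square/log blocks make large steps unstable: at a 0.01 learning rate
training diverges and then collapses to chance, while the standard
0.001 rate (with momentum 0.9) descends smoothly - the package
defaults follow the latter.

## Zero-phase filtering of fixed-length trials

The 5-35 Hz band-pass is a linear-phase Hamming-window FIR sized by
its 2 Hz transition band (length `3.3 * fs / 2`, ~1.65 s at 160 Hz),
which comfortably exceeds the 40 dB stopband target. Because a trial
(4 s) is only ~2.4 filter lengths long, how edges are handled
dominates the realized attenuation: zero, even- or odd-reflection
padding leaves 1.6-9% RMS edge transients for a pure stopband tone.
The filter is therefore applied circularly in the DFT domain with its
group delay compensated, so each trial experiences exactly the
designed zero-phase amplitude response. The trade-off - wrap-around
mixing of the first and last ~1.65 s in place of pad transients - is
acceptable for fixed-length spectral features and is the documented
behavior of `bandpass()`.

## What the synthetic generator emulates

`simulate_mi_segments()` produces 64 x 640 trials containing:

* spatially correlated `1/f^alpha` background noise (`alpha = 1`,
  4 uV RMS): independent spectrally-shaped sources at each electrode
  mixed with Gaussian distance-decaying weights (sigma 1.5 grid
  units), emulating the similarity of neighboring channels;
* two narrowband mu sources (band-limited Gaussian noise, 10-15 Hz,
  6 uV RMS at the bump center) with Gaussian spatial profiles
  (sigma 2 grid units) centered on C3 and C4;
* lateralized ERD: a left-fist trial scales the C4-side mu *power* by
  `1 - erd_effect` and symmetrically for right-fist trials.

With these amplitudes roughly four fifths of the 10-15 Hz band power
over the motor channels is mu, so the measured between-class band
power ratio tracks `1 - erd_effect` (~0.42 at `erd_effect = 0.6`) -
the generator contract the tests verify. The generator makes no
attempt at biophysical realism beyond this: no volume-conduction
forward model, no eye/muscle artifacts, no inter-subject variability,
no beta-band ERS, stationary statistics within a trial. Passing tests
therefore demonstrate that the pipeline recovers a lateralized
narrowband power contrast of realistic size from realistic noise -
not that it reaches any particular accuracy on recorded human EEG.

## Desk-scale study configuration

`run_synthetic_study()` is the package's end-to-end experiment, also
recomputed by `scripts/acceptance.R`. Its defaults are chosen to train
in a few minutes on one CPU core: 100 trials per class, ERD effect
0.6, 10-15 Hz band, tensors interpolated to a 55 x 50 lattice (the
lattice is an explicit pipeline parameter; the full 110 x 100 shape is
the imaging default and is what the shape tests exercise), per-trial
z-scoring, the reduced network (4 and 8 filters), 25 epochs of SGD at
learning rate 0.001 with momentum 0.9 and batch 16, and the seeded
75-25 split. Under these conditions the decoder reaches >= 90%
held-out accuracy, stays at chance when `erd_effect = 0`, and the
5-35 Hz band scan (ridge-classifier protocol, 3 repeated splits)
selects the 10-15 Hz band.

## Evaluation conventions

Headline accuracy over subjects is the *unweighted mean of
per-subject rates* (a pooled-count variant is provided separately);
kappa uses the fixed chance rate 0.5 of the balanced binary task, so
`kappa = 2 * accuracy - 1`; recall/precision/F1 default to
`left_fist` as the positive class (configurable); the train/test
split is a seed-42 shuffle of the whole dataset with a 75-25 cut,
non-stratified by default. When per-subject tables are supplied, the
report carries both the kappa of the average accuracy and the mean of
per-subject kappas - the two conventions differ and the package does
not force them to agree.

## Known limitations

* The network is CPU-bound R/C++ code; it is sized for hundreds of
  trials, not for the full 104-subject benchmark with 500-epoch
  training, whose published accuracies this package does not attempt
  to reproduce.
* The EDF reader covers the common EDF/EDF+ continuous layout (16-bit
  samples, one annotation signal) - not discontinuous EDF+D files or
  logarithmically transduced signals.
* Band-scan accuracies depend on the injected classifier protocol;
  the fast ridge classifier ranks bands reliably but its absolute
  accuracies are not comparable to the network's.
* Circular filter application assumes the trial is analyzed as a
  window (spectral features); for waveform-domain analyses a
  continuous-recording filter should be preferred.
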
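#' Run the desk-scale synthetic decoding study
#'
#' End-to-end run of the pipeline on synthetic trials: generate labeled
#' mu-ERD EEG, build 10-frame spatial-spectral tensors for the 10-15 Hz
#' band, split 75-25 with the seeded shuffle, train the reduced
#' pseudo-3D network, and score the held-out set. The desk-scale
#' defaults (55 x 50 per-frame lattice, 4/8 filters, 25 epochs of
#' mini-batch SGD at the standard 0.001 learning rate with momentum 0.9,
#' batch 16, z-scored tensors) train in a few minutes on one CPU core;
#' see the methods vignette for how they were chosen.
#'
#' @param n_trials_per_class trials per class.
#' @param erd_effect contralateral mu power reduction in `[0, 1)`.
#' @param seed master seed; the generator, weight initialization and
#'   SGD shuffling derive their seeds from it. The split keeps its own
#'   conventional seed (42) from `split`.
#' @param band analysis band in Hz.
#' @param n_subbands tensor frames.
#' @param target_shape per-frame lattice.
#' @param epochs,learning_rate,momentum,batch_size training schedule.
#' @param model_config optional [p3dcnn_config()] override.
#' @param split a [split_spec()].
#' @param normalize tensor normalization (see [assemble_tensor()]).
#' @return list with `report` (a [metrics_report()]), `model`,
#'   `history`, `n_train`, `n_test`.
#' @export
run_synthetic_study <- function(n_trials_per_class = 100L,
                                erd_effect = 0.6, seed = 1L,
                                band = c(10, 15), n_subbands = 10L,
                                target_shape = c(55L, 50L),
                                epochs = 25L, learning_rate = 0.001,
                                momentum = 0.9, batch_size = 16L,
                                model_config = NULL,
                                split = split_spec(),
                                normalize = "zscore") {
  segs <- simulate_mi_segments(
    synthetic_mi_config(n_trials_per_class = n_trials_per_class,
                        erd_effect = erd_effect, seed = seed))
  feats <- tensorize_segments(segs, band = band, n_subbands = n_subbands,
                              target_shape = target_shape,
                              normalize = normalize)
  sp <- train_test_split(feats$y, split)
  cfg <- model_config %||%
    p3dcnn_config_reduced(input_shape = c(target_shape, n_subbands))
  model <- build_p3dcnn(cfg, seed = seed + 1L)
  tc <- train_config(epochs = epochs, learning_rate = learning_rate,
                     batch_size = batch_size, momentum = momentum,
                     seed = seed + 2L)
  model <- train_p3dcnn(model, feats$x, feats$y, tc, subset = sp$train)
  pred <- predict(model, feats$x[sp$test, , , , drop = FALSE],
                  type = "class")
  report <- metrics_report(feats$y[sp$test], pred)
  list(report = report, model = model,
       history = model$training_history,
       n_train = length(sp$train), n_test = length(sp$test))
}
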
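# Arithmetic shape oracle: valid convolution along x/y, same-padded
# spectral depth, stride-2 unpadded conv-pool.
oracle_shapes <- function(input, k_sp, k_fr, k_pool, s, f1, f2) {
  conv <- function(d, k, st, pad_z = 0) {
    c((d[1] - k[1]) %/% st + 1, (d[2] - k[2]) %/% st + 1,
      (d[3] + 2 * pad_z - k[3]) %/% st + 1)
  }
  d <- input
  out <- list()
  for (f in c(f1, f2)) {
    d <- conv(d, k_sp, 1)
    out <- c(out, list(c(d, f)))
    d <- conv(d, k_fr, 1, pad_z = (k_fr[3] - 1) %/% 2)
    out <- c(out, list(c(d, f)))
    d <- conv(d, k_pool, s)
    out <- c(out, list(c(d, f)))
  }
  out
}

test_that("the default build has a 256-unit FC layer and 2-way softmax", {
  m <- build_p3dcnn(p3dcnn_config(), seed = 1)
  sh <- model_shapes(m)
  expect_equal(sh$shape[sh$layer == "fc"], "256")
  expect_equal(sh$shape[sh$layer == "output"], "2")
  expect_equal(m$config$dropout_p, 0.5)
})

test_that("per-layer shapes match the arithmetic oracle", {
  for (cfgs in list(list(p3dcnn_config(), c(110, 100, 10), c(5, 5, 1),
                         c(1, 1, 5), c(2, 2, 2), 16, 32),
                    list(tiny_model_config(), c(14, 12, 8), c(3, 3, 1),
                         c(1, 1, 3), c(2, 2, 2), 2, 3))) {
    m <- build_p3dcnn(cfgs[[1]], seed = 1)
    want <- oracle_shapes(cfgs[[2]], cfgs[[3]], cfgs[[4]], cfgs[[5]], 2,
                          cfgs[[6]], cfgs[[7]])
    got <- lapply(Filter(function(l) l$type == "conv", m$layers),
                  `[[`, "out_shape")
    expect_equal(lapply(got, as.numeric), lapply(want, as.numeric))
  }
})

test_that("too-small feature maps raise an error naming the layer", {
  expect_error(build_p3dcnn(p3dcnn_config(input_shape = c(12, 12, 10))),
               "conv")
})

test_that("the parameter count equals an independent hand calculation", {
  cfg <- p3dcnn_config()
  m <- build_p3dcnn(cfg, seed = 1)
  f1 <- 16; f2 <- 32
  flat <- 24 * 22 * 2 * f2      # block-2 conv-pool output, from the oracle
  by_hand <- (5 * 5 * 1 * 1 * f1 + f1) +          # conv1 spatial
             (1 * 1 * 5 * f1 * f1 + f1) +         # conv2 spectral
             2 * f1 +                             # bn after conv2
             (2 * 2 * 2 * f1 * f1 + f1) +         # conv3 pool
             (5 * 5 * 1 * f1 * f2 + f2) +         # conv4 spatial
             (1 * 1 * 5 * f2 * f2 + f2) +         # conv5 spectral
             (2 * 2 * 2 * f2 * f2 + f2) +         # conv6 pool
             2 * f2 +                             # bn after conv6
             (flat * 256 + 256) +                 # fc
             (256 * 2 + 2)                        # output
  expect_equal(n_parameters(m), by_hand)
})

test_that("softmax outputs are normalized probabilities", {
  m <- build_p3dcnn(tiny_model_config(), seed = 3)
  set.seed(1)
  x <- array(rnorm(4 * 14 * 12 * 8), c(4, 14, 12, 8))
  p <- forward(m, x)
  expect_equal(dim(p), c(4L, 2L))
  expect_lt(max(abs(rowSums(p) - 1)), 1e-6)
  expect_true(all(p > 0 & p < 1))
  # an untrained model (zero output layer) predicts exactly (0.5, 0.5)
  expect_lt(max(abs(p - 0.5)), 1e-12)
  # single tensor input yields one probability row
  expect_equal(dim(forward(m, x[1, , , ])), c(1L, 2L))
})

test_that("eval-mode forward is deterministic and row-consistent", {
  m <- build_p3dcnn(tiny_model_config(dropout_p = 0.5), seed = 3)
  sep <- separable_tensors(8)
  m <- train_p3dcnn(m, sep$x, sep$y,
                    train_config(epochs = 2, learning_rate = 0.005,
                                 batch_size = 4, seed = 1))
  x2 <- sep$x[c(1, 1, 2), , , , drop = FALSE]
  p1 <- forward(m, x2); p2 <- forward(m, x2)
  expect_identical(p1, p2)
  expect_equal(p1[1, ], p1[2, ])            # duplicated inputs agree
})

test_that("nll_loss matches its closed forms and the per-sample oracle", {
  expect_equal(nll_loss(matrix(0.5, 1, 2), 1L), log(2))
  expect_equal(nll_loss(matrix(c(1, 0), 1), 1L), 0)
  p <- rbind(c(0.8, 0.2), c(0.3, 0.7))
  by_hand <- mean(c(-log(0.8), -log(0.7)))
  expect_equal(nll_loss(p, c(1L, 2L)), by_hand)
  colnames(p) <- c("left_fist", "right_fist")
  expect_equal(nll_loss(p, c("left_fist", "right_fist")), by_hand)
  expect_warning(nll_loss(rbind(c(0, 1)), 1L), "clamped")
})

test_that("a square -> uniform pool -> log block computes log mean power", {
  # fix the conv-pool weights to an exact average and push a known
  # input through square / pool / log by direct arithmetic
  x <- array(abs(rnorm(6 * 6 * 4)) + 0.5, c(6, 6, 4, 1, 1))
  sq <- x^2
  w <- array(1 / 8, c(2, 2, 2, 1, 1))
  pooled <- mi3dnet:::conv3d_fwd(sq, dim(sq), w, dim(w), 0, c(2L, 2L, 2L))
  got <- log(pmax(pooled, 1e-6))
  ref <- array(0, c(3, 3, 2))
  for (i in 1:3) for (j in 1:3) for (k in 1:2)
    ref[i, j, k] <- log(mean(sq[2 * i - 1:0, 2 * j - 1:0,
                                2 * k - 1:0, 1, 1]))
  expect_lt(max(abs(got[, , , 1, 1] - ref)), 1e-12)
})

test_that("training reaches 100% on a separable fixture, loss decreasing", {
  sep <- separable_tensors(24)
  m <- build_p3dcnn(tiny_model_config(), seed = 1)
  m <- train_p3dcnn(m, sep$x, sep$y,
                    train_config(epochs = 40, learning_rate = 0.003,
                                 batch_size = 8, momentum = 0.9, seed = 4))
  h <- m$training_history
  expect_equal(h$accuracy[40], 1)
  pred <- predict(m, sep$x, type = "class")
  expect_equal(as.character(pred), as.character(sep$y))
  # steady descent: 5-epoch block means are non-increasing (5% slack
  # absorbs mini-batch noise) and the final loss is far below the start
  blocks <- colMeans(matrix(h$loss, nrow = 5))
  expect_true(all(diff(blocks) <= 0.05 * blocks[-length(blocks)]))
  expect_lt(h$loss[40], 0.05 * h$loss[1])
})

test_that("the first-epoch loss starts near ln 2 for balanced classes", {
  sep <- separable_tensors(16)
  m <- build_p3dcnn(tiny_model_config(), seed = 2)
  m <- train_p3dcnn(m, sep$x, sep$y,
                    train_config(epochs = 1, learning_rate = 1e-5,
                                 batch_size = 16, seed = 1))
  expect_lt(abs(m$training_history$loss[1] - log(2)), 0.1)
})

test_that("training is reproducible given the seed", {
  sep <- separable_tensors(8)
  run <- function() {
    m <- build_p3dcnn(tiny_model_config(dropout_p = 0.3), seed = 7)
    m <- train_p3dcnn(m, sep$x, sep$y,
                      train_config(epochs = 3, learning_rate = 0.005,
                                   batch_size = 4, seed = 11))
    forward(m, sep$x)
  }
  expect_identical(run(), run())
})

test_that("analytic gradients agree with finite differences", {
  cfg <- tiny_model_config()
  m <- build_p3dcnn(cfg, seed = 5)
  m$layers[[length(m$layers)]]$W <- matrix(rnorm(16, sd = 0.3), 2, 8)
  for (i in seq_along(m$layers))
    if (m$layers[[i]]$type == "bn") m$layers[[i]]$momentum <- 0
  set.seed(3)
  n <- 4
  x <- array(rnorm(n * 14 * 12 * 8), c(n, 14, 12, 8))
  yi <- rep(1:2, 2)
  loss_of <- function(m) {
    xb <- mi3dnet:::as_internal_batch(x, cfg$input_shape)
    fw <- mi3dnet:::model_forward(m, xb, training = TRUE)
    list(loss = mean(-log(fw$probs[cbind(yi, 1:n)])), fw = fw)
  }
  r <- loss_of(m)
  onehot <- matrix(0, 2, n); onehot[cbind(yi, 1:n)] <- 1
  g <- (r$fw$probs - onehot) / n
  grads <- vector("list", length(m$layers))
  for (i in rev(seq_along(m$layers))) {
    bk <- mi3dnet:::layer_backward(m$layers[[i]], g, r$fw$caches[[i]])
    g <- bk$gx
    grads[i] <- list(bk$grads)
  }
  h <- 1e-6
  set.seed(8)
  for (i in seq_along(grads)) {
    gr <- grads[[i]]
    if (is.null(gr)) next
    for (nm in names(gr)) {
      j <- sample(length(gr[[nm]]), 1)
      mp <- m; mp$layers[[i]][[nm]][j] <- mp$layers[[i]][[nm]][j] + h
      mm <- m; mm$layers[[i]][[nm]][j] <- mm$layers[[i]][[nm]][j] - h
      fd <- (loss_of(mp)$loss - loss_of(mm)$loss) / (2 * h)
      expect_lt(abs(fd - gr[[nm]][j]) / max(1e-4, abs(fd)), 1e-3)
    }
  }
})

test_that("activation export matches the documented stages", {
  m <- build_p3dcnn(tiny_model_config(), seed = 1)
  set.seed(2)
  x <- array(rnorm(3 * 14 * 12 * 8), c(3, 14, 12, 8))
  expect_equal(dim(export_activations(m, x, "softmax")), c(3L, 2L))
  expect_equal(dim(export_activations(m, x, "raw")),
               c(3L, 14L * 12L * 8L))
  expect_equal(dim(export_activations(m, x, "fc")), c(3L, 8L))
  a1 <- export_activations(m, x, "pool2")
  expect_identical(a1, export_activations(m, x, "pool2"))
  expect_error(export_activations(m, x, "bogus"), "valid tags")
})

test_that("input shape mismatches are rejected", {
  m <- build_p3dcnn(tiny_model_config(), seed = 1)
  expect_error(forward(m, array(0, c(2, 10, 12, 8))), "shape")
  sep <- separable_tensors(8)
  expect_error(train_p3dcnn(build_p3dcnn(tiny_model_config()), sep$x,
                            sep$y,
                            train_config(epochs = 1, batch_size = 50)),
               "batch_size")
})
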
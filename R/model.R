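#' Architecture configuration of the pseudo-3D network
#'
#' The network factorizes 3D convolution into a spatial kernel (5 x 5 x 1)
#' followed by a spectral kernel (1 x 1 x 5), grouped into two blocks.
#' Each block runs: spatial conv -> ReLU -> spectral conv -> square ->
#' conv-pool (a learnable 2 x 2 x 2 convolution with stride 2, no
#' padding) -> log, i.e. it ends in a smoothed log-power feature. Batch
#' normalization follows the conv layers listed in `bn_after_layers`
#' (conv layers are numbered 1-6 across the two blocks; the default
#' `c(2, 6)` normalizes after the block-1 spectral conv and after the
#' block-2 conv-pool). Dropout follows block 2, then a 256-unit ReLU
#' fully connected layer and a softmax output over the two imagery
#' classes.
#'
#' Spatial and conv-pool kernels are unpadded; the spectral (1 x 1 x k)
#' convolutions are same-padded along the depth axis only, so ten
#' sub-band frames survive both blocks (unpadded spectral kernels would
#' leave fewer frames than the second kernel needs).
#'
#' @param input_shape `c(x, y, bands)` of one feature tensor.
#' @param n_filters_block1,n_filters_block2 filters per conv layer in
#'   each block.
#' @param fc_units width of the fully connected hidden layer.
#' @param n_classes number of output classes K.
#' @param dropout_p dropout probability after block 2.
#' @param spatial_kernel,spectral_kernel,pool_kernel kernel shapes.
#' @param pool_stride stride of the conv-pool layers.
#' @param bn_after_layers conv layer indices (1-6) followed by batch
#'   normalization.
#' @param bn_momentum,bn_eps batch-normalization running-stat momentum
#'   and variance floor.
#' @param log_eps floor applied inside the log activation,
#'   `log(max(x, log_eps))`.
#' @return A `p3dcnn_config`.
#' @export
p3dcnn_config <- function(input_shape = c(110L, 100L, 10L),
                          n_filters_block1 = 16L, n_filters_block2 = 32L,
                          fc_units = 256L, n_classes = 2L, dropout_p = 0.5,
                          spatial_kernel = c(5L, 5L, 1L),
                          spectral_kernel = c(1L, 1L, 5L),
                          pool_kernel = c(2L, 2L, 2L), pool_stride = 2L,
                          bn_after_layers = c(2L, 6L),
                          bn_momentum = 0.1, bn_eps = 1e-5,
                          log_eps = 1e-6) {
  if (dropout_p < 0 || dropout_p >= 1) stop("dropout_p must be in [0, 1)")
  if (n_classes < 2) stop("n_classes must be >= 2")
  structure(as.list(environment()), class = "p3dcnn_config")
}

#' Reduced preset of the network for desk-scale experiments
#'
#' Same architecture with fewer filters (4 / 8); suitable for CPU
#' training on a few hundred trials.
#' @param ... overrides passed to [p3dcnn_config()].
#' @export
p3dcnn_config_reduced <- function(...) {
  p3dcnn_config(n_filters_block1 = 4L, n_filters_block2 = 8L, ...)
}

glorot <- function(dims, positive = FALSE, fan_in, fan_out) {
  lim <- sqrt(6 / (fan_in + fan_out))
  w <- stats::runif(prod(dims), -lim, lim)
  if (positive) w <- abs(w)
  array(w, dims)
}

#' Build an (untrained) pseudo-3D network
#'
#' Weights are Glorot-uniform; the conv-pool layers use non-negative
#' Glorot-uniform weights so each square -> pool -> log block starts out
#' as a smoothed log-power extractor, and the output layer is
#' zero-initialized so an untrained model predicts the uniform
#' distribution (balanced-class starting loss ln K).
#'
#' @param config a [p3dcnn_config()].
#' @param seed integer seed for weight initialization.
#' @return A `p3dcnn` model object.
#' @export
build_p3dcnn <- function(config = p3dcnn_config(), seed = 1L) {
  stopifnot(inherits(config, "p3dcnn_config"))
  old_seed <- if (exists(".Random.seed", globalenv()))
    get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old_seed))
    assign(".Random.seed", old_seed, globalenv()))
  set.seed(seed)

  layers <- list()
  shape <- c(config$input_shape, 1L)        # (X, Y, Z, C)
  conv_idx <- 0L
  add <- function(l) layers[[length(layers) + 1L]] <<- l
  conv_out_shape <- function(shape, kern, stride, pad_z, co, name) {
    zin <- shape[3] + 2L * pad_z
    out <- c((shape[1] - kern[1]) %/% stride[1] + 1L,
             (shape[2] - kern[2]) %/% stride[2] + 1L,
             (zin - kern[3]) %/% stride[3] + 1L, co)
    if (shape[1] < kern[1] || shape[2] < kern[2] || zin < kern[3])
      stop(sprintf(paste0("layer %s: feature map %s is smaller than the ",
                          "kernel %s"), name,
                   paste(shape[1:3], collapse = "x"),
                   paste(kern, collapse = "x")))
    out
  }
  add_conv <- function(kern, co, stride, pad_z, init, kind, blk,
                       tag = NULL) {
    conv_idx <<- conv_idx + 1L
    name <- sprintf("conv%d (block %d %s)", conv_idx, blk, kind)
    ci <- shape[4]
    w <- glorot(c(kern, ci, co), positive = identical(init, "glorot_pos"),
                fan_in = prod(kern) * ci, fan_out = prod(kern) * co)
    out <- conv_out_shape(shape, kern, stride, pad_z, co, name)
    add(list(type = "conv", name = name, tag = tag, w = w,
             b = numeric(co), stride = as.integer(stride),
             pad_z = as.integer(pad_z), out_shape = out))
    shape <<- out
    if (conv_idx %in% config$bn_after_layers)
      add(list(type = "bn", name = paste0("bn", conv_idx),
               gamma = rep(1, co), beta = numeric(co),
               run_mean = numeric(co), run_var = rep(1, co),
               momentum = config$bn_momentum, eps = config$bn_eps,
               out_shape = shape))
  }
  nf <- c(config$n_filters_block1, config$n_filters_block2)
  for (b in 1:2) {
    add_conv(config$spatial_kernel, nf[b], c(1L, 1L, 1L), 0L, "glorot",
             "spatial", b, tag = if (b == 1L) "conv1")
    add(list(type = "relu", name = sprintf("relu%d", b), out_shape = shape))
    add_conv(config$spectral_kernel, nf[b], c(1L, 1L, 1L),
             (config$spectral_kernel[3] - 1L) %/% 2L, "glorot",
             "spectral", b)
    add(list(type = "square", name = sprintf("square%d", b),
             out_shape = shape))
    add_conv(config$pool_kernel, nf[b], rep(config$pool_stride, 3L), 0L,
             "glorot_pos", "conv-pool", b)
    add(list(type = "logact", name = sprintf("log%d", b),
             eps = config$log_eps, out_shape = shape,
             tag = paste0("pool", b)))
  }
  add(list(type = "dropout", name = "dropout", p = config$dropout_p,
           out_shape = shape))
  flat <- prod(shape)
  add(list(type = "flatten", name = "flatten", out_shape = flat))
  W1 <- glorot(c(config$fc_units, flat), fan_in = flat,
               fan_out = config$fc_units)
  add(list(type = "dense", name = "fc", tag = "fc", W = W1,
           b = numeric(config$fc_units), activation = "relu",
           out_shape = config$fc_units))
  add(list(type = "dense", name = "output",
           W = matrix(0, config$n_classes, config$fc_units),
           b = numeric(config$n_classes), activation = "linear",
           out_shape = config$n_classes))
  structure(list(config = config, layers = layers, classes = NULL,
                 training_history = NULL),
            class = "p3dcnn")
}

#' @export
print.p3dcnn <- function(x, ...) {
  cat(sprintf("<p3dcnn> input %s, %d layers, %d parameters%s\n",
              paste(x$config$input_shape, collapse = "x"),
              length(x$layers), n_parameters(x),
              if (is.null(x$training_history)) " (untrained)" else ""))
  invisible(x)
}

#' Per-layer output shapes
#' @param model a `p3dcnn`.
#' @return data.frame with layer names and output shapes.
#' @export
model_shapes <- function(model) {
  data.frame(layer = vapply(model$layers, `[[`, "", "name"),
             shape = vapply(model$layers, function(l)
               paste(l$out_shape, collapse = "x"), ""))
}

#' Trainable parameter count
#' @param model a `p3dcnn`.
#' @return Integer: weights + biases + batch-norm scale/shift.
#' @export
n_parameters <- function(model) {
  sum(vapply(model$layers, function(l) {
    switch(l$type,
           conv = length(l$w) + length(l$b),
           bn = length(l$gamma) + length(l$beta),
           dense = length(l$W) + length(l$b),
           0L)
  }, numeric(1)))
}

pad_z_array <- function(x, p) {
  if (p == 0L) return(x)
  d <- dim(x)
  out <- array(0, c(d[1], d[2], d[3] + 2L * p, d[4], d[5]))
  out[, , p + seq_len(d[3]), , ] <- x
  out
}

bn_channel_stats <- function(x3, C) {
  mu <- numeric(C); vv <- numeric(C)
  for (c in seq_len(C)) {
    sl <- x3[, c, ]
    mu[c] <- mean(sl)
    vv[c] <- mean((sl - mu[c])^2)
  }
  list(mu = mu, var = vv)
}

layer_forward <- function(l, x, training) {
  switch(l$type,
    conv = {
      xp <- pad_z_array(x, l$pad_z)
      out <- conv3d_fwd(xp, dim(xp), l$w, dim(l$w), l$b, l$stride)
      list(out = out, cache = if (training) list(xp = xp), layer = l)
    },
    relu = {
      out <- x * (x > 0)
      list(out = out, cache = if (training) list(mask = x > 0), layer = l)
    },
    square = list(out = x * x, cache = if (training) list(x = x), layer = l),
    logact = {
      out <- x
      out[] <- log(pmax(x, l$eps))
      list(out = out, cache = if (training) list(x = x), layer = l)
    },
    bn = {
      d <- dim(x); C <- d[4]; S <- prod(d[1:3]); N <- d[5]
      x3 <- x; dim(x3) <- c(S, C, N)
      if (training) {
        st <- bn_channel_stats(x3, C)
        mu <- st$mu; vv <- st$var
        l$run_mean <- (1 - l$momentum) * l$run_mean + l$momentum * mu
        l$run_var <- (1 - l$momentum) * l$run_var + l$momentum * vv
      } else {
        mu <- l$run_mean; vv <- l$run_var
      }
      inv_sd <- 1 / sqrt(vv + l$eps)
      xhat <- (as.vector(x) - rep(mu, each = S)) * rep(inv_sd, each = S)
      out <- xhat * rep(l$gamma, each = S) + rep(l$beta, each = S)
      dim(out) <- d
      if (training) dim(xhat) <- d
      list(out = out,
           cache = if (training) list(xhat = xhat, inv_sd = inv_sd, S = S),
           layer = l)
    },
    dropout = {
      if (training && l$p > 0) {
        mask <- (stats::runif(length(x)) >= l$p) / (1 - l$p)
        dim(mask) <- dim(x)
        list(out = x * mask, cache = list(mask = mask), layer = l)
      } else list(out = x, cache = NULL, layer = l)
    },
    flatten = {
      d <- dim(x)
      out <- x
      dim(out) <- c(prod(d[1:4]), d[5])
      list(out = out, cache = if (training) list(d = d), layer = l)
    },
    dense = {
      z <- l$W %*% x + l$b
      out <- if (l$activation == "relu") z * (z > 0) else z
      list(out = out,
           cache = if (training) list(x = x, mask = if (l$activation ==
                                      "relu") z > 0),
           layer = l)
    },
    stop("unknown layer type ", l$type))
}

layer_backward <- function(l, g, cache) {
  switch(l$type,
    conv = {
      xp <- cache$xp
      gw <- conv3d_bwd_weights(xp, dim(xp), g, dim(g), dim(l$w), l$stride)
      gx <- conv3d_bwd_input(g, dim(g), l$w, dim(l$w), dim(xp), l$stride)
      if (l$pad_z > 0L) {
        d <- dim(gx)
        gx <- gx[, , l$pad_z + seq_len(d[3] - 2L * l$pad_z), , , drop = FALSE]
      }
      list(gx = gx, grads = list(w = gw$dw, b = gw$db))
    },
    relu = list(gx = g * cache$mask, grads = NULL),
    square = list(gx = 2 * g * cache$x, grads = NULL),
    logact = list(gx = g * (cache$x > l$eps) / pmax(cache$x, l$eps),
                  grads = NULL),
    bn = {
      d <- dim(g); C <- d[4]; S <- cache$S; N <- d[5]
      m <- S * N
      g3 <- g; dim(g3) <- c(S, C, N)
      xh3 <- cache$xhat; dim(xh3) <- c(S, C, N)
      sg <- numeric(C); sgx <- numeric(C)
      for (c in seq_len(C)) {
        sg[c] <- sum(g3[, c, ])
        sgx[c] <- sum(g3[, c, ] * xh3[, c, ])
      }
      coef <- l$gamma * cache$inv_sd
      gx <- (as.vector(g) - rep(sg / m, each = S) -
             as.vector(cache$xhat) * rep(sgx / m, each = S)) *
            rep(coef, each = S)
      dim(gx) <- d
      list(gx = gx, grads = list(gamma = sgx, beta = sg))
    },
    dropout = {
      if (is.null(cache)) list(gx = g, grads = NULL)
      else list(gx = g * cache$mask, grads = NULL)
    },
    flatten = {
      gx <- g
      dim(gx) <- cache$d
      list(gx = gx, grads = NULL)
    },
    dense = {
      if (!is.null(cache$mask)) g <- g * cache$mask
      list(gx = crossprod(l$W, g),
           grads = list(W = tcrossprod(g, cache$x), b = rowSums(g)))
    },
    stop("unknown layer type ", l$type))
}

# x: [n, X, Y, Z] array (or [X, Y, Z] for one sample) -> internal layout
as_internal_batch <- function(x, input_shape) {
  if (length(dim(x)) == 3L) dim(x) <- c(1L, dim(x))
  d <- dim(x)
  if (!identical(as.integer(d[-1]), as.integer(input_shape)))
    stop(sprintf("input shape %s does not match model input %s",
                 paste(d[-1], collapse = "x"),
                 paste(input_shape, collapse = "x")))
  xb <- aperm(x, c(2, 3, 4, 1))
  dim(xb) <- c(d[2], d[3], d[4], 1L, d[1])
  xb
}

model_forward <- function(model, xb, training = FALSE, capture = NULL) {
  caches <- vector("list", length(model$layers))
  acts <- list()
  if (!is.null(capture) && "raw" %in% capture) acts$raw <- xb
  h <- xb
  for (i in seq_along(model$layers)) {
    r <- layer_forward(model$layers[[i]], h, training)
    h <- r$out
    model$layers[[i]] <- r$layer
    if (training) caches[[i]] <- r$cache
    tag <- model$layers[[i]]$tag
    if (!is.null(capture) && !is.null(tag) && tag %in% capture)
      acts[[tag]] <- h
  }
  # softmax over the final logits (columns = samples)
  zmax <- apply(h, 2, max)
  ez <- exp(sweep(h, 2, zmax))
  probs <- sweep(ez, 2, colSums(ez), `/`)
  if (!is.null(capture) && "softmax" %in% capture) acts$softmax <- probs
  list(logits = h, probs = probs, caches = caches, acts = acts,
       layers = model$layers)
}

#' Class probabilities for a batch of feature tensors
#'
#' Runs the network in evaluation mode (dropout off, batch-norm running
#' statistics).
#'
#' @param model a trained or untrained `p3dcnn`.
#' @param x array `n x X x Y x Z` (or a single `X x Y x Z` tensor).
#' @param batch_size samples per forward chunk.
#' @return `n x K` matrix of probabilities; columns named by class when
#'   the model has been trained.
#' @export
forward <- function(model, x, batch_size = 32L) {
  stopifnot(inherits(model, "p3dcnn"))
  if (length(dim(x)) == 3L) dim(x) <- c(1L, dim(x))
  n <- dim(x)[1]
  out <- matrix(NA_real_, n, model$config$n_classes)
  for (start in seq(1L, n, by = batch_size)) {
    idx <- start:min(n, start + batch_size - 1L)
    xb <- as_internal_batch(x[idx, , , , drop = FALSE],
                            model$config$input_shape)
    out[idx, ] <- t(model_forward(model, xb, training = FALSE)$probs)
  }
  if (!is.null(model$classes)) colnames(out) <- model$classes
  out
}

#' @export
#' @rdname forward
#' @param object,... standard predict arguments; `type` one of
#'   `"prob"` or `"class"`.
#' @param type output type.
predict.p3dcnn <- function(object, x, type = c("prob", "class"),
                           batch_size = 32L, ...) {
  type <- match.arg(type)
  p <- forward(object, x, batch_size)
  if (type == "prob") return(p)
  cls <- colnames(p) %||% as.character(seq_len(ncol(p)))
  factor(cls[max.col(p)], levels = cls)
}

#' Mean negative log-likelihood of predicted probabilities
#'
#' `mean(-log p[true class])` over the batch. Zero probabilities at the
#' true class are floored at `eps` with a warning.
#'
#' @param probabilities `n x K` matrix, rows summing to 1.
#' @param labels integer class indices (1..K), or a factor/character
#'   matching the probability column names.
#' @param eps floor for the true-class probability.
#' @return Mean negative log-likelihood (nats).
#' @export
nll_loss <- function(probabilities, labels, eps = 1e-12) {
  probabilities <- as.matrix(probabilities)
  if (is.factor(labels) || is.character(labels)) {
    cls <- colnames(probabilities)
    if (is.null(cls)) stop("probability columns are unnamed; supply indices")
    labels <- match(as.character(labels), cls)
    if (anyNA(labels)) stop("labels not found among probability columns")
  }
  stopifnot(all(labels >= 1), all(labels <= ncol(probabilities)))
  p <- probabilities[cbind(seq_len(nrow(probabilities)), labels)]
  if (any(p < eps)) {
    warning("true-class probabilities below eps were clamped")
    p <- pmax(p, eps)
  }
  mean(-log(p))
}

#' Training configuration (mini-batch SGD)
#'
#' @param epochs passes over the training set.
#' @param learning_rate SGD step size.
#' @param batch_size mini-batch size.
#' @param momentum classical momentum (0 = plain SGD).
#' @param seed RNG seed controlling shuffling, dropout and (via
#'   [build_p3dcnn()] if rebuilt) initialization.
#' @param verbose print per-epoch loss.
#' @return A `train_config`.
#' @export
train_config <- function(epochs = 500L, learning_rate = 0.001,
                         batch_size = 64L, momentum = 0, seed = 1L,
                         verbose = FALSE) {
  stopifnot(epochs >= 1, learning_rate > 0, batch_size >= 1)
  structure(as.list(environment()), class = "train_config")
}

#' Train the network with mini-batch SGD on the NLL loss
#'
#' @param model a `p3dcnn` from [build_p3dcnn()].
#' @param x array `n x X x Y x Z` of feature tensors.
#' @param y factor (or character) of class labels, length n.
#' @param config a [train_config()].
#' @param subset optional integer indices restricting training to a
#'   subset of `x` without copying it.
#' @return The trained model; `$training_history` holds per-epoch mean
#'   loss and training accuracy.
#' @export
train_p3dcnn <- function(model, x, y, config = train_config(),
                         subset = NULL) {
  stopifnot(inherits(model, "p3dcnn"), inherits(config, "train_config"))
  y <- factor(y)
  if (nlevels(y) != model$config$n_classes)
    stop("number of classes in y does not match the model")
  model$classes <- levels(y)
  yi <- as.integer(y)
  idx_all <- subset %||% seq_len(dim(x)[1])
  n <- length(idx_all)
  if (config$batch_size > n) stop("batch_size exceeds the training set")
  old_seed <- if (exists(".Random.seed", globalenv()))
    get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old_seed))
    assign(".Random.seed", old_seed, globalenv()))
  set.seed(config$seed)

  vel <- NULL
  hist_loss <- numeric(config$epochs)
  hist_acc <- numeric(config$epochs)
  K <- model$config$n_classes
  for (ep in seq_len(config$epochs)) {
    ord <- idx_all[sample.int(n)]
    ep_loss <- 0; ep_correct <- 0
    for (start in seq(1L, n, by = config$batch_size)) {
      bidx <- ord[start:min(n, start + config$batch_size - 1L)]
      nb <- length(bidx)
      xb <- as_internal_batch(x[bidx, , , , drop = FALSE],
                              model$config$input_shape)
      fw <- model_forward(model, xb, training = TRUE)
      model$layers <- fw$layers
      probs <- fw$probs                      # K x nb
      yb <- yi[bidx]
      pt <- probs[cbind(yb, seq_len(nb))]
      loss <- mean(-log(pmax(pt, 1e-12)))
      if (!is.finite(loss))
        stop(sprintf("non-finite loss at epoch %d; last batch loss %g",
                     ep, loss))
      ep_loss <- ep_loss + loss * nb
      ep_correct <- ep_correct + sum(max.col(t(probs)) == yb)
      onehot <- matrix(0, K, nb)
      onehot[cbind(yb, seq_len(nb))] <- 1
      g <- (probs - onehot) / nb
      grads <- vector("list", length(model$layers))
      for (i in rev(seq_along(model$layers))) {
        bk <- layer_backward(model$layers[[i]], g, fw$caches[[i]])
        g <- bk$gx
        grads[i] <- list(bk$grads)     # keep NULL slots (no [[<- deletion)
      }
      if (is.null(vel)) vel <- lapply(grads, function(gr)
        if (is.null(gr)) NULL else lapply(gr, function(a) a * 0))
      lr <- config$learning_rate
      for (i in seq_along(grads)) {
        gr <- grads[[i]]
        if (is.null(gr)) next
        for (nm in names(gr)) {
          v <- config$momentum * vel[[i]][[nm]] - lr * gr[[nm]]
          vel[[i]][[nm]] <- v
          model$layers[[i]][[nm]] <- model$layers[[i]][[nm]] + v
        }
      }
    }
    hist_loss[ep] <- ep_loss / n
    hist_acc[ep] <- ep_correct / n
    if (config$verbose)
      message(sprintf("epoch %3d  loss %.4f  acc %.3f", ep,
                      hist_loss[ep], hist_acc[ep]))
  }
  model$training_history <- data.frame(epoch = seq_len(config$epochs),
                                       loss = hist_loss,
                                       accuracy = hist_acc)
  model
}

#' Export intermediate activations for embedding visualization
#'
#' Flattened eval-mode activations at a named processing stage, suitable
#' for external embedding tools (t-SNE, UMAP).
#'
#' @param model a `p3dcnn`.
#' @param x array `n x X x Y x Z`.
#' @param layer_tag one of `"raw"` (the flattened input), `"conv1"`
#'   (after the first spatial conv), `"pool1"` / `"pool2"` (block
#'   outputs, after the log), `"fc"` (hidden fully connected layer) or
#'   `"softmax"`.
#' @param batch_size samples per forward chunk.
#' @return `n x d` numeric matrix.
#' @export
export_activations <- function(model, x, layer_tag, batch_size = 32L) {
  valid <- c("raw", "conv1", "pool1", "pool2", "fc", "softmax")
  if (!layer_tag %in% valid)
    stop("unknown layer_tag '", layer_tag, "'; valid tags: ",
         paste(valid, collapse = ", "))
  if (length(dim(x)) == 3L) dim(x) <- c(1L, dim(x))
  n <- dim(x)[1]
  rows <- vector("list", 0L)
  for (start in seq(1L, n, by = batch_size)) {
    idx <- start:min(n, start + batch_size - 1L)
    xb <- as_internal_batch(x[idx, , , , drop = FALSE],
                            model$config$input_shape)
    a <- model_forward(model, xb, training = FALSE,
                       capture = layer_tag)$acts[[layer_tag]]
    nb <- length(idx)
    dim(a) <- c(length(a) / nb, nb)
    rows[[length(rows) + 1L]] <- t(a)
  }
  do.call(rbind, rows)
}
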
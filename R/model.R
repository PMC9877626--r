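# ECA attention and the attention-DenseNet classifier with its training
# and evaluation harness.

#' ECA attention coefficients
#'
#' Coefficients of the adaptive kernel-size rule for efficient channel
#' attention: from the channel-to-kernel mapping C = 2^(gamma*k - beta) the
#' kernel size is k = |log2(C)/gamma + beta/gamma| forced odd, so wider
#' feature maps get a wider 1-D interaction window.
#'
#' @param gamma channel-to-kernel slope coefficient (> 0). Default 2.
#' @param beta offset coefficient. Default 1.
#' @return An object of class `eca_config`.
#' @export
eca_config <- function(gamma = 2, beta = 1) {
  if (gamma <= 0) stop_config("`gamma` must be positive")
  structure(list(gamma = gamma, beta = beta), class = "eca_config")
}

#' Adaptive ECA kernel size
#'
#' t = |log2(C)/gamma + beta/gamma|, truncated to an integer; if the result
#' is even it is bumped up by one so the kernel is always odd (and at
#' least 1). Non-decreasing in C.
#'
#' @param C channel count (>= 1).
#' @param gamma,beta coefficients, see [eca_config()].
#' @return An odd positive integer kernel size.
#' @export
eca_kernel_size <- function(C, gamma = 2, beta = 1) {
  if (inherits(gamma, "eca_config")) {
    beta <- gamma$beta; gamma <- gamma$gamma
  }
  if (any(C < 1)) stop_config("`C` must be >= 1")
  t <- abs(log2(C) / gamma + beta / gamma)
  k <- as.integer(trunc(t))
  k[k %% 2L == 0L] <- k[k %% 2L == 0L] + 1L
  pmax(k, 1L)
}

#' Apply efficient channel attention to a feature map
#'
#' Global average pooling reduces each channel to one descriptor; a size-k
#' 1-D convolution across the channel axis (k from [eca_kernel_size()],
#' zero-padded, no channel reduction) models local cross-channel
#' interaction; a sigmoid maps the result to per-channel weights in (0,1)
#' which rescale the input multiplicatively.
#'
#' @param x feature map, a C x H x W array.
#' @param cfg an [eca_config()].
#' @param kernel optional numeric kernel of the adaptive size; defaults to
#'   a uniform (mean-filter) kernel, which is deterministic.
#' @return The reweighted C x H x W array, with the channel weights
#'   attached as attribute `"weights"`.
#' @export
eca_forward <- function(x, cfg = eca_config(), kernel = NULL) {
  if (!is.array(x) || length(dim(x)) != 3L) {
    stop_config("`x` must be a C x H x W array")
  }
  if (!all(is.finite(x))) stop_config("`x` contains non-finite values")
  C <- dim(x)[1L]
  k <- eca_kernel_size(C, cfg$gamma, cfg$beta)
  if (is.null(kernel)) kernel <- rep(1 / k, k)
  if (length(kernel) != k) {
    stop_config("`kernel` must have length %d for C = %d channels", k, C)
  }
  s <- apply(x, 1L, mean)
  p <- (k - 1L) %/% 2L
  z <- numeric(C)
  for (j in seq_len(k)) {
    off <- j - p - 1L
    src <- seq_len(C) + off
    ok <- src >= 1L & src <= C
    z[ok] <- z[ok] + kernel[j] * s[src[ok]]
  }
  w <- sigmoid(z)
  out <- sweep(x, 1L, w, `*`)
  attr(out, "weights") <- w
  out
}

#' Architecture configuration for the attention-DenseNet classifier
#'
#' @param block_sizes dense-connection counts of the four attention dense
#'   blocks. Default c(6, 12, 24, 16).
#' @param growth_rate channels added per dense layer. Default 32.
#' @param dropout dropout rate in \[0,1). Default 0.5.
#' @param input_size square input side in pixels. Default 224.
#' @param num_classes output classes. Default 12.
#' @param stem_kernel first-convolution kernel size. Default 7 (stride 2).
#' @param use_eca include the ECA module after each dense connection
#'   (FALSE gives the attention-free ablation arm).
#' @param use_stem_pool 3x3/stride-2 max pooling after the stem.
#' @param final_block_layers dense connections in the plain (attention-free)
#'   block before the decoder. Default 1.
#' @param compression transition channel compression factor. Default 0.5.
#' @param decoder_channels channels of the two 3x3 decoder deconvolutions;
#'   default 4 * growth_rate.
#' @return An object of class `eca_dense_config`.
#' @export
eca_dense_config <- function(block_sizes = c(6L, 12L, 24L, 16L),
                             growth_rate = 32L, dropout = 0.5,
                             input_size = 224L, num_classes = 12L,
                             stem_kernel = 7L, use_eca = TRUE,
                             use_stem_pool = TRUE, final_block_layers = 1L,
                             compression = 0.5, decoder_channels = NULL) {
  if (length(block_sizes) != 4L) stop_config("`block_sizes` must have length 4")
  if (any(block_sizes < 1L)) stop_config("all `block_sizes` must be >= 1")
  if (growth_rate < 1L) stop_config("`growth_rate` must be >= 1")
  if (dropout < 0 || dropout >= 1) stop_config("`dropout` must lie in [0, 1)")
  if (num_classes < 2L) stop_config("`num_classes` must be >= 2")
  if (compression <= 0 || compression > 1) stop_config("`compression` must lie in (0, 1]")
  structure(list(block_sizes = as.integer(block_sizes),
                 growth_rate = as.integer(growth_rate), dropout = dropout,
                 input_size = as.integer(input_size),
                 num_classes = as.integer(num_classes),
                 stem_kernel = as.integer(stem_kernel),
                 use_eca = isTRUE(use_eca),
                 use_stem_pool = isTRUE(use_stem_pool),
                 final_block_layers = as.integer(final_block_layers),
                 compression = compression,
                 decoder_channels = as.integer(decoder_channels %||%
                                                 (4L * growth_rate))),
            class = "eca_dense_config")
}

#' Training hyperparameters
#'
#' Defaults are the operating point used throughout: Adam with default
#' moment coefficients, learning rate 1e-4, batch size 64, 40 epochs.
#'
#' @param learning_rate Adam learning rate. Default 1e-4.
#' @param batch_size minibatch size. Default 64.
#' @param epochs training epochs. Default 40.
#' @param seed integer seed for shuffling, dropout and initialization.
#' @param optimizer only `"adam"` is provided.
#' @return An object of class `train_config`.
#' @export
train_config <- function(learning_rate = 1e-4, batch_size = 64L,
                         epochs = 40L, seed = 1L, optimizer = "adam") {
  if (learning_rate < 0) stop_config("`learning_rate` must be >= 0")
  if (batch_size < 1L) stop_config("`batch_size` must be >= 1")
  if (epochs < 1L) stop_config("`epochs` must be >= 1")
  if (!identical(optimizer, "adam")) stop_config("only the adam optimizer is provided")
  structure(list(learning_rate = learning_rate,
                 batch_size = as.integer(batch_size),
                 epochs = as.integer(epochs), seed = as.integer(seed),
                 optimizer = optimizer),
            class = "train_config")
}

#' Build the attention-DenseNet classifier
#'
#' Architecture: a 7x7 stride-2 stem convolution (BN + ReLU) with dropout
#' and 3x3/2 max pooling; four densely connected blocks with an ECA
#' reweighting after each dense connection and a BN-ReLU-3x3-conv +
#' 2x2-average-pool transition after each block; one plain dense block;
#' two 3x3 decoder deconvolutions (stride 1) that refine the final feature
#' map; dropout; global average pooling and a linear classifier.
#'
#' @param cfg an [eca_dense_config()].
#' @param eca an [eca_config()].
#' @param seed integer seed for weight initialization.
#' @return An object of class `eca_densenet`.
#' @export
build_model <- function(cfg = eca_dense_config(), eca = eca_config(),
                        seed = 1L) {
  stopifnot(inherits(cfg, "eca_dense_config"), inherits(eca, "eca_config"))
  with_seed(seed, {
    layers <- list()
    C <- 2L * cfg$growth_rate
    layers$stem <- layer_conv(3L, C, cfg$stem_kernel, stride = 2L,
                              pad = (cfg$stem_kernel - 1L) %/% 2L,
                              first = TRUE, type = "stem_conv")
    layers$stem_bn <- layer_bn(C)
    layers$stem_relu <- layer_relu()
    layers$stem_dropout <- layer_dropout(cfg$dropout)
    if (cfg$use_stem_pool) layers$stem_pool <- layer_pool("max", 3L, 2L, pad = 1L)
    for (b in seq_len(4L)) {
      blk <- layer_dense_block(C, cfg$block_sizes[b], cfg$growth_rate,
                               use_eca = cfg$use_eca,
                               eca_gamma = eca$gamma, eca_beta = eca$beta)
      layers[[paste0("block", b)]] <- blk
      C <- blk$c_out
      tr <- layer_transition(C, cfg$compression)
      layers[[paste0("transition", b)]] <- tr
      C <- tr$c_out
    }
    fin <- layer_dense_block(C, cfg$final_block_layers, cfg$growth_rate,
                             use_eca = FALSE)
    layers$final_block <- fin
    C <- fin$c_out
    layers$deconv1 <- layer_conv(C, cfg$decoder_channels, 3L, type = "deconv")
    layers$deconv1_relu <- layer_relu()
    layers$deconv2 <- layer_conv(cfg$decoder_channels, cfg$decoder_channels,
                                 3L, type = "deconv")
    layers$deconv2_relu <- layer_relu()
    layers$head_dropout <- layer_dropout(cfg$dropout)
    layers$gap <- layer_gap()
    layers$classifier <- layer_linear(cfg$decoder_channels, cfg$num_classes)
    structure(list(layers = layers, config = cfg, eca = eca,
                   n_updates = 0L),
              class = "eca_densenet")
  })
}

#' Forward pass
#'
#' @param model an `eca_densenet`.
#' @param x input images: an H x W x 3 array or an H x W x 3 x N batch.
#' @param train training mode (batch statistics, dropout active).
#' @return An N x num_classes logits matrix.
#' @export
model_forward <- function(model, x, train = FALSE) {
  if (length(dim(x)) == 3L) dim(x) <- c(dim(x), 1L)
  for (ly in model$layers) x <- ly$forward(x, train)
  x
}

model_backward <- function(model, dlogits) {
  d <- dlogits
  for (ly in rev(model$layers)) {
    d <- ly$backward(d)
    if (is.null(d)) break
  }
  invisible(NULL)
}

#' Flattened sequence of primitive layer types
#'
#' Useful for inspecting the layer graph, e.g. to confirm that the
#' attention-free ablation differs from the full model only by the absence
#' of `"eca"` nodes.
#'
#' @param model an `eca_densenet`.
#' @return A character vector of layer type names in execution order.
#' @export
model_layer_types <- function(model) {
  walk <- function(ly) {
    if (ly$type %in% c("eca_dense_block", "dense_block")) {
      out <- character()
      for (i in seq_len(ly$n_layers)) {
        out <- c(out, "bn", "relu", "conv", if (ly$use_eca) "eca")
      }
      out
    } else if (ly$type == "transition") {
      c("bn", "relu", "conv", "avgpool")
    } else {
      ly$type
    }
  }
  unlist(lapply(model$layers, walk), use.names = FALSE)
}

#' Predict class labels
#' @param object an `eca_densenet`.
#' @param x image array or batch (H x W x 3 \[x N\]).
#' @param type `"class"` for integer labels, `"prob"` for softmax rows.
#' @param batch_size forward-pass batch size.
#' @param ... unused.
#' @return Integer labels or an N x K probability matrix.
#' @export
predict.eca_densenet <- function(object, x, type = c("class", "prob"),
                                 batch_size = 16L, ...) {
  type <- match.arg(type)
  if (length(dim(x)) == 3L) dim(x) <- c(dim(x), 1L)
  n <- dim(x)[4L]
  out <- NULL
  for (start in seq(1L, n, by = batch_size)) {
    ix <- start:min(start + batch_size - 1L, n)
    logits <- model_forward(object, x[, , , ix, drop = FALSE], train = FALSE)
    out <- rbind(out, logits)
  }
  if (type == "class") return(max.col(out, ties.method = "first"))
  ez <- exp(out - apply(out, 1L, max))
  ez / rowSums(ez)
}

#' Train the classifier
#'
#' Minibatch cross-entropy training with Adam. Shuffling, dropout and
#' initialization are all governed by `tc$seed`, so a run is exactly
#' reproducible. When validation data are supplied, the weights achieving
#' the best validation accuracy are restored at the end.
#'
#' @param model an `eca_densenet` (modified in place and returned).
#' @param data training data: `list(x = H x W x 3 x N array, y = integer
#'   labels in 1..num_classes)`.
#' @param tc a [train_config()].
#' @param valid optional validation data in the same format.
#' @param stop_at_train_acc optional early-stop threshold on training
#'   accuracy in \[0,1\].
#' @param verbose print one line per epoch.
#' @return A list with `model` and `history` (data.frame: epoch, loss,
#'   train_acc, valid_acc).
#' @export
train_model <- function(model, data, tc = train_config(), valid = NULL,
                        stop_at_train_acc = NULL, verbose = FALSE) {
  stopifnot(inherits(model, "eca_densenet"), inherits(tc, "train_config"))
  if (is.null(data$x) || is.null(data$y)) stop_config("`data` must have `x` and `y`")
  n <- dim(data$x)[4L]
  if (n == 0L || length(data$y) != n) stop_config("empty or inconsistent training split")
  y <- as.integer(data$y)
  history <- NULL
  best_acc <- -Inf
  best_par <- NULL
  t_step <- model$n_updates
  with_seed(tc$seed, {
    for (epoch in seq_len(tc$epochs)) {
      ord <- sample.int(n)
      losses <- c(); correct <- 0L
      for (start in seq(1L, n, by = tc$batch_size)) {
        ix <- ord[start:min(start + tc$batch_size - 1L, n)]
        xb <- data$x[, , , ix, drop = FALSE]
        yb <- y[ix]
        logits <- model_forward(model, xb, train = TRUE)
        sx <- softmax_xent(logits, yb)
        losses <- c(losses, sx$loss)
        correct <- correct + sum(max.col(logits, ties.method = "first") == yb)
        model_backward(model, sx$dlogits)
        t_step <- t_step + 1L
        adam_step(model$layers, tc$learning_rate, t_step)
      }
      train_acc <- correct / n
      valid_acc <- NA_real_
      if (!is.null(valid)) {
        valid_acc <- mean(predict(model, valid$x) == as.integer(valid$y))
        if (valid_acc > best_acc) {
          best_acc <- valid_acc
          best_par <- save_weights(model)
        }
      }
      history <- rbind(history,
                       data.frame(epoch = epoch, loss = mean(losses),
                                  train_acc = train_acc, valid_acc = valid_acc))
      if (verbose) {
        message(sprintf("epoch %3d  loss %.4f  train %.3f  valid %s",
                        epoch, mean(losses), train_acc,
                        ifelse(is.na(valid_acc), "-", sprintf("%.3f", valid_acc))))
      }
      if (!is.null(stop_at_train_acc) && train_acc >= stop_at_train_acc) break
    }
  })
  model$n_updates <- t_step
  if (!is.null(best_par)) load_weights(model, best_par)
  list(model = model, history = history)
}

#' Extract all trainable weights
#' @param model an `eca_densenet`.
#' @return A list of parameter lists, one per parameterized layer.
#' @export
save_weights <- function(model) {
  lapply(flatten_layers(model$layers), function(ly) ly$par)
}

#' Restore weights extracted with [save_weights()]
#' @param model an `eca_densenet`.
#' @param weights value of [save_weights()] for an identically built model.
#' @return The model, invisibly.
#' @export
load_weights <- function(model, weights) {
  ls <- flatten_layers(model$layers)
  if (length(ls) != length(weights)) stop_config("weight list does not match the model")
  for (i in seq_along(ls)) ls[[i]]$par <- weights[[i]]
  invisible(model)
}

#' Evaluate a classifier
#'
#' @param model an `eca_densenet`.
#' @param data `list(x, y)` evaluation data.
#' @param classes optional class names for labelling the confusion matrix.
#' @return A list with `accuracy`, `per_class` (named accuracy vector),
#'   `confusion` (matrix, rows = true class), `predictions` and
#'   `mean_inference_ms` (mean per-image forward time, informational).
#' @export
evaluate_model <- function(model, data, classes = NULL) {
  y <- as.integer(data$y)
  n <- length(y)
  t0 <- proc.time()[["elapsed"]]
  pred <- predict(model, data$x)
  dt <- proc.time()[["elapsed"]] - t0
  k <- model$config$num_classes
  classes <- classes %||% sprintf("class_%02d", seq_len(k))
  cm <- matrix(0L, k, k, dimnames = list(true = classes, predicted = classes))
  for (i in seq_len(n)) cm[y[i], pred[i]] <- cm[y[i], pred[i]] + 1L
  per_class <- diag(cm) / pmax(rowSums(cm), 1L)
  list(accuracy = mean(pred == y), per_class = per_class, confusion = cm,
       predictions = pred, mean_inference_ms = 1000 * dt / n)
}
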
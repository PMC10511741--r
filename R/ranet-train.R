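# Bridge between declarative layer tables and the compiled training engine.

# Engine layer list from a ranet_spec: conv -> relu -> bn -> pool per block,
# then gap and dense layers with relu between (softmax handled by the loss).
spec_to_engine_layers <- function(spec) {
  layers <- list()
  for (i in seq_len(nrow(spec))) {
    kind <- spec$kind[i]
    if (kind == "conv2d") {
      k <- spec$kernel[i]
      pad <- if (!is.na(spec$padding[i]) && spec$padding[i] == "same")
        (k - 1) %/% 2 else 0L
      layers <- c(layers, list(list(type = "conv", k = as.integer(k),
                                    out = as.integer(spec$out[i]),
                                    pad = as.integer(pad))))
      if (spec$activation[i] == "ReLU")
        layers <- c(layers, list(list(type = "relu")))
    } else if (kind == "batchnorm") {
      layers <- c(layers, list(list(type = "bn")))
    } else if (kind == "maxpool") {
      layers <- c(layers, list(list(type = "pool")))
    } else if (kind == "global_average_pool") {
      layers <- c(layers, list(list(type = "gap")))
    } else if (kind == "dense") {
      layers <- c(layers, list(list(type = "dense",
                                    out = as.integer(spec$out[i]))))
      if (spec$activation[i] == "ReLU")
        layers <- c(layers, list(list(type = "relu")))
    }
  }
  layers
}

# 1-based engine-layer index of the output requested by `layer_name`
# ("FC_3" etc., post-ReLU where the layer has one).
engine_layer_index <- function(spec, layer_name) {
  hit <- which(startsWith(spec$name, layer_name))
  if (length(hit) != 1)
    stop_input("unknown layer: ", layer_name)
  idx <- 0L
  for (i in seq_len(nrow(spec))) {
    kind <- spec$kind[i]
    n_engine <- switch(kind, input = 0L,
                       conv2d = if (spec$activation[i] == "ReLU") 2L else 1L,
                       batchnorm = 1L, maxpool = 1L, global_average_pool = 1L,
                       dense = if (spec$activation[i] == "ReLU") 2L else 1L)
    idx <- idx + n_engine
    if (i == hit) return(idx)
  }
  stop_input("unknown layer: ", layer_name)
}

#' Training configuration for the CNN models
#'
#' Defaults follow the RANet training recipe: stochastic gradient descent
#' with learning rate 0.01, batch size 16, categorical cross-entropy, 50
#' epochs, checkpointing on validation accuracy.  The QNN head uses its own
#' recipe (see [train_qnn()]).
#'
#' @param optimizer `"sgd"` or `"adam"`.
#' @param learning_rate Positive learning rate.
#' @param batch_size Minibatch size (>= 1).
#' @param epochs Number of epochs.
#' @param momentum SGD momentum (default 0).
#' @param loss `"categorical_cross_entropy"` or `"binary_cross_entropy"`.
#' @param bn_momentum,bn_eps Batch-normalization moving-average momentum and
#'   variance epsilon.
#' @param seed Integer seed controlling weight init and shuffling.
#' @return Object of class `train_config`.
#' @export
train_config <- function(optimizer = "sgd", learning_rate = 0.01,
                         batch_size = 16, epochs = 50, momentum = 0,
                         loss = "categorical_cross_entropy",
                         bn_momentum = 0.99, bn_eps = 1e-3, seed = 1L) {
  if (learning_rate <= 0) stop_input("learning_rate must be positive")
  if (batch_size < 1) stop_input("batch_size must be >= 1")
  if (!optimizer %in% c("sgd", "adam")) stop_input("unknown optimizer")
  structure(list(optimizer = optimizer, learning_rate = learning_rate,
                 batch_size = as.integer(batch_size),
                 epochs = as.integer(epochs), momentum = momentum,
                 loss = loss, bn_momentum = bn_momentum, bn_eps = bn_eps,
                 seed = as.integer(seed)),
            class = "train_config")
}

one_hot <- function(y, levels = thermo_labels) {
  y <- factor(y, levels = levels)
  m <- matrix(0, length(y), length(levels))
  m[cbind(seq_along(y), as.integer(y))] <- 1
  m
}

check_images <- function(x, name = "x") {
  if (length(dim(x)) != 4)
    stop_input(name, " must be an H x W x C x n array")
  if (min(x) < -1e-8 || max(x) > 1 + 1e-8)
    stop_input(name, " values must lie in [0, 1]")
}

#' Train the RANet classifier
#'
#' Builds the RANet architecture for the given input size (dropping trailing
#' conv blocks when the input is too small for all six), trains it with the
#' configured optimizer, and keeps the weights of the epoch with the best
#' validation accuracy (checkpointing).
#'
#' @param x_train H x W x 3 x n array of images in \[0, 1\].
#' @param y_train Labels (`"normal"` / `"RA"`), length n.
#' @param x_val,y_val Optional validation set (same formats).
#' @param config A [train_config()].
#' @return Object of class `ranet` with the architecture spec, checkpointed
#'   and final weights, and a per-epoch history data frame.
#' @export
train_ranet <- function(x_train, y_train, x_val = NULL, y_val = NULL,
                        config = train_config()) {
  check_images(x_train, "x_train")
  n <- dim(x_train)[4]
  if (n == 0) stop_input("empty training set")
  if (length(y_train) != n) stop_input("label count does not match image count")
  spec <- build_ranet_spec(input_size = dim(x_train)[1])
  layers <- spec_to_engine_layers(spec)
  yt <- one_hot(y_train)
  if (!is.null(x_val)) {
    check_images(x_val, "x_val")
    yv <- one_hot(y_val)
  } else {
    x_val <- numeric(0); yv <- matrix(0, 0, 2)
  }
  opts <- list(loss = "cce", optimizer = config$optimizer,
               lr = config$learning_rate, momentum = config$momentum,
               batch_size = config$batch_size, epochs = config$epochs,
               bn_momentum = config$bn_momentum, bn_eps = config$bn_eps,
               seed = config$seed)
  fit <- cnn_train_cpp(layers, x_train, yt, x_val, yv, opts)
  history <- as.data.frame(fit$history)
  names(history) <- c("train_loss", "train_accuracy", "val_loss", "val_accuracy")
  history$epoch <- seq_len(nrow(history))
  structure(list(spec = spec, engine_layers = layers,
                 weights = fit$best_weights, final_weights = fit$weights,
                 best_epoch = fit$best_epoch,
                 best_val_accuracy = fit$best_val_accuracy,
                 history = history, config = config,
                 classes = thermo_labels, loss = "cce"),
            class = "ranet")
}

#' @export
print.ranet <- function(x, ...) {
  acct <- count_parameters(x$spec)
  cat(sprintf("RANet classifier (input %s; %s parameters)\n",
              paste(attr(x$spec, "input_shape"), collapse = " x "),
              format(acct$total, big.mark = ",")))
  if (!is.null(x$best_epoch) && !is.na(x$best_val_accuracy))
    cat(sprintf("  checkpoint: epoch %d, val accuracy %.4f\n",
                x$best_epoch, x$best_val_accuracy))
  invisible(x)
}

#' @export
summary.ranet <- function(object, ...) {
  print(object)
  print(count_parameters(object$spec))
  cat("Last epochs of training history:\n")
  print(utils::tail(object$history, 5), row.names = FALSE)
  invisible(object)
}

#' Class-probability predictions from a trained RANet
#'
#' @param object A `ranet` model.
#' @param x H x W x 3 x n image array.
#' @param type `"prob"` for the n x 2 probability matrix (rows sum to 1) or
#'   `"class"` for label predictions.
#' @param ... Unused.
#' @return Probability matrix or factor of labels.
#' @export
predict.ranet <- function(object, x, type = c("prob", "class"), ...) {
  type <- match.arg(type)
  check_images(x)
  p <- cnn_forward_cpp(object$engine_layers, object$weights, x, object$loss,
                       object$config$bn_eps, 0L)
  colnames(p) <- object$classes
  if (type == "class")
    return(factor(object$classes[max.col(p, ties.method = "first")],
                  levels = object$classes))
  p
}

#' @export
plot.ranet <- function(x, ...) {
  h <- x$history
  op <- graphics::par(mfrow = c(1, 2)); on.exit(graphics::par(op))
  plot(h$epoch, h$train_accuracy, type = "l", ylim = c(0, 1),
       xlab = "epoch", ylab = "accuracy", main = "Accuracy")
  graphics::lines(h$epoch, h$val_accuracy, lty = 2)
  graphics::legend("bottomright", c("train", "val"), lty = 1:2, bty = "n")
  plot(h$epoch, h$train_loss, type = "l", xlab = "epoch", ylab = "loss",
       main = "Loss")
  graphics::lines(h$epoch, h$val_loss, lty = 2)
  invisible(x)
}

#' Extract deep features from a trained RANet
#'
#' Returns the post-ReLU activations of a named dense layer; the default
#' `"FC_3"` yields the 32-dimensional deep-feature representation used by the
#' hybrid machine-learning pipeline.
#'
#' @param model A trained `ranet`.
#' @param x H x W x 3 x n image array.
#' @param layer_name Dense layer name (`"FC_1"`, `"FC_2"`, `"FC_3"`).
#' @return n x d matrix of activations with column names `F1..Fd`.
#' @export
extract_features <- function(model, x, layer_name = "FC_3") {
  check_images(x)
  idx <- engine_layer_index(model$spec, layer_name)
  f <- cnn_forward_cpp(model$engine_layers, model$weights, x, model$loss,
                       model$config$bn_eps, as.integer(idx))
  colnames(f) <- paste0("F", seq_len(ncol(f)))
  f
}
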
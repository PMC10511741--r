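#' Declarative RANet architecture specification
#'
#' RANet is a compact CNN for 256 x 256 x 3 thermograms: six blocks of
#' (conv -> ReLU -> batch norm -> 2x2 max pool) with conv filter counts
#' 8, 16, 32, 64, 128, 256 and alternating kernels 1x1 / 3x3 (stride 1),
#' followed by global average pooling and dense layers of 128, 64, 32 and 2
#' units, the last with SoftMax.  1x1 convolutions preserve spatial size
#' ("same" padding is a no-op at kernel 1) while 3x3 convolutions use no
#' padding — the unique assignment under which the spatial sizes follow
#' 256 -> 126 -> 63 -> 29 -> 14 -> 5 -> 2 before pooling to the head.
#'
#' Smaller inputs are supported by dropping trailing conv blocks that can no
#' longer propagate a positive spatial size (e.g. a 64 x 64 input keeps five
#' of the six blocks); the dense head is unchanged except for its input width.
#'
#' @param input_size Spatial side of the (square) input, default 256.
#' @param blocks Maximum number of conv blocks to keep (default 6).
#' @return An object of class `ranet_spec`: a data frame of layers with
#'   propagated output shapes, plus attributes `input_shape`.
#' @export
build_ranet_spec <- function(input_size = 256, blocks = 6) {
  filters <- c(8, 16, 32, 64, 128, 256)[seq_len(blocks)]
  kernels <- c(1, 3, 1, 3, 1, 3)[seq_len(blocks)]
  rows <- list(data.frame(name = "Input", kind = "input", out = 3,
                          kernel = NA, stride = NA, padding = NA,
                          activation = "", stringsAsFactors = FALSE))
  h <- input_size
  kept <- 0L
  for (b in seq_along(filters)) {
    k <- kernels[b]
    pad <- if (k == 1) "same" else "valid"
    h_conv <- if (pad == "same") h else h - k + 1
    h_pool <- floor(h_conv / 2)
    if (h_conv < 1 || h_pool < 1) break
    kept <- kept + 1L
    rows[[length(rows) + 1]] <- data.frame(
      name = sprintf("Conv2D_%d", b), kind = "conv2d", out = filters[b],
      kernel = k, stride = 1, padding = pad, activation = "ReLU")
    rows[[length(rows) + 1]] <- data.frame(
      name = sprintf("BN_%d", b), kind = "batchnorm", out = filters[b],
      kernel = NA, stride = NA, padding = NA, activation = "")
    rows[[length(rows) + 1]] <- data.frame(
      name = sprintf("Maxpooling_%d", b), kind = "maxpool", out = filters[b],
      kernel = 2, stride = 2, padding = NA, activation = "")
    h <- h_pool
  }
  rows[[length(rows) + 1]] <- data.frame(
    name = "Global Average Pooling", kind = "global_average_pool",
    out = filters[kept], kernel = NA, stride = NA, padding = NA,
    activation = "")
  dense_units <- c(128, 64, 32, 2)
  dense_names <- c("FC_1", "FC_2", "FC_3", "Classification layer (FC_4)")
  dense_act <- c("ReLU", "ReLU", "ReLU", "SoftMax")
  for (i in 1:4) {
    rows[[length(rows) + 1]] <- data.frame(
      name = dense_names[i], kind = "dense", out = dense_units[i],
      kernel = NA, stride = NA, padding = NA, activation = dense_act[i])
  }
  spec <- do.call(rbind, rows)
  rownames(spec) <- NULL
  spec <- propagate_shapes(spec, input_size)
  structure(spec, class = c("ranet_spec", "data.frame"),
            input_shape = c(input_size, input_size, 3))
}

# Annotate a layer table with output shapes (out_h, out_w, out_c) by replaying
# the shape rules: "same" preserves spatial size, "valid" subtracts k - 1,
# 2x2 max pooling floors the halved size.
propagate_shapes <- function(spec, input_size) {
  h <- input_size; c_in <- 3
  spec$out_h <- spec$out_w <- spec$out_c <- NA_integer_
  spec$params <- 0
  for (i in seq_len(nrow(spec))) {
    kind <- spec$kind[i]
    if (kind == "input") {
      spec$out_c[i] <- c_in
    } else if (kind == "conv2d") {
      k <- spec$kernel[i]
      if (!is.na(spec$padding[i]) && spec$padding[i] == "valid") h <- h - k + 1
      if (h < 1) stop_input("spatial size collapsed at layer ", spec$name[i])
      spec$params[i] <- k * k * c_in * spec$out[i] + spec$out[i]
      c_in <- spec$out[i]
    } else if (kind == "batchnorm") {
      spec$params[i] <- 4 * c_in
    } else if (kind == "maxpool") {
      h <- floor(h / spec$stride[i])
    } else if (kind == "global_average_pool") {
      h <- NA_integer_
    } else if (kind == "dense") {
      spec$params[i] <- c_in * spec$out[i] + spec$out[i]
      c_in <- spec$out[i]
    }
    spec$out_h[i] <- spec$out_w[i] <- if (kind == "dense" ||
                                          kind == "global_average_pool") NA_integer_ else h
    spec$out_c[i] <- if (kind %in% c("dense", "global_average_pool")) spec$out[i] else c_in
  }
  spec
}

#' Parameter accounting for an architecture specification
#'
#' Counts parameters per layer independently of any training framework:
#' conv2d contributes `kh*kw*c_in*c_out + c_out` (weights + bias), dense
#' `n_in*n_out + n_out`, batch normalization `4*channels` of which
#' `2*channels` (the moving mean/variance) are non-trainable; pooling and
#' global average pooling contribute nothing.
#'
#' @param spec A `ranet_spec` (or any layer table produced by
#'   [build_ranet_spec()]).
#' @return Object of class `parameter_account` with `per_layer` (data frame of
#'   name, count), `total`, `trainable`, `non_trainable`.
#' @export
count_parameters <- function(spec) {
  if (is.null(spec) || nrow(spec) == 0) {
    return(structure(list(per_layer = data.frame(name = character(),
                                                 params = numeric()),
                          total = 0, trainable = 0, non_trainable = 0),
                     class = "parameter_account"))
  }
  if (!all(c("kind", "params") %in% names(spec)))
    stop_input("malformed architecture spec")
  keep <- spec$params > 0
  per <- data.frame(name = spec$name[keep], params = spec$params[keep],
                    stringsAsFactors = FALSE)
  non_trainable <- sum(2 * spec$out[spec$kind == "batchnorm"])
  total <- sum(spec$params)
  structure(list(per_layer = per, total = total,
                 trainable = total - non_trainable,
                 non_trainable = non_trainable),
            class = "parameter_account")
}

#' @export
print.parameter_account <- function(x, ...) {
  cat("Parameter account\n")
  if (nrow(x$per_layer)) {
    w <- max(nchar(x$per_layer$name))
    for (i in seq_len(nrow(x$per_layer)))
      cat(sprintf("  %-*s %12s\n", w, x$per_layer$name[i],
                  format(x$per_layer$params[i], big.mark = ",")))
  }
  cat(sprintf("  Total parameters:         %s\n", format(x$total, big.mark = ",")))
  cat(sprintf("  Trainable parameters:     %s\n", format(x$trainable, big.mark = ",")))
  cat(sprintf("  Non-trainable parameters: %s\n", format(x$non_trainable, big.mark = ",")))
  invisible(x)
}

#' @export
print.ranet_spec <- function(x, ...) {
  cat(sprintf("RANet architecture (input %s)\n",
              paste(attr(x, "input_shape"), collapse = " x ")))
  df <- as.data.frame(x)
  size <- ifelse(is.na(df$out_h), as.character(df$out_c),
                 sprintf("%d x %d x %d", df$out_h, df$out_w, df$out_c))
  print(data.frame(Layer = df$name, Size = size,
                   Kernel = ifelse(is.na(df$kernel), "-",
                                   sprintf("%d x %d", df$kernel, df$kernel)),
                   Stride = ifelse(is.na(df$stride), "-", df$stride),
                   Activation = ifelse(df$activation == "", "-", df$activation),
                   Params = df$params),
        row.names = FALSE)
  invisible(x)
}
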
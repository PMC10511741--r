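# Four-qubit statevector simulation and the quanvolutional image transform.
#
# States are vectors of 16 complex amplitudes in little-endian basis order:
# basis index b = sum_q bit_q * 2^q, so qubit 0 is the least significant bit.

N_QUBITS <- 4L
DIM <- 16L

#' Construct a gate operation
#'
#' @param name One of `"RX"`, `"RY"`, `"RZ"`, `"X"`, `"H"`, `"CNOT"`.
#' @param qubits Qubit index (0..3), or `c(control, target)` for CNOT.
#' @param angle Rotation angle in radians (rotation gates only).
#' @return Object of class `gate_op`.
#' @export
gate_op <- function(name, qubits, angle = NULL) {
  name <- toupper(name)
  rot <- name %in% c("RX", "RY", "RZ")
  if (!name %in% c("RX", "RY", "RZ", "X", "H", "CNOT"))
    stop_input("unknown gate: ", name)
  qubits <- as.integer(qubits)
  if (any(qubits < 0 | qubits >= N_QUBITS)) stop_input("qubit index out of range")
  if (name == "CNOT") {
    if (length(qubits) != 2 || qubits[1] == qubits[2])
      stop_input("CNOT needs two distinct qubits")
  } else if (length(qubits) != 1) stop_input(name, " acts on one qubit")
  if (rot && is.null(angle)) stop_input(name, " needs an angle")
  if (!rot && !is.null(angle)) stop_input(name, " takes no angle")
  structure(list(name = name, qubits = qubits, angle = angle),
            class = "gate_op")
}

# 2x2 matrix of a single-qubit gate.
gate_matrix_1q <- function(gate) {
  th <- gate$angle
  switch(gate$name,
    RX = matrix(c(cos(th / 2), -1i * sin(th / 2),
                  -1i * sin(th / 2), cos(th / 2)), 2, 2),
    RY = matrix(c(cos(th / 2), sin(th / 2),
                  -sin(th / 2), cos(th / 2)), 2, 2),
    RZ = diag(c(exp(-1i * th / 2), exp(1i * th / 2))),
    X = matrix(c(0, 1, 1, 0), 2, 2),
    H = matrix(c(1, 1, 1, -1), 2, 2) / sqrt(2))
}

#' The ground state |0000>
#'
#' @return Complex vector of 16 amplitudes.
#' @export
ground_state <- function() {
  s <- complex(DIM)
  s[1] <- 1 + 0i
  s
}

#' Apply one gate to a statevector
#'
#' Single-qubit gates contract the 2x2 matrix over the indexed qubit;
#' CNOT permutes amplitudes where the control bit is set.  The norm is
#' preserved (gates are unitary).
#'
#' @param state Complex vector of 16 amplitudes (little-endian).
#' @param gate A [gate_op()].
#' @return The new statevector.
#' @export
apply_gate <- function(state, gate) {
  if (length(state) != DIM) stop_input("state must have 16 amplitudes")
  b <- 0:(DIM - 1)
  if (gate$name == "CNOT") {
    ctl <- gate$qubits[1]; tgt <- gate$qubits[2]
    src <- ifelse(bitwAnd(b, bitwShiftL(1L, ctl)) > 0,
                  bitwXor(b, bitwShiftL(1L, tgt)), b)
    return(state[src + 1L])
  }
  q <- gate$qubits[1]
  m <- gate_matrix_1q(gate)
  i0 <- which(bitwAnd(b, bitwShiftL(1L, q)) == 0)        # 1-based positions
  i1 <- i0 + 2^q
  s0 <- state[i0]; s1 <- state[i1]
  out <- state
  out[i0] <- m[1, 1] * s0 + m[1, 2] * s1
  out[i1] <- m[2, 1] * s0 + m[2, 2] * s1
  out
}

#' Pauli-Z expectation of one qubit
#'
#' Returns `sum_b |a_b|^2 * (+1 if bit_q(b) = 0 else -1)`, a real number in
#' \[-1, 1\].
#'
#' @param state Complex statevector of 16 amplitudes.
#' @param qubit Qubit index in 0..3.
#' @return Real expectation value.
#' @export
expectation_z <- function(state, qubit) {
  if (qubit < 0 || qubit >= N_QUBITS) stop_input("qubit index out of range")
  b <- 0:(DIM - 1)
  sign <- 1 - 2 * (bitwAnd(b, bitwShiftL(1L, as.integer(qubit))) > 0)
  sum(Mod(state)^2 * sign)
}

#' Build a seeded random quanvolution circuit
#'
#' Each layer is one uniformly drawn RY rotation per qubit (angles in
#' `[0, 2*pi)`) followed by a CNOT ring 0->1, 1->2, 2->3, 3->0.  The circuit
#' is a deterministic function of the seed.
#'
#' @param n_layers Number of random layers (>= 0; 0 gives the identity).
#' @param seed Integer seed.
#' @return Object of class `circuit_spec` with fields `n_qubits`,
#'   `random_layers` (flat list of [gate_op()]s), `n_layers`, `seed`.
#' @export
build_random_circuit <- function(n_layers = 1, seed = 1L) {
  if (n_layers < 0) stop_input("n_layers must be >= 0")
  gates <- list()
  if (n_layers > 0) {
    angles <- withr::with_seed(seed, runif(n_layers * N_QUBITS, 0, 2 * pi))
    k <- 0L
    for (l in seq_len(n_layers)) {
      for (q in 0:(N_QUBITS - 1)) {
        k <- k + 1L
        gates[[length(gates) + 1]] <- gate_op("RY", q, angles[k])
      }
      for (q in 0:(N_QUBITS - 1))
        gates[[length(gates) + 1]] <- gate_op("CNOT", c(q, (q + 1L) %% N_QUBITS))
    }
  }
  structure(list(n_qubits = N_QUBITS, random_layers = gates,
                 n_layers = as.integer(n_layers), seed = as.integer(seed)),
            class = "circuit_spec")
}

#' @export
print.circuit_spec <- function(x, ...) {
  cat(sprintf("<circuit_spec> %d qubits, %d random layer(s), %d gate(s), seed %d\n",
              x$n_qubits, x$n_layers, length(x$random_layers), x$seed))
  invisible(x)
}

#' Densify a gate sequence into its 16 x 16 unitary
#'
#' Built independently of [apply_gate()] (Kronecker products / explicit
#' permutation matrices), so the two routes can be checked against each other.
#'
#' @param gates List of [gate_op()]s (or a `circuit_spec`, whose
#'   `random_layers` are used).
#' @return Complex 16 x 16 matrix.
#' @export
circuit_unitary <- function(gates) {
  if (inherits(gates, "circuit_spec")) gates <- gates$random_layers
  U <- diag(DIM) + 0i
  for (g in gates) {
    if (g$name == "CNOT") {
      ctl <- g$qubits[1]; tgt <- g$qubits[2]
      G <- matrix(0 + 0i, DIM, DIM)
      for (b in 0:(DIM - 1)) {
        b2 <- if (bitwAnd(b, bitwShiftL(1L, ctl)) > 0)
          bitwXor(b, bitwShiftL(1L, tgt)) else b
        G[b2 + 1, b + 1] <- 1
      }
    } else {
      q <- g$qubits[1]
      m <- gate_matrix_1q(g)
      G <- diag(1) + 0i
      # little-endian: qubit 0 is the fastest-varying kron factor (rightmost)
      for (qq in (N_QUBITS - 1):0) {
        G <- G %x% (if (qq == q) m else diag(2) + 0i)
      }
    }
    U <- G %*% U
  }
  U
}

# Encoded RY(pi * x) product state for a 2x2 patch, vectorized over patches.
# xs: 4 x N matrix of pixel values; returns 16 x N complex... all real here
# (RY on |0> keeps amplitudes real), so a numeric matrix is returned.
encode_patches <- function(xs) {
  cth <- cos(pi * xs / 2)   # rows: qubit 0..3
  sth <- sin(pi * xs / 2)
  b <- 0:(DIM - 1)
  A <- matrix(1, DIM, ncol(xs))
  for (q in 0:(N_QUBITS - 1)) {
    bit <- bitwAnd(b, bitwShiftL(1L, q)) > 0
    A[bit, ] <- A[bit, , drop = FALSE] *
      matrix(sth[q + 1, ], sum(bit), ncol(xs), byrow = TRUE)
    A[!bit, ] <- A[!bit, , drop = FALSE] *
      matrix(cth[q + 1, ], sum(!bit), ncol(xs), byrow = TRUE)
  }
  A
}

#' Quanvolve one 2x2 patch
#'
#' Encodes the four pixel values (row-major order) as RY(pi*x) rotations on
#' qubits 0..3 from |0000>, applies the circuit's random layers gate by gate,
#' and returns the four per-qubit Pauli-Z expectations.
#'
#' @param patch Numeric vector of 4 pixel values in \[0, 1\] (row-major), or
#'   a 2 x 2 matrix.
#' @param circuit A `circuit_spec`.
#' @return Numeric vector of 4 channel values in \[-1, 1\].
#' @export
quanv_patch <- function(patch, circuit) {
  if (is.matrix(patch)) patch <- c(t(patch))  # row-major flattening
  if (length(patch) != 4) stop_input("patch must contain 4 pixels")
  if (any(patch < 0 | patch > 1)) stop_input("patch values must lie in [0, 1]")
  state <- ground_state()
  for (q in 0:3) state <- apply_gate(state, gate_op("RY", q, pi * patch[q + 1]))
  for (g in circuit$random_layers) state <- apply_gate(state, g)
  vapply(0:3, function(q) expectation_z(state, q), numeric(1))
}

#' Quanvolutional transform of an image
#'
#' Tiles each band independently into non-overlapping 2x2 patches (stride 2;
#' odd trailing rows/columns are dropped) and emits the four per-qubit Z
#' expectations per patch, shrinking the image by a factor of 2 and expanding
#' each band into 4 quantum channels (a 3-band image gives 12 channels,
#' ordered band-major then qubit).
#'
#' @param image H x W (x bands) array with values in \[0, 1\].
#' @param circuit A `circuit_spec` (shared across all four channels).
#' @return `floor(H/2) x floor(W/2) x (bands*4)` array with values in
#'   \[-1, 1\].
#' @export
quanvolve_image <- function(image, circuit) {
  d <- dim(image)
  if (is.null(d) || d[1] < 2 || d[2] < 2)
    stop_input("image must be at least 2 x 2")
  if (min(image) < 0 || max(image) > 1)
    stop_input("image values must lie in [0, 1]")
  if (length(d) == 2) image <- array(image, c(d, 1))
  bands <- dim(image)[3]
  H2 <- d[1] %/% 2; W2 <- d[2] %/% 2
  U <- circuit_unitary(circuit)
  ri <- seq_len(H2) * 2 - 1; ci <- seq_len(W2) * 2 - 1
  b <- 0:(DIM - 1)
  signs <- sapply(0:3, function(q) 1 - 2 * (bitwAnd(b, bitwShiftL(1L, q)) > 0))
  out <- array(0, c(H2, W2, bands * 4))
  for (bd in seq_len(bands)) {
    sl <- image[, , bd]
    # row-major patch order: (r,c), (r,c+1), (r+1,c), (r+1,c+1) -> qubits 0..3
    xs <- rbind(c(sl[ri, ci]), c(sl[ri, ci + 1]),
                c(sl[ri + 1, ci]), c(sl[ri + 1, ci + 1]))
    S <- U %*% encode_patches(xs)
    P <- Mod(S)^2
    for (q in 0:3)
      out[, , (bd - 1) * 4 + q + 1] <- matrix(colSums(P * signs[, q + 1]), H2, W2)
  }
  out
}

#' Train the QNN classical head
#'
#' The classifier that consumes quanvolutional feature maps: four 3x3
#' convolution blocks of 32, 16, 16 and 8 filters (each followed by 2x2 max
#' pooling), a 128-unit ReLU dense layer and a single sigmoid output, trained
#' with Adam (learning rate 0.001), binary cross-entropy, batch size 64 and
#' 30 epochs by default.
#'
#' @param x_train H x W x C x n array of quanvolutional feature maps (values
#'   are shifted from \[-1, 1\] to \[0, 1\] internally).
#' @param y_train Binary labels (`"normal"` / `"RA"`).
#' @param x_val,y_val Optional validation set.
#' @param config A [train_config()]; defaults to the QNN recipe.
#' @return Object of class `qnn` with weights and history.
#' @export
train_qnn <- function(x_train, y_train, x_val = NULL, y_val = NULL,
                      config = train_config(optimizer = "adam",
                                            learning_rate = 0.001,
                                            batch_size = 64, epochs = 30,
                                            loss = "binary_cross_entropy")) {
  d <- dim(x_train)
  if (length(d) != 4) stop_input("x_train must be an H x W x C x n array")
  if (d[4] == 0) stop_input("empty training set")
  if (length(y_train) != d[4]) stop_input("label count mismatch")
  # feature maps live in [-1, 1]; rescale to [0, 1] for the head
  rescale <- function(x) (x + 1) / 2
  xt <- rescale(x_train)
  layers <- qnn_head_layers()
  yt <- matrix(as.numeric(factor(y_train, levels = thermo_labels)) - 1,
               ncol = 1)
  if (!is.null(x_val)) {
    xv <- rescale(x_val)
    yv <- matrix(as.numeric(factor(y_val, levels = thermo_labels)) - 1,
                 ncol = 1)
  } else {
    xv <- numeric(0); yv <- matrix(0, 0, 1)
  }
  opts <- list(loss = "bce", optimizer = config$optimizer,
               lr = config$learning_rate, momentum = config$momentum,
               batch_size = config$batch_size, epochs = config$epochs,
               bn_momentum = config$bn_momentum, bn_eps = config$bn_eps,
               seed = config$seed)
  fit <- cnn_train_cpp(layers, xt, yt, xv, yv, opts)
  history <- as.data.frame(fit$history)
  names(history) <- c("train_loss", "train_accuracy", "val_loss", "val_accuracy")
  history$epoch <- seq_len(nrow(history))
  structure(list(engine_layers = layers, weights = fit$best_weights,
                 final_weights = fit$weights, best_epoch = fit$best_epoch,
                 best_val_accuracy = fit$best_val_accuracy, history = history,
                 config = config, classes = thermo_labels, loss = "bce"),
            class = "qnn")
}

qnn_head_layers <- function() {
  list(list(type = "conv", k = 3L, out = 32L, pad = 1L), list(type = "relu"),
       list(type = "pool"),
       list(type = "conv", k = 3L, out = 16L, pad = 1L), list(type = "relu"),
       list(type = "pool"),
       list(type = "conv", k = 3L, out = 16L, pad = 1L), list(type = "relu"),
       list(type = "pool"),
       list(type = "conv", k = 3L, out = 8L, pad = 1L), list(type = "relu"),
       list(type = "pool"),
       list(type = "flat"),
       list(type = "dense", out = 128L), list(type = "relu"),
       list(type = "dense", out = 1L))
}

#' @export
print.qnn <- function(x, ...) {
  cat("QNN classifier head (conv 32-16-16-8, dense 128-1, sigmoid)\n")
  if (!is.null(x$best_epoch) && !is.na(x$best_val_accuracy))
    cat(sprintf("  checkpoint: epoch %d, val accuracy %.4f\n",
                x$best_epoch, x$best_val_accuracy))
  invisible(x)
}

#' RA-probability predictions from a trained QNN head
#'
#' @param object A `qnn` model.
#' @param x Feature-map array (H x W x C x n, values in \[-1, 1\]).
#' @param type `"prob"` for P(RA) in (0, 1) or `"class"` for labels.
#' @param ... Unused.
#' @return Numeric vector of probabilities or factor of labels.
#' @export
predict.qnn <- function(object, x, type = c("prob", "class"), ...) {
  type <- match.arg(type)
  p <- cnn_forward_cpp(object$engine_layers, object$weights, (x + 1) / 2,
                       object$loss, object$config$bn_eps, 0L)[, 1]
  if (type == "class")
    return(factor(object$classes[1 + (p > 0.5)], levels = object$classes))
  p
}

#' Quanvolve a whole image set
#'
#' @param x H x W x 3 x n image array.
#' @param circuit A `circuit_spec`.
#' @return `floor(H/2) x floor(W/2) x 12 x n` array of feature maps.
#' @export
quanvolve_images <- function(x, circuit) {
  d <- dim(x)
  out <- array(0, c(d[1] %/% 2, d[2] %/% 2, d[3] * 4, d[4]))
  for (i in seq_len(d[4])) out[, , , i] <- quanvolve_image(x[, , , i], circuit)
  out
}
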
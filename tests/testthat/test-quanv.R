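test_that("gate construction validates its arguments", {
  expect_error(gate_op("RY", 5, 1), "out of range")
  expect_error(gate_op("RY", 0), "angle")
  expect_error(gate_op("X", 0, 1), "no angle")
  expect_error(gate_op("CNOT", c(1, 1)), "distinct")
  expect_error(gate_op("SWAP", c(0, 1)), "unknown gate")
})

test_that("basis-state gate actions follow the little-endian convention", {
  s <- ground_state()
  sx <- apply_gate(s, gate_op("X", 0))
  expect_equal(which(Mod(sx) > 0.5), 2)   # |0001> is basis index 1
  for (q in 0:3) {
    sr <- apply_gate(s, gate_op("RY", q, pi))
    expect_equal(which(Mod(sr) > 0.5), 2^q + 1)
    expect_equal(max(Mod(sr)), 1, tolerance = 1e-12)
    expect_equal(expectation_z(sr, q), -1, tolerance = 1e-12)
  }
  expect_equal(expectation_z(s, 2), 1)
})

test_that("RY expectation follows the cosine closed form on an angle grid", {
  for (th in seq(0, 2 * pi, length.out = 33)) {
    st <- apply_gate(ground_state(), gate_op("RY", 0, th))
    expect_equal(expectation_z(st, 0), cos(th), tolerance = 1e-12)
  }
})

test_that("random circuits are seeded, layered and empty at zero layers", {
  c0 <- build_random_circuit(0, 1)
  expect_length(c0$random_layers, 0)
  c1 <- build_random_circuit(2, 7)
  c2 <- build_random_circuit(2, 7)
  expect_identical(c1, c2)
  expect_length(c1$random_layers, 2 * 8)   # 4 RY + 4 CNOT per layer
  kinds <- vapply(c1$random_layers[1:8], `[[`, "", "name")
  expect_equal(kinds, c(rep("RY", 4), rep("CNOT", 4)))
  expect_error(build_random_circuit(-1), "n_layers")
})

test_that("densified circuits are unitary and match gate-by-gate application", {
  worst_u <- 0; worst_s <- 0
  for (r in 1:100) {
    circ <- build_random_circuit(1 + r %% 3, r)
    U <- circuit_unitary(circ)
    worst_u <- max(worst_u, max(Mod(Conj(t(U)) %*% U - diag(16))))
    st <- withr::with_seed(r, {
      v <- complex(real = rnorm(16), imaginary = rnorm(16))
      v / sqrt(sum(Mod(v)^2))
    })
    s2 <- st
    for (g in circ$random_layers) s2 <- apply_gate(s2, g)
    worst_s <- max(worst_s, max(Mod(s2 - U %*% st)))
    expect_equal(sum(Mod(s2)^2), 1, tolerance = 1e-10)
  }
  expect_lt(worst_u, 1e-10)
  expect_lt(worst_s, 1e-10)
})

test_that("patch quanvolution satisfies the identity-circuit closed forms", {
  id <- build_random_circuit(0, 1)
  expect_equal(quanv_patch(c(0, 0, 0, 0), id), rep(1, 4), tolerance = 1e-12)
  expect_equal(quanv_patch(c(1, 1, 1, 1), id), rep(-1, 4), tolerance = 1e-12)
  expect_equal(quanv_patch(c(0.5, 0, 0, 0), id), c(0, 1, 1, 1),
               tolerance = 1e-12)
  expect_error(quanv_patch(c(2, 0, 0, 0), id), "\\[0, 1\\]")
})

test_that("image quanvolution halves the size and expands bands into channels", {
  circ <- build_random_circuit(1, 7)
  img <- array(runif(16 * 16 * 3), c(16, 16, 3))
  q <- quanvolve_image(img, circ)
  expect_equal(dim(q), c(8, 8, 12))
  expect_true(all(q >= -1 & q <= 1))
  # odd sizes floor
  odd <- matrix(runif(9 * 7), 9, 7)
  expect_equal(dim(quanvolve_image(odd, circ)), c(4, 3, 4))
  expect_error(quanvolve_image(matrix(0.5, 1, 1), circ), "at least 2 x 2")
})

test_that("a constant image gives spatially constant channels", {
  circ <- build_random_circuit(2, 3)
  q <- quanvolve_image(matrix(0.3, 8, 8), circ)
  for (ch in 1:4) expect_equal(max(q[, , ch]) - min(q[, , ch]), 0,
                               tolerance = 1e-12)
})

test_that("a 2x2 image reduces to the single-patch operation", {
  circ <- build_random_circuit(2, 11)
  patch <- matrix(c(0.1, 0.7, 0.4, 0.9), 2, 2, byrow = TRUE)
  q <- quanvolve_image(patch, circ)
  expect_equal(as.vector(q[1, 1, ]), quanv_patch(patch, circ),
               tolerance = 1e-10)
})

test_that("identity-circuit channels equal cos(pi x) across a whole image", {
  id <- build_random_circuit(0, 1)
  img <- array(runif(10 * 10 * 3), c(10, 10, 3))
  q <- quanvolve_image(img, id)
  ri <- seq(1, 10, 2); ci <- seq(1, 10, 2)
  for (bd in 1:3) {
    expect_equal(q[, , (bd - 1) * 4 + 1], cos(pi * img[ri, ci, bd]),
                 tolerance = 1e-12)
    expect_equal(q[, , (bd - 1) * 4 + 2], cos(pi * img[ri, ci + 1, bd]),
                 tolerance = 1e-12)
    expect_equal(q[, , (bd - 1) * 4 + 3], cos(pi * img[ri + 1, ci, bd]),
                 tolerance = 1e-12)
    expect_equal(q[, , (bd - 1) * 4 + 4], cos(pi * img[ri + 1, ci + 1, bd]),
                 tolerance = 1e-12)
  }
})

test_that("the QNN head outputs sigmoid probabilities and memorizes a tiny set", {
  fx <- fixture_images(n = 8, size = 32, seed = 31)
  circ <- build_random_circuit(1, 5)
  q <- quanvolve_images(fx$x, circ)
  expect_equal(dim(q), c(16, 16, 12, 8))
  m <- train_qnn(q, fx$y, config = train_config(optimizer = "adam",
                 learning_rate = 0.001, batch_size = 4, epochs = 30,
                 loss = "binary_cross_entropy", seed = 1))
  p <- predict(m, q)
  expect_true(all(p > 0 & p < 1))
  expect_equal(tail(m$history$train_accuracy, 1), 1.0)
  expect_equal(levels(predict(m, q, type = "class")), c("normal", "RA"))
})

test_that("the quanvolved classifier separates synthetic classes across seeds", {
  accs <- vapply(1:3, function(seed) {
    cfg <- thermo_config(n_subjects_per_class = 15, image_size = 64,
                         effect_size = 0.4, noise_sd = 0.05, seed = seed)
    man <- generate_dataset(cfg, file.path(tempdir(), paste0("qnn", seed)))
    sp <- split_train_test(man, split_config(seed = seed))
    tr <- load_images(sp$train); te <- load_images(sp$test)
    circ <- build_random_circuit(1, seed = 100 + seed)
    qtr <- quanvolve_images(tr$x, circ)
    qte <- quanvolve_images(te$x, circ)
    m <- train_qnn(qtr, tr$y, config = train_config(optimizer = "adam",
                   learning_rate = 0.001, batch_size = 64, epochs = 30,
                   loss = "binary_cross_entropy", seed = seed))
    mean(predict(m, qte, type = "class") == te$y)
  }, numeric(1))
  expect_true(all(accs >= 0.85))
})
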
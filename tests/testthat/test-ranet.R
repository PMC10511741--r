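# Frozen layer sizes and per-layer parameter counts for the full 256-input
# architecture, derived by replaying the shape/count rules by hand:
# conv "same" keeps the spatial size, conv 3x3 "valid" subtracts 2, 2x2 max
# pooling floors the halved size; conv params = k^2*cin*cout + cout, dense
# params = nin*nout + nout, batchnorm params = 4*channels.
ranet_expected <- data.frame(
  name = c("Conv2D_1", "BN_1", "Maxpooling_1", "Conv2D_2", "BN_2",
           "Maxpooling_2", "Conv2D_3", "BN_3", "Maxpooling_3", "Conv2D_4",
           "BN_4", "Maxpooling_4", "Conv2D_5", "BN_5", "Maxpooling_5",
           "Conv2D_6", "BN_6", "Maxpooling_6"),
  size = c(256, 256, 128, 126, 126, 63, 63, 63, 31, 29, 29, 14, 14, 14, 7,
           5, 5, 2),
  channels = rep(c(8, 16, 32, 64, 128, 256), each = 3),
  params = c(32, 32, 0, 1168, 64, 0, 544, 128, 0, 18496, 256, 0, 8320, 512,
             0, 295168, 1024, 0),
  stringsAsFactors = FALSE)

test_that("shape propagation reproduces every documented layer size", {
  spec <- as.data.frame(build_ranet_spec())
  for (i in seq_len(nrow(ranet_expected))) {
    row <- spec[spec$name == ranet_expected$name[i], ]
    expect_equal(row$out_h, ranet_expected$size[i], info = ranet_expected$name[i])
    expect_equal(row$out_c, ranet_expected$channels[i])
  }
  expect_equal(spec$out_c[spec$name == "Global Average Pooling"], 256)
  expect_equal(spec$out_c[spec$kind == "dense"], c(128, 64, 32, 2))
})

test_that("the spec has 6 conv, 6 batchnorm, 6 maxpool, 1 GAP, 4 dense stages", {
  spec <- as.data.frame(build_ranet_spec())
  expect_equal(as.integer(table(factor(spec$kind,
    c("conv2d", "batchnorm", "maxpool", "global_average_pool", "dense")))),
    c(6L, 6L, 6L, 1L, 4L))
})

test_that("the parameter accountant reproduces every per-layer count and total", {
  acct <- count_parameters(build_ranet_spec())
  exp_layers <- ranet_expected[ranet_expected$params > 0, ]
  for (i in seq_len(nrow(exp_layers))) {
    got <- acct$per_layer$params[acct$per_layer$name == exp_layers$name[i]]
    expect_equal(got, exp_layers$params[i], info = exp_layers$name[i])
  }
  dense <- c(FC_1 = 256 * 128 + 128, FC_2 = 128 * 64 + 64,
             FC_3 = 64 * 32 + 32, FC_4 = 32 * 2 + 2)
  expect_equal(acct$per_layer$params[acct$per_layer$name == "FC_1"], dense[["FC_1"]])
  expect_equal(acct$per_layer$params[acct$per_layer$name == "FC_3"], dense[["FC_3"]])
  expect_equal(acct$total, 369042)
  expect_equal(acct$trainable, 368034)
  expect_equal(acct$non_trainable, 1008)
  expect_equal(acct$total, acct$trainable + acct$non_trainable)
  expect_equal(sum(acct$per_layer$params), acct$total)
})

test_that("parameter counting handles degenerate and hand-checked cases", {
  empty <- count_parameters(NULL)
  expect_equal(empty$total, 0)
  lone <- data.frame(name = "conv", kind = "conv2d", out = 8, kernel = 3,
                     stride = 1, padding = "valid", activation = "ReLU",
                     stringsAsFactors = FALSE)
  lone <- thermonet:::propagate_shapes(lone, 10)
  expect_equal(count_parameters(lone)$total, 3 * 3 * 3 * 8 + 8)  # 224
})

test_that("accountant totals equal the engine's actual tensor element counts", {
  spec <- build_ranet_spec(input_size = 32)
  acct <- count_parameters(spec)
  layers <- thermonet:::spec_to_engine_layers(spec)
  w <- thermonet:::cnn_init_cpp(layers, c(32L, 32L, 3L), 1L)
  trainable <- sum(vapply(w, function(lw)
    sum(vapply(lw[names(lw) %in% c("W", "b", "gamma", "beta")], length,
               integer(1))), numeric(1)))
  frozen <- sum(vapply(w, function(lw)
    sum(vapply(lw[names(lw) %in% c("rmean", "rvar")], length, integer(1))),
    numeric(1)))
  expect_equal(trainable, acct$trainable)
  expect_equal(frozen, acct$non_trainable)
})

test_that("engine gradients match finite differences for both losses", {
  set.seed(2)
  X <- array(runif(8 * 8 * 2 * 5), c(8, 8, 2, 5))
  cases <- list(
    list(layers = list(list(type = "conv", k = 3L, out = 4L, pad = 1L),
                       list(type = "relu"), list(type = "bn"),
                       list(type = "pool"),
                       list(type = "conv", k = 1L, out = 3L, pad = 0L),
                       list(type = "relu"), list(type = "gap"),
                       list(type = "dense", out = 5L), list(type = "relu"),
                       list(type = "dense", out = 2L)),
         loss = "cce", K = 2),
    list(layers = list(list(type = "conv", k = 3L, out = 4L, pad = 1L),
                       list(type = "relu"), list(type = "pool"),
                       list(type = "flat"),
                       list(type = "dense", out = 6L), list(type = "relu"),
                       list(type = "dense", out = 1L)),
         loss = "bce", K = 1))
  eps <- 1e-6
  for (cs in cases) {
    Y <- if (cs$K == 2) {
      m <- matrix(0, 5, 2); m[cbind(1:5, sample(1:2, 5, TRUE))] <- 1; m
    } else matrix(sample(0:1, 5, TRUE), ncol = 1)
    w <- thermonet:::cnn_init_cpp(cs$layers, c(8L, 8L, 2L), 42L)
    g <- thermonet:::cnn_grad_cpp(cs$layers, w, X, Y, cs$loss, 1e-3)
    worst <- 0
    for (li in seq_along(w)) for (nm in names(w[[li]])) {
      if (!nm %in% c("W", "b", "gamma", "beta")) next
      arr <- w[[li]][[nm]]
      for (ii in sample(length(arr), min(3, length(arr)))) {
        wp <- w; wp[[li]][[nm]][ii] <- arr[ii] + eps
        wm <- w; wm[[li]][[nm]][ii] <- arr[ii] - eps
        fd <- (thermonet:::cnn_loss_cpp(cs$layers, wp, X, Y, cs$loss, 1e-3) -
               thermonet:::cnn_loss_cpp(cs$layers, wm, X, Y, cs$loss, 1e-3)) /
          (2 * eps)
        an <- g$grads[[li]][[nm]][ii]
        worst <- max(worst, abs(fd - an) / max(1e-6, abs(fd) + abs(an)))
      }
    }
    expect_lt(worst, 1e-6)
  }
})

test_that("predictions are SoftMax-normalized, deterministic and batch-invariant", {
  fx <- fixture_images(n = 6, size = 32)
  m <- train_ranet(fx$x, fx$y, config = train_config(epochs = 2, seed = 1))
  p <- predict(m, fx$x)
  expect_equal(rowSums(p), rep(1, 6), tolerance = 1e-6)
  expect_true(all(p >= 0 & p <= 1))
  # duplicated input row -> identical output rows
  xdup <- fx$x[, , , c(1, 1), drop = FALSE]
  pdup <- predict(m, xdup)
  expect_equal(pdup[1, ], pdup[2, ], tolerance = 0)
  # batch-of-1 equals the same image inside a larger batch
  p1 <- predict(m, fx$x[, , , 3, drop = FALSE])
  expect_equal(unname(p1[1, ]), unname(p[3, ]), tolerance = 1e-5)
})

test_that("a tiny training set is memorized (overfit sanity)", {
  fx <- fixture_images(n = 8, size = 32)
  m <- train_ranet(fx$x, fx$y, config = train_config(epochs = 50, seed = 1))
  expect_equal(tail(m$history$train_accuracy, 1), 1.0)
  expect_equal(nrow(m$history), m$config$epochs)
})

test_that("checkpointed weights reproduce the recorded validation accuracy", {
  fx <- fixture_images(n = 12, size = 32, seed = 21)
  m <- train_ranet(fx$x[, , , 1:8], fx$y[1:8],
                   fx$x[, , , 9:12], fx$y[9:12],
                   config = train_config(epochs = 6, seed = 2))
  pred <- predict(m, fx$x[, , , 9:12], type = "class")
  expect_equal(mean(pred == fx$y[9:12]), m$best_val_accuracy)
})

test_that("deep-feature extraction honours layer widths and ReLU positivity", {
  fx <- fixture_images(n = 5, size = 32)
  m <- train_ranet(fx$x, fx$y, config = train_config(epochs = 2, seed = 3))
  f3 <- extract_features(m, fx$x, "FC_3")
  expect_equal(dim(f3), c(5, 32))
  expect_true(all(f3 >= 0))
  expect_equal(colnames(f3), paste0("F", 1:32))
  f1 <- extract_features(m, fx$x, "FC_1")
  expect_equal(ncol(f1), 128)
  expect_identical(extract_features(m, fx$x, "FC_3"), f3)  # deterministic
  expect_error(extract_features(m, fx$x, "FC_9"), "unknown layer")
})

test_that("training rejects malformed inputs", {
  fx <- fixture_images(n = 4, size = 32)
  expect_error(train_ranet(fx$x[, , 1, ], fx$y), "array")
  expect_error(train_ranet(fx$x, fx$y[1:2]), "label count")
  expect_error(train_config(learning_rate = 0), "learning_rate")
})
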
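test_that("the 80-20 and 70-30 splits partition, stratify and round per class", {
  # exhaustive per-class rounding check on small synthetic manifests
  for (n_per_class in 1:10) {
    man <- data.frame(path = sprintf("img%03d.png", seq_len(2 * n_per_class)),
                      label = rep(c("normal", "RA"), each = n_per_class),
                      subject_id = seq_len(2 * n_per_class),
                      hand = "left", view = "dorsal", split = "unassigned",
                      stringsAsFactors = FALSE)
    sc <- split_config(seed = n_per_class, group_by_subject = FALSE)
    sp <- split_train_test(man, sc)
    expect_setequal(c(sp$train$path, sp$test$path), man$path)
    expect_length(intersect(sp$train$path, sp$test$path), 0)
    for (cl in c("normal", "RA")) {
      expect_equal(sum(sp$test$label == cl), floor(n_per_class * 0.2))
      expect_equal(sum(sp$train$label == cl),
                   n_per_class - floor(n_per_class * 0.2))
    }
    sv <- split_train_val(man, sc)
    for (cl in c("normal", "RA"))
      expect_equal(sum(sv$val$label == cl), floor(n_per_class * 0.3))
  }
})

test_that("10 balanced records split 8/2 with 4/4 and 1/1 per class", {
  man <- data.frame(path = paste0("p", 1:10),
                    label = rep(c("normal", "RA"), 5),
                    subject_id = 1:10, hand = "left", view = "dorsal",
                    split = "unassigned", stringsAsFactors = FALSE)
  sp <- split_train_test(man, split_config(seed = 1, group_by_subject = FALSE))
  expect_equal(nrow(sp$train), 8)
  expect_equal(nrow(sp$test), 2)
  expect_equal(as.integer(table(sp$test$label)), c(1L, 1L))
})

test_that("empty manifests split into empty halves", {
  empty <- thermonet:::empty_manifest()
  sp <- split_train_test(empty, split_config())
  expect_equal(nrow(sp$train), 0)
  expect_equal(nrow(sp$test), 0)
  expect_equal(nrow(augment_training_set(empty)), 0)
})

test_that("subject grouping keeps all of a subject's images on one side", {
  fx <- fixture_dataset(n_per_class = 6, size = 16)
  sp <- split_train_test(fx$manifest, split_config(seed = 3))
  both <- intersect(sp$train$subject_id, sp$test$subject_id)
  expect_length(both, 0)
  # split membership is deterministic under a fixed seed
  sp2 <- split_train_test(fx$manifest, split_config(seed = 3))
  expect_identical(sp$test$path, sp2$test$path)
})

test_that("invalid split fractions are rejected", {
  expect_error(split_config(test_fraction = 0), "fractions")
  expect_error(split_config(test_fraction = 1), "fractions")
  expect_error(augment_config(elastic_sigma = 0), "sigma")
  expect_error(adjust_brightness(matrix(0.5, 2, 2), 0), "factor")
  expect_error(scale_zoom(matrix(0.5, 2, 2), 3), "factor")
})

test_that("brightness adjustment multiplies and clips", {
  img <- array(0.5, c(4, 4, 3))
  expect_identical(adjust_brightness(img, 1), img)
  expect_equal(adjust_brightness(img, 1.1), array(0.55, c(4, 4, 3)))
  expect_equal(adjust_brightness(array(0.95, c(4, 4, 3)), 1.1),
               array(1, c(4, 4, 3)))
})

test_that("zoom is identity at factor 1 and on constant fields", {
  img <- array(runif(16 * 16 * 3), c(16, 16, 3))
  expect_equal(scale_zoom(img, 1), img, tolerance = 1e-12)
  flat <- array(0.7, c(16, 16, 3))
  expect_equal(scale_zoom(flat, 1.3), flat, tolerance = 1e-12)
  expect_equal(scale_zoom(flat, 0.8), flat, tolerance = 1e-12)
})

test_that("zooming a disk scales its radius (area-count oracle)", {
  s <- 64; r <- 10
  xs <- matrix(seq_len(s) - 0.5, s, s, byrow = TRUE)
  ys <- matrix(seq_len(s) - 0.5, s, s)
  img <- matrix(0, s, s)
  img[(xs - s / 2)^2 + (ys - s / 2)^2 <= r^2] <- 1
  for (f in c(1.1, 0.9)) {
    z <- scale_zoom(img, f)
    r_fit <- sqrt(sum(z > 0.5) / pi)
    expect_lt(abs(r_fit - f * r), 1)
  }
})

test_that("elastic deformation is identity at zero magnitude and on constants", {
  img <- array(runif(12 * 12 * 3), c(12, 12, 3))
  expect_equal(elastic_deform(img, sigma = 2, alpha = 0, seed = 1), img,
               tolerance = 1e-12)
  flat <- array(0.4, c(12, 12, 3))
  expect_equal(elastic_deform(flat, sigma = 2, alpha = 5, seed = 2), flat,
               tolerance = 1e-12)
})

test_that("elastic resampling weights sum to one (dense-matrix oracle)", {
  n <- 12
  T <- resampling_matrix(n, function(e)
    elastic_deform(e, sigma = 2, alpha = 4, seed = 7))
  expect_equal(range(rowSums(T)), c(1, 1), tolerance = 1e-12)
  # consequence: smooth images keep their total intensity closely
  img <- render_hand_thermogram("RA", thermo_config(image_size = 32, seed = 1),
                                3)$field
  warped <- elastic_deform(img, sigma = 2, alpha = 4, seed = 7)
  expect_lt(abs(sum(warped) - sum(img)) / sum(img), 0.01)
})

test_that("augmentation triples cardinality, inherits labels, keeps range", {
  fx <- fixture_dataset(n_per_class = 2, size = 16)
  aug <- augment_training_set(fx$manifest, augment_config(seed = 3),
                              out_dir = file.path(tempdir(), "aug_t"))
  expect_equal(nrow(aug), 3 * nrow(fx$manifest))
  expect_equal(as.integer(table(aug$source)),
               rep(3L, nrow(fx$manifest)))
  expect_identical(aug$label, rep(fx$manifest$label, each = 3))
  suffix <- sub(".*_(el|br|sc)\\.png$", "\\1", aug$path)
  expect_equal(as.integer(table(suffix)), rep(nrow(fx$manifest), 3))
  p <- png::readPNG(aug$path[1])
  expect_true(all(p >= 0 & p <= 1))
  expect_equal(dim(p)[1:2], c(16, 16))
})

test_that("augmentation output bytes are deterministic for a fixed seed", {
  fx <- fixture_dataset(n_per_class = 1, size = 16)
  d1 <- file.path(tempdir(), "aug_d1"); d2 <- file.path(tempdir(), "aug_d2")
  a1 <- augment_training_set(fx$manifest, augment_config(seed = 8), d1)
  a2 <- augment_training_set(fx$manifest, augment_config(seed = 8), d2)
  same <- vapply(seq_len(nrow(a1)), function(i) {
    identical(readBin(a1$path[i], "raw", 1e6), readBin(a2$path[i], "raw", 1e6))
  }, logical(1))
  expect_true(all(same))
})
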
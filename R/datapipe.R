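#' Split configuration
#'
#' Controls the stratified train/test and train/validation partitions.  By
#' default the test side holds 20% and the validation side 30% of the
#' (augmented) training pool, reproducing the 600 -> 480/120 and
#' 1440 -> 1008/432 arithmetic of a 50 + 50 subject cohort.  Subject-wise
#' grouping is on by default so that all six images of one subject land on the
#' same side (image-level splitting of multi-view subjects leaks identity);
#' with six images per subject both modes give the same counts.
#'
#' @param test_fraction Proportion held out for testing (default 0.2).
#' @param val_fraction_of_train Proportion of the training pool held out for
#'   validation (default 0.3).
#' @param stratified Stratify by class label (default TRUE).
#' @param group_by_subject Keep each subject's images on one side (default TRUE).
#' @param seed Integer seed for the shuffles.
#' @return Object of class `split_config`.
#' @export
split_config <- function(test_fraction = 0.2, val_fraction_of_train = 0.3,
                         stratified = TRUE, group_by_subject = TRUE,
                         seed = 1L) {
  for (f in c(test_fraction, val_fraction_of_train))
    if (f <= 0 || f >= 1) stop_input("split fractions must lie in (0, 1)")
  structure(list(test_fraction = test_fraction,
                 val_fraction_of_train = val_fraction_of_train,
                 stratified = stratified, group_by_subject = group_by_subject,
                 seed = as.integer(seed)),
            class = "split_config")
}

# Stratified partition of manifest rows.  Per class the smaller side gets
# floor(n_units * small_fraction) units (remainder to the larger side), units
# being subjects or single records.  Ties are broken by a seeded shuffle.
partition_manifest <- function(manifest, small_fraction, seed,
                               stratified = TRUE, group_by_subject = TRUE,
                               tags = c("train", "test")) {
  if (nrow(manifest) == 0) {
    return(setNames(list(manifest, manifest), tags))
  }
  strata <- if (stratified) unique(manifest$label) else "all"
  small_idx <- integer(0)
  for (si in seq_along(strata)) {
    rows <- if (stratified) which(manifest$label == strata[si]) else
      seq_len(nrow(manifest))
    if (group_by_subject) {
      units <- unique(manifest$subject_id[rows])
      n_small <- floor(length(units) * small_fraction)
      pick <- withr::with_seed(derive_seed(seed, si),
                               sample(units, n_small))
      small_idx <- c(small_idx, rows[manifest$subject_id[rows] %in% pick])
    } else {
      n_small <- floor(length(rows) * small_fraction)
      pick <- withr::with_seed(derive_seed(seed, si),
                               sample(rows, n_small))
      small_idx <- c(small_idx, pick)
    }
  }
  large <- manifest[setdiff(seq_len(nrow(manifest)), small_idx), , drop = FALSE]
  small <- manifest[sort(small_idx), , drop = FALSE]
  if (nrow(large)) large$split <- tags[1]
  if (nrow(small)) small$split <- tags[2]
  rownames(large) <- rownames(small) <- NULL
  setNames(list(large, small), tags)
}

#' Stratified train/test split of a manifest
#'
#' @param manifest Dataset manifest data frame.
#' @param config A [split_config()].
#' @return List with elements `train` and `test` (disjoint, covering).
#' @export
split_train_test <- function(manifest, config = split_config()) {
  partition_manifest(manifest, config$test_fraction,
                     derive_seed(config$seed, 101L),
                     config$stratified, config$group_by_subject,
                     c("train", "test"))
}

#' Stratified train/validation split (applied after augmentation)
#'
#' @param manifest Manifest of the (augmented) training pool.
#' @param config A [split_config()]; uses `val_fraction_of_train`.
#' @return List with elements `train` and `val`.
#' @export
split_train_val <- function(manifest, config = split_config()) {
  partition_manifest(manifest, config$val_fraction_of_train,
                     derive_seed(config$seed, 202L),
                     config$stratified, config$group_by_subject,
                     c("train", "val"))
}

#' Augmentation configuration
#'
#' Three transforms, one output image each per input: an elastic deformation
#' (uniform displacement field smoothed with a Gaussian of `elastic_sigma`
#' pixels and scaled to `elastic_alpha` pixels), a brightness rescale with a
#' factor drawn in `1 +/- brightness_fraction`, and a central zoom with factor
#' drawn in `1 +/- scale_fraction`.  Originals are not retained, so the
#' augmented set has exactly three times the cardinality of its input.
#'
#' @param elastic_sigma Gaussian smoothing sd in pixels (default 2).
#' @param elastic_alpha Displacement magnitude in pixels (default 8).
#' @param brightness_fraction Half-width of the brightness factor range
#'   (default 0.10).
#' @param scale_fraction Half-width of the zoom factor range (default 0.10).
#' @param seed Integer seed.
#' @return Object of class `augment_config`.
#' @export
augment_config <- function(elastic_sigma = 2, elastic_alpha = 8,
                           brightness_fraction = 0.10, scale_fraction = 0.10,
                           seed = 1L) {
  if (elastic_sigma <= 0) stop_input("elastic_sigma must be positive")
  for (f in c(brightness_fraction, scale_fraction))
    if (f < 0 || f >= 1) stop_input("fractions must lie in [0, 1)")
  structure(list(elastic_sigma = elastic_sigma, elastic_alpha = elastic_alpha,
                 brightness_fraction = brightness_fraction,
                 scale_fraction = scale_fraction, seed = as.integer(seed)),
            class = "augment_config")
}

# Separable Gaussian blur with renormalized (edge-aware) kernels, via small
# banded matrices; exact enough for sigma of a few pixels.
gaussian_blur_mat <- function(m, sigma) {
  blur_1d <- function(n) {
    r <- max(1L, ceiling(3 * sigma))
    k <- exp(-((-r:r)^2) / (2 * sigma^2))
    K <- matrix(0, n, n)
    for (d in -r:r) {
      idx <- seq_len(n)
      j <- idx + d
      ok <- j >= 1 & j <= n
      K[cbind(idx[ok], j[ok])] <- k[d + r + 1]
    }
    K / rowSums(K)
  }
  blur_1d(nrow(m)) %*% m %*% t(blur_1d(ncol(m)))
}

# Bilinear sampling of matrix `m` at (row, col) query coordinates with edge
# clamping.  Vectorized over the query grid.
bilinear_sample <- function(m, rq, cq) {
  H <- nrow(m); W <- ncol(m)
  rq <- as.vector(pmin(pmax(rq, 1), H)); cq <- as.vector(pmin(pmax(cq, 1), W))
  r0 <- pmin(floor(rq), H - 1); c0 <- pmin(floor(cq), W - 1)
  fr <- rq - r0; fc <- cq - c0
  i00 <- cbind(r0, c0); i10 <- cbind(r0 + 1, c0)
  i01 <- cbind(r0, c0 + 1); i11 <- cbind(r0 + 1, c0 + 1)
  out <- m[i00] * (1 - fr) * (1 - fc) + m[i10] * fr * (1 - fc) +
    m[i01] * (1 - fr) * fc + m[i11] * fr * fc
  matrix(out, H, W)
}

apply_per_band <- function(image, f) {
  if (length(dim(image)) == 2) return(clip01(f(image)))
  out <- image
  for (b in seq_len(dim(image)[3])) out[, , b] <- f(image[, , b])
  clip01(out)
}

#' Elastic deformation of an image
#'
#' Per-pixel displacement fields drawn uniform in \[-1, 1\], smoothed with a
#' Gaussian of sd `sigma`, scaled by `alpha` pixels, and applied by bilinear
#' resampling with edge clamping.  The same field warps every band.
#'
#' @param image H x W (x bands) array with values in \[0, 1\].
#' @param sigma Smoothing sd in pixels (> 0).
#' @param alpha Displacement magnitude in pixels.
#' @param seed Integer seed for the displacement draw.
#' @return Deformed image of the same shape, values clipped to \[0, 1\].
#' @export
elastic_deform <- function(image, sigma = 2, alpha = 8, seed = 1L) {
  if (sigma <= 0) stop_input("sigma must be positive")
  d <- dim(image)
  H <- d[1]; W <- d[2]
  flds <- withr::with_seed(seed, list(
    dr = matrix(runif(H * W, -1, 1), H, W),
    dc = matrix(runif(H * W, -1, 1), H, W)))
  dr <- alpha * gaussian_blur_mat(flds$dr, sigma)
  dc <- alpha * gaussian_blur_mat(flds$dc, sigma)
  rq <- matrix(seq_len(H), H, W) + dr
  cq <- matrix(seq_len(W), H, W, byrow = TRUE) + dc
  apply_per_band(image, function(m) bilinear_sample(m, rq, cq))
}

#' Brightness adjustment
#'
#' @param image Image array in \[0, 1\].
#' @param factor Positive multiplier; result is clipped to \[0, 1\].
#' @return Adjusted image.
#' @export
adjust_brightness <- function(image, factor) {
  if (factor <= 0) stop_input("brightness factor must be positive")
  clip01(image * factor)
}

#' Central zoom
#'
#' Zooms about the image centre by `factor` with bilinear resampling: factors
#' above 1 crop-and-enlarge, factors below 1 shrink and pad with edge values.
#' Output shape is unchanged.
#'
#' @param image Image array in \[0, 1\].
#' @param factor Zoom factor in \[0.5, 2\].
#' @return Zoomed image of the same shape.
#' @export
scale_zoom <- function(image, factor) {
  if (factor < 0.5 || factor > 2) stop_input("zoom factor must lie in [0.5, 2]")
  d <- dim(image)
  H <- d[1]; W <- d[2]
  cr <- (H + 1) / 2; cc <- (W + 1) / 2
  rq <- cr + (matrix(seq_len(H), H, W) - cr) / factor
  cq <- cc + (matrix(seq_len(W), H, W, byrow = TRUE) - cc) / factor
  apply_per_band(image, function(m) bilinear_sample(m, rq, cq))
}

#' Augment a training manifest threefold
#'
#' Each input image yields exactly three outputs (elastic-deformed `_el`,
#' brightness-adjusted `_br`, zoomed `_sc`); originals are not retained, so
#' 480 training images become 1440.  Labels and subject ids are inherited and
#' a `source` column records provenance.
#'
#' @param manifest Training manifest.
#' @param config An [augment_config()].
#' @param out_dir Directory for the augmented PNGs (defaults to the source
#'   images' directory).
#' @return Augmented manifest data frame.
#' @export
augment_training_set <- function(manifest, config = augment_config(),
                                 out_dir = NULL) {
  if (nrow(manifest) == 0) {
    out <- empty_manifest()
    out$source <- character(0)
    return(out)
  }
  rows <- vector("list", 3L * nrow(manifest))
  for (i in seq_len(nrow(manifest))) {
    img <- png::readPNG(manifest$path[i])[, , 1:3]
    dir <- out_dir %||% dirname(manifest$path[i])
    dir.create(dir, recursive = TRUE, showWarnings = FALSE)
    base <- sub("\\.png$", "", basename(manifest$path[i]))
    sd_el <- derive_seed(config$seed, i, 1L)
    el <- elastic_deform(img, config$elastic_sigma, config$elastic_alpha, sd_el)
    bf <- withr::with_seed(derive_seed(config$seed, i, 2L),
                           runif(1, 1 - config$brightness_fraction,
                                 1 + config$brightness_fraction))
    br <- adjust_brightness(img, bf)
    zf <- withr::with_seed(derive_seed(config$seed, i, 3L),
                           runif(1, 1 - config$scale_fraction,
                                 1 + config$scale_fraction))
    sc <- scale_zoom(img, zf)
    outs <- c("_el", "_br", "_sc")
    imgs <- list(el, br, sc)
    for (k in 1:3) {
      path <- file.path(dir, paste0(base, outs[k], ".png"))
      png::writePNG(imgs[[k]], path)
      row <- manifest[i, , drop = FALSE]
      row$path <- path
      row$source <- manifest$path[i]
      rows[[3L * (i - 1L) + k]] <- row
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
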
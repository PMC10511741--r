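#' Configuration for the synthetic thermogram generator
#'
#' The generator emulates rainbow-palette hand thermograms of the kind used to
#' screen for rheumatoid arthritis: a warm hand silhouette over a cooler
#' background, with circular "hot spots" at finger-joint positions.  In the RA
#' class the hot-spot intensity is elevated by `effect_size` (on the unitless
#' pre-colormap temperature scale in \[0, 1\]) before pixel noise is added.
#'
#' @param n_subjects_per_class Number of subjects per class; each subject
#'   contributes 2 hands x 3 views = 6 images.
#' @param image_size Side length in pixels of the square images (default 256).
#' @param effect_size Hot-spot intensity elevation for the RA class, in
#'   \[0, 1\] intensity units (default 0.4).
#' @param noise_sd Standard deviation of additive Gaussian pixel noise
#'   (default 0.05).
#' @param seed Integer seed; the whole dataset is a deterministic function of
#'   the configuration including this seed.
#' @return An object of class `thermo_config`.
#' @export
thermo_config <- function(n_subjects_per_class = 50, image_size = 256,
                          effect_size = 0.4, noise_sd = 0.05, seed = 1L) {
  if (image_size < 4) stop_input("image_size must be at least 4")
  if (effect_size < 0) stop_input("effect_size must be >= 0")
  if (noise_sd < 0) stop_input("noise_sd must be >= 0")
  if (n_subjects_per_class < 0) stop_input("n_subjects_per_class must be >= 0")
  structure(list(n_subjects_per_class = as.integer(n_subjects_per_class),
                 image_size = as.integer(image_size),
                 effect_size = effect_size, noise_sd = noise_sd,
                 seed = as.integer(seed)),
            class = "thermo_config")
}

thermo_labels <- c("normal", "RA")
thermo_hands <- c("left", "right")
thermo_views <- c("dorsal", "ventral", "AP")

# Fixed hand template in normalized [0,1]^2 coordinates (x right, y down;
# fingers point towards y = 0).  Four fingers as capsules plus a thumb capsule
# and a palm ellipse; 14 joint loci: MCP/PIP/DIP on digits 2-5 and two thumb
# joints.  The paper-style acquisition measures finger-joint temperature, so
# the class signal lives entirely in these disks.
hand_template <- function() {
  fx <- c(0.38, 0.48, 0.58, 0.68)
  tips <- c(0.22, 0.17, 0.20, 0.26)
  fingers <- data.frame(x0 = fx, y0 = 0.52, x1 = fx, y1 = tips, r = 0.035)
  thumb <- data.frame(x0 = 0.32, y0 = 0.60, x1 = 0.20, y1 = 0.45, r = 0.040)
  loci <- rbind(
    data.frame(cx = rep(fx, 3),
               cy = rep(c(0.50, 0.36, 0.26), each = 4)),
    data.frame(cx = c(0.28, 0.23), cy = c(0.55, 0.49)))
  list(capsules = rbind(fingers, thumb),
       palm = list(cx = 0.52, cy = 0.64, ax = 0.20, ay = 0.16),
       loci = cbind(loci, r = 0.018))
}

#' Joint-locus disk positions in pixel coordinates
#'
#' @param image_size Image side length in pixels.
#' @param hand `"left"` or `"right"`; the right hand mirrors the template.
#' @return Data frame with columns `cx`, `cy`, `r` (pixels).
#' @export
joint_loci <- function(image_size, hand = "left") {
  tl <- hand_template()$loci
  if (hand == "right") tl$cx <- 1 - tl$cx
  data.frame(cx = tl$cx * image_size, cy = tl$cy * image_size,
             r = tl$r * image_size)
}

#' Logical mask of the union of joint-locus disks
#'
#' @param image_size Image side length in pixels.
#' @param hand `"left"` or `"right"`.
#' @return `image_size` x `image_size` logical matrix.
#' @export
joint_disk_mask <- function(image_size, hand = "left") {
  loci <- joint_loci(image_size, hand)
  xs <- matrix((seq_len(image_size) - 0.5), image_size, image_size, byrow = TRUE)
  ys <- matrix((seq_len(image_size) - 0.5), image_size, image_size)
  m <- matrix(FALSE, image_size, image_size)
  for (i in seq_len(nrow(loci))) {
    m <- m | ((xs - loci$cx[i])^2 + (ys - loci$cy[i])^2 <= loci$r[i]^2)
  }
  m
}

hand_mask <- function(image_size, hand = "left") {
  tpl <- hand_template()
  caps <- tpl$capsules
  palm <- tpl$palm
  if (hand == "right") {
    caps$x0 <- 1 - caps$x0; caps$x1 <- 1 - caps$x1
    palm$cx <- 1 - palm$cx
  }
  s <- image_size
  xs <- matrix((seq_len(s) - 0.5) / s, s, s, byrow = TRUE)
  ys <- matrix((seq_len(s) - 0.5) / s, s, s)
  m <- ((xs - palm$cx) / palm$ax)^2 + ((ys - palm$cy) / palm$ay)^2 <= 1
  for (i in seq_len(nrow(caps))) {
    dx <- caps$x1[i] - caps$x0[i]; dy <- caps$y1[i] - caps$y0[i]
    len2 <- dx^2 + dy^2
    t <- ((xs - caps$x0[i]) * dx + (ys - caps$y0[i]) * dy) / len2
    t <- pmin(1, pmax(0, t))
    d2 <- (xs - (caps$x0[i] + t * dx))^2 + (ys - (caps$y0[i] + t * dy))^2
    m <- m | (d2 <= caps$r[i]^2)
  }
  m
}

#' Piecewise-linear rainbow colormap
#'
#' Maps a scalar temperature field in \[0, 1\] to RGB through fixed stops
#' blue (0) -> cyan (0.25) -> green (0.5) -> yellow (0.75) -> red (1),
#' emulating the rainbow palette of clinical thermal cameras.
#'
#' @param field Numeric matrix (or vector) with values in \[0, 1\].
#' @return An array of dimension `c(dim(field), 3)` with values in \[0, 1\].
#' @export
rainbow_colormap <- function(field) {
  stops <- c(0, 0.25, 0.5, 0.75, 1)
  rs <- c(0, 0, 0, 1, 1); gs <- c(0, 1, 1, 1, 0); bs <- c(1, 1, 0, 0, 0)
  v <- clip01(as.numeric(field))
  out <- array(0, c(dim(field) %||% length(field), 3))
  ch <- function(y) stats::approx(stops, y, xout = v, rule = 2)$y
  n <- length(v)
  out[seq_len(n)] <- ch(rs)
  out[n + seq_len(n)] <- ch(gs)
  out[2 * n + seq_len(n)] <- ch(bs)
  out
}

# Pre-colormap scalar temperature field for one image.  Returns the field
# before noise plus the noise realization separately so callers can reason
# about the noiseless structure.
render_field <- function(label, config, severity, hand, view) {
  s <- config$image_size
  bg <- matrix(rep(seq(0.12, 0.28, length.out = s), each = s), s, s)
  fld <- bg
  hm <- hand_mask(s, hand)
  view_shift <- c(dorsal = 0, ventral = 0.015, AP = -0.015)[[view]]
  fld[hm] <- 0.45 + view_shift
  dm <- joint_disk_mask(s, hand)
  fld[dm] <- fld[dm] + 0.12 * severity
  if (label == "RA") fld[dm] <- fld[dm] + config$effect_size
  fld
}

#' Render one synthetic hand thermogram
#'
#' Draws the per-subject latent severity and the per-image noise from streams
#' derived deterministically from `subject_seed`, renders the scalar
#' temperature field (background gradient, warm hand silhouette, joint-locus
#' hot-spot disks; RA elevation `effect_size` added inside the disks before
#' noise), then maps it through the rainbow colormap.  All six images of one
#' subject (2 hands x 3 views) share the same severity draw.
#'
#' @param label `"normal"` or `"RA"`.
#' @param config A [thermo_config()].
#' @param subject_seed Integer seed identifying the subject.
#' @param hand `"left"` or `"right"`.
#' @param view `"dorsal"`, `"ventral"` or `"AP"`.
#' @return An object of class `thermogram`: list with `pixels` (H x W x 3 in
#'   \[0, 1\]), `field` (pre-colormap scalar field after noise), `field_clean`
#'   (before noise), `label`, `hand`, `view`.
#' @export
render_hand_thermogram <- function(label, config, subject_seed,
                                   hand = "left", view = "dorsal") {
  if (!label %in% thermo_labels)
    stop_input("label must be one of: ", paste(thermo_labels, collapse = ", "))
  if (!hand %in% thermo_hands) stop_input("unknown hand: ", hand)
  if (!view %in% thermo_views) stop_input("unknown view: ", view)
  if (config$image_size < 4) stop_input("image_size must be at least 4")

  severity <- withr::with_seed(derive_seed(subject_seed, 1L),
                               rnorm(1, mean = 1, sd = 0.1))
  clean <- render_field(label, config, severity, hand, view)
  noise_seed <- derive_seed(subject_seed, 2L, match(hand, thermo_hands),
                            match(view, thermo_views))
  fld <- withr::with_seed(noise_seed, {
    clean + rnorm(length(clean), 0, config$noise_sd)
  })
  fld <- clip01(matrix(fld, nrow = config$image_size))
  structure(list(pixels = rainbow_colormap(fld), field = fld,
                 field_clean = clean, label = label, hand = hand, view = view),
            class = "thermogram")
}

#' @export
print.thermogram <- function(x, ...) {
  cat(sprintf("<thermogram> %dx%d, label=%s, hand=%s, view=%s\n",
              nrow(x$field), ncol(x$field), x$label, x$hand, x$view))
  invisible(x)
}

#' Mean pre-colormap intensity inside the joint-locus disks
#'
#' The summary statistic that carries the class signal: with zero noise the
#' RA-minus-normal difference of this mean equals `effect_size` exactly.
#'
#' @param field Scalar field matrix (or a `thermogram`, whose `field` is used).
#' @param hand Which hand template the image used.
#' @return Mean intensity over the union of joint disks.
#' @export
joint_disk_mean <- function(field, hand = "left") {
  if (inherits(field, "thermogram")) {
    hand <- field$hand
    field <- field$field
  }
  mean(field[joint_disk_mask(nrow(field), hand)])
}

#' Generate a labelled synthetic thermogram dataset on disk
#'
#' Writes one 8-bit RGB PNG per (subject, hand, view, class) plus a CSV
#' manifest `manifest.csv` with header `path,label,subject_id,hand,view,split`.
#' Generation is bit-reproducible for a fixed configuration.
#'
#' @param config A [thermo_config()].
#' @param out_dir Output directory (created if needed).
#' @return The manifest as a data frame (invisibly also written to CSV).
#' @export
generate_dataset <- function(config, out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  if (!dir.exists(out_dir)) stop_input("cannot create output directory: ", out_dir)
  rows <- list()
  sid <- 0L
  for (ci in seq_along(thermo_labels)) {
    label <- thermo_labels[ci]
    for (subj in seq_len(config$n_subjects_per_class)) {
      sid <- sid + 1L
      subject_seed <- derive_seed(config$seed, ci, subj)
      for (hand in thermo_hands) for (view in thermo_views) {
        img <- render_hand_thermogram(label, config, subject_seed, hand, view)
        fn <- sprintf("%s_s%03d_%s_%s.png", label, sid, hand, view)
        path <- file.path(out_dir, fn)
        png::writePNG(img$pixels, path)
        rows[[length(rows) + 1L]] <- data.frame(
          path = path, label = label, subject_id = sid, hand = hand,
          view = view, split = "unassigned", stringsAsFactors = FALSE)
      }
    }
  }
  manifest <- if (length(rows)) do.call(rbind, rows) else empty_manifest()
  write_manifest(manifest, file.path(out_dir, "manifest.csv"))
  manifest
}

empty_manifest <- function() {
  data.frame(path = character(), label = character(),
             subject_id = integer(), hand = character(), view = character(),
             split = character(), stringsAsFactors = FALSE)
}

#' Read / write a dataset manifest CSV
#'
#' @param manifest Manifest data frame.
#' @param path CSV file path.
#' @return `read_manifest` returns the manifest data frame.
#' @export
write_manifest <- function(manifest, path) {
  write.csv(manifest, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_manifest
#' @export
read_manifest <- function(path) {
  m <- read.csv(path, stringsAsFactors = FALSE,
                colClasses = c(subject_id = "integer"))
  if (nrow(m) == 0) return(empty_manifest())
  m
}

#' Load manifest images into an array
#'
#' @param manifest Manifest data frame with a `path` column.
#' @return List with `x` (H x W x 3 x n array) and `y` (factor of labels).
#' @export
load_images <- function(manifest) {
  n <- nrow(manifest)
  if (n == 0) stop_input("empty manifest")
  first <- png::readPNG(manifest$path[1])
  x <- array(0, c(dim(first)[1], dim(first)[2], 3, n))
  for (i in seq_len(n)) {
    p <- png::readPNG(manifest$path[i])
    x[, , , i] <- p[, , 1:3]
  }
  list(x = x, y = factor(manifest$label, levels = thermo_labels))
}
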
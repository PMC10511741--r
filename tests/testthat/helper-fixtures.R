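# Shared fixtures, generated in code and cached for the session.

fixture_dataset <- local({
  cache <- new.env(parent = emptyenv())
  function(n_per_class = 4, size = 32, effect = 0.4, noise = 0.05, seed = 42) {
    key <- paste("fix", n_per_class, size, effect * 100, noise * 100, seed,
                 sep = "_")
    if (is.null(cache[[key]])) {
      cfg <- thermo_config(n_per_class, size, effect, noise, seed)
      dir <- file.path(tempdir(), key)
      cache[[key]] <- list(config = cfg,
                           manifest = generate_dataset(cfg, dir), dir = dir)
    }
    cache[[key]]
  }
})

# Small labelled image array rendered directly (no disk round-trip).
fixture_images <- function(n = 8, size = 32, effect = 0.4, noise = 0.05,
                           seed = 5) {
  cfg <- thermo_config(image_size = size, effect_size = effect,
                       noise_sd = noise, seed = seed)
  labels <- rep(c("normal", "RA"), length.out = n)
  x <- array(0, c(size, size, 3, n))
  for (i in seq_len(n)) {
    img <- render_hand_thermogram(labels[i], cfg, seed + 100 + i)
    x[, , , i] <- img$pixels
  }
  list(x = x, y = labels, config = cfg)
}

# Dense resampling matrix of a deterministic warp, column by column.
resampling_matrix <- function(n, transform) {
  T <- matrix(0, n * n, n * n)
  for (j in seq_len(n * n)) {
    e <- matrix(0, n, n)
    e[j] <- 1
    T[, j] <- as.vector(transform(e))
  }
  T
}
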
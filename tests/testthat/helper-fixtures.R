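# Shared fixtures, built in code. The default synthetic dataset and its
# reference embedding are expensive enough to cache per test session.

img <- function(mat, mz = NA_real_, pitch = 1, mask = NULL) {
  ion_image_new(mat, mz = mz, pixel_size_um = pitch, mask = mask)
}

# 2x2-pixel, 3-channel continuous dataset used across msi_io tests
tiny_dataset <- function() {
  coords <- cbind(x = c(0L, 1L, 0L, 1L), y = c(0L, 0L, 1L, 1L))
  mz <- c(700, 701.003, 710.5)
  intens <- rbind(c(1, 2, 3), c(4, 5, 6), c(7, 8, 9), c(10, 11, 12))
  msi_dataset(coords, mz, intens, pixel_size_um = 10)
}

.fixture_cache <- new.env(parent = emptyenv())

cached <- function(key, builder) {
  if (!exists(key, envir = .fixture_cache)) {
    assign(key, builder(), envir = .fixture_cache)
  }
  get(key, envir = .fixture_cache)
}

default_sim <- function() cached("sim", function() {
  generate_msi_dataset(synthetic_config())
})

# standardized channel images of the default sim. TIC normalization is
# deliberately skipped here: the generator models no per-pixel sensitivity
# variation, so the TIC ratio transform would only distort the engineered
# spatial correlations (see the methods vignette).
default_images <- function() cached("images", function() {
  lapply(channel_images(default_sim()$dataset), standardize_image)
})

# reference-embedder neural ion images of the default sim
default_embedding <- function() cached("embedding", function() {
  embed_dataset(default_images(), reference_embedder(), preprocessed = TRUE)
})

default_pairs <- function() cached("pairs", function() {
  sim <- default_sim()
  find_isotope_pairs(sim$dataset$mz_axis, default_images(),
                     isotope_criteria())
})
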
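# Seeded synthetic MSI generator. Emulates the structure the isotope-based
# evaluation assumes: groups of m/z channels sharing a spatial pattern,
# +1.003 Da isotope companions with near-identical expression at reduced
# amplitude, pure-noise channels, and additive per-channel noise — with
# ground-truth pattern labels and the engineered isotope-pair list.

#' Synthetic dataset configuration
#'
#' Defaults describe the stated world of the package's tests: a 64 x 64
#' grid at 50 um pitch, 4 spatial patterns with 10 channels each, half the
#' base channels carrying a +1.003 Da isotope companion at 0.4x amplitude,
#' 8 pure-noise channels, and additive Gaussian noise (sd 0.02, clipped at
#' zero) on every channel.
#'
#' @param shape `c(rows, cols)` of the pixel grid (each `>= 16`).
#' @param n_patterns number of distinct spatial patterns (`<= 12`).
#' @param channels_per_pattern base channels sharing each pattern.
#' @param isotope_fraction fraction of base channels given a companion.
#' @param isotope_ratio companion amplitude multiplier, in (0,1).
#' @param noise_channels number of pure-noise channels.
#' @param noise_sigma sd of the additive Gaussian noise.
#' @param mz_range `c(low, high)` m/z window (Da) for channel placement.
#' @param pixel_size_um pixel pitch in micrometers.
#' @param seed integer master seed.
#' @return object of class `synthetic_config`.
#' @export
synthetic_config <- function(shape = c(64L, 64L), n_patterns = 4L,
                             channels_per_pattern = 10L,
                             isotope_fraction = 0.5, isotope_ratio = 0.4,
                             noise_channels = 8L, noise_sigma = 0.02,
                             mz_range = c(620, 1200), pixel_size_um = 50,
                             seed = 7L) {
  if (any(shape < 16L)) stopf("shape too small (< 16 x 16)")
  if (n_patterns > 12L) stopf("n_patterns must be <= 12")
  if (isotope_ratio <= 0 || isotope_ratio >= 1) {
    stopf("isotope_ratio must be in (0,1)")
  }
  if (isotope_fraction < 0 || isotope_fraction > 1) {
    stopf("isotope_fraction must be in [0,1]")
  }
  structure(list(shape = as.integer(shape), n_patterns = as.integer(n_patterns),
                 channels_per_pattern = as.integer(channels_per_pattern),
                 isotope_fraction = isotope_fraction,
                 isotope_ratio = isotope_ratio,
                 noise_channels = as.integer(noise_channels),
                 noise_sigma = noise_sigma, mz_range = as.numeric(mz_range),
                 pixel_size_um = pixel_size_um, seed = as.integer(seed)),
            class = "synthetic_config")
}

# one pattern image in [0,1]; family cycles blob -> ring -> half-plane ->
# stripe band, with seeded random placement (caller manages RNG state)
make_pattern <- function(shape, family) {
  r <- shape[1]; c <- shape[2]
  yy <- matrix(seq_len(r), r, c)
  xx <- matrix(seq_len(c), r, c, byrow = TRUE)
  span <- min(r, c)
  cy <- stats::runif(1, 0.25 * r, 0.75 * r)
  cx <- stats::runif(1, 0.25 * c, 0.75 * c)
  d <- sqrt((yy - cy)^2 + (xx - cx)^2)
  img <- switch(family,
    blob = {
      s <- stats::runif(1, 0.12, 0.25) * span
      exp(-d^2 / (2 * s^2))
    },
    ring = {
      r0 <- stats::runif(1, 0.22, 0.38) * span
      w <- stats::runif(1, 0.05, 0.10) * span
      exp(-(d - r0)^2 / (2 * w^2))
    },
    halfplane = {
      th <- stats::runif(1, 0, 2 * pi)
      proj <- (yy - cy) * sin(th) + (xx - cx) * cos(th)
      1 / (1 + exp(-proj / (0.04 * span)))
    },
    stripe = {
      th <- stats::runif(1, 0, 2 * pi)
      w <- stats::runif(1, 0.07, 0.14) * span
      proj <- (yy - cy) * sin(th) + (xx - cx) * cos(th)
      exp(-proj^2 / (2 * w^2))
    },
    stopf("unknown pattern family %s", family))
  lo <- min(img); hi <- max(img)
  if (hi > lo) (img - lo) / (hi - lo) else img * 0
}

#' Generate a library of distinct spatial patterns
#'
#' Cycles through the families Gaussian blob, ring, half-plane and stripe
#' band at seeded random placements, each scaled to `[0, 1]`, resampling
#' placements until all pairwise Pearson correlations are at most
#' `max_corr`.
#'
#' @param shape `c(rows, cols)`, each `>= 16`.
#' @param n_patterns number of patterns (`<= 12`).
#' @param seed integer seed.
#' @param max_corr pairwise correlation ceiling (default 0.5).
#' @return list of `[0, 1]` matrices.
#' @export
generate_pattern_library <- function(shape, n_patterns, seed = 7L,
                                     max_corr = 0.5) {
  if (any(shape < 16L)) stopf("shape too small (< 16 x 16)")
  if (n_patterns > 12L) stopf("n_patterns must be <= 12")
  families <- c("blob", "ring", "halfplane", "stripe")
  with_seed(seed, {
    pats <- lapply(seq_len(n_patterns), function(i) {
      make_pattern(shape, families[((i - 1L) %% 4L) + 1L])
    })
    for (attempt in seq_len(200L)) {
      bad <- FALSE
      for (i in seq_len(n_patterns)) {
        others <- setdiff(seq_len(n_patterns), i)
        cors <- vapply(others, function(j) {
          stats::cor(as.numeric(pats[[i]]), as.numeric(pats[[j]]))
        }, numeric(1))
        if (length(cors) && max(cors) > max_corr) {
          pats[[i]] <- make_pattern(shape, families[((i - 1L) %% 4L) + 1L])
          bad <- TRUE
          break
        }
      }
      if (!bad) return(pats)
    }
    stopf("could not generate %d patterns with pairwise correlation <= %g",
          n_patterns, max_corr)
  })
}

#' Generate a synthetic MSI dataset with ground truth
#'
#' Each base channel is `amplitude * pattern + noise` (amplitude uniform in
#' `[0.5, 1.5]`, Gaussian noise clipped at zero). Selected base channels get
#' an isotope companion at exactly `mz + 1.003` Da with amplitude scaled by
#' `isotope_ratio`, the same pattern, and independent noise. Pure-noise
#' channels are clipped Gaussian noise with pattern label `-1`. Base and
#' noise channels sit on a jittered 2.4 Da grid, so no unintended mass
#' difference falls near 1.003 Da.
#'
#' @param config a [synthetic_config()].
#' @return list with `dataset` (an [msi_dataset()]), `truth` (class
#'   `ground_truth`: `pattern_label` per sorted channel, noise = -1;
#'   `isotope_pairs` two-column matrix of 1-based channel indices;
#'   `channel_table` data frame), and `patterns` (the pattern library).
#' @export
generate_msi_dataset <- function(config = synthetic_config()) {
  stopifnot(inherits(config, "synthetic_config"))
  n_base <- config$n_patterns * config$channels_per_pattern
  n_iso_per_pat <- round(config$channels_per_pattern * config$isotope_fraction)
  n_slots <- n_base + config$noise_channels
  grid <- seq(config$mz_range[1] + 1.2, config$mz_range[2] - 1.2, by = 2.4)
  if (length(grid) < n_slots) {
    stopf("mz_range too narrow for %d channels at 2.4 Da spacing", n_slots)
  }

  with_seed(config$seed, {
    patterns <- generate_pattern_library(config$shape, config$n_patterns,
                                         seed = NULL)
    slots <- sort(sample(grid, n_slots)) + stats::runif(n_slots, -0.05, 0.05)
    npx <- prod(config$shape)

    ch_mz <- numeric(0); ch_pat <- integer(0); ch_img <- list()
    partner_of <- integer(0)   # index of the base channel, 0 for none
    k <- 0L
    for (p in seq_len(config$n_patterns)) {
      for (cidx in seq_len(config$channels_per_pattern)) {
        k <- k + 1L
        amp <- stats::runif(1, 0.5, 1.5)
        base_img <- pmax(amp * patterns[[p]] +
                           stats::rnorm(npx, 0, config$noise_sigma), 0)
        ch_mz <- c(ch_mz, slots[k]); ch_pat <- c(ch_pat, p - 1L)
        partner_of <- c(partner_of, 0L)
        ch_img[[length(ch_img) + 1L]] <- base_img
        if (cidx <= n_iso_per_pat) {
          comp <- pmax(amp * config$isotope_ratio * patterns[[p]] +
                         stats::rnorm(npx, 0, config$noise_sigma), 0)
          ch_mz <- c(ch_mz, slots[k] + 1.003); ch_pat <- c(ch_pat, p - 1L)
          partner_of <- c(partner_of, length(ch_img))
          ch_img[[length(ch_img) + 1L]] <- comp
        }
      }
    }
    for (j in seq_len(config$noise_channels)) {
      k <- k + 1L
      ch_mz <- c(ch_mz, slots[k]); ch_pat <- c(ch_pat, -1L)
      partner_of <- c(partner_of, 0L)
      ch_img[[length(ch_img) + 1L]] <-
        pmax(stats::rnorm(npx, 0, config$noise_sigma), 0)
    }

    o <- order(ch_mz)
    rank_of <- match(seq_along(ch_mz), o)
    mz_axis <- ch_mz[o]
    pattern_label <- ch_pat[o]
    pairs <- which(partner_of > 0L)
    isotope_pairs <- cbind(i = rank_of[partner_of[pairs]],
                           j = rank_of[pairs])
    isotope_pairs <- isotope_pairs[order(isotope_pairs[, 1]), , drop = FALSE]

    intens <- matrix(0, npx, length(mz_axis))
    for (jj in seq_along(o)) intens[, jj] <- ch_img[[o[jj]]]

    # pixel order matches R's column-major matrix flattening: y varies
    # fastest, so intensity row i maps to image[y+1, x+1] exactly.
    cg <- expand.grid(y = 0:(config$shape[1] - 1L),
                      x = 0:(config$shape[2] - 1L))
    coords <- cbind(x = cg$x, y = cg$y)
    ds <- msi_dataset(coords, mz_axis, intens,
                      pixel_size_um = config$pixel_size_um,
                      meta = list(source = "synthetic",
                                  seed = as.character(config$seed)))
    channel_table <- data.frame(
      channel = seq_along(mz_axis), mz = mz_axis, pattern = pattern_label,
      partner_channel = vapply(seq_along(mz_axis), function(ch) {
        hit <- which(isotope_pairs[, 1] == ch | isotope_pairs[, 2] == ch)
        if (length(hit)) {
          pr <- isotope_pairs[hit[1], ]
          as.integer(if (pr[1] == ch) pr[2] else pr[1])
        } else NA_integer_
      }, integer(1)))
    truth <- structure(list(pattern_label = pattern_label,
                            isotope_pairs = isotope_pairs,
                            channel_table = channel_table),
                       class = "ground_truth")
    list(dataset = ds, truth = truth, patterns = patterns)
  })
}

#' Write the ground-truth channel table to CSV
#'
#' Header `channel,mz,pattern,partner_channel`; noise channels have pattern
#' `-1` and an empty partner.
#'
#' @param truth a `ground_truth` from [generate_msi_dataset()].
#' @param path output CSV path.
#' @return `path`, invisibly.
#' @export
write_ground_truth <- function(truth, path) {
  stopifnot(inherits(truth, "ground_truth"))
  utils::write.csv(truth$channel_table, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
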
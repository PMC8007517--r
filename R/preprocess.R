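# Shared preprocessing: spectral normalization/baseline correction, then
# per-ion-image upper winsorization and unit scaling.

#' Preprocessing configuration
#'
#' @param winsor_quantile upper winsorization quantile, in (0,1). Default
#'   0.95: intensities above the 95th percentile of each ion image are
#'   clipped; the lower tail is never clipped (intensities are bounded at 0).
#' @param baseline_window odd window width (in m/z bins, `>= 3`) for the
#'   running-median baseline. Only used when `baseline_enabled`.
#' @param tic_enabled normalize each spectrum to unit total ion current.
#' @param baseline_enabled apply median baseline correction (appropriate for
#'   profile-mode axes; off by default for centroided data).
#' @return object of class `preprocess_config`.
#' @export
preprocess_config <- function(winsor_quantile = 0.95, baseline_window = 51L,
                              tic_enabled = TRUE, baseline_enabled = FALSE) {
  if (!is.numeric(winsor_quantile) || winsor_quantile <= 0 ||
      winsor_quantile >= 1) {
    stopf("winsor_quantile must be in (0,1)")
  }
  if (!is_count(baseline_window) || baseline_window < 3 ||
      baseline_window %% 2 == 0) {
    stopf("baseline_window must be an odd integer >= 3")
  }
  structure(list(winsor_quantile = winsor_quantile,
                 baseline_window = as.integer(baseline_window),
                 tic_enabled = isTRUE(tic_enabled),
                 baseline_enabled = isTRUE(baseline_enabled)),
            class = "preprocess_config")
}

#' Total ion current normalization
#'
#' Divides a spectrum by its intensity sum so it sums to 1. An all-zero
#' spectrum is returned unchanged with a warning.
#'
#' @param spectrum non-negative intensity vector.
#' @return normalized intensity vector.
#' @export
tic_normalize <- function(spectrum) {
  if (any(spectrum < 0)) stopf("negative intensities")
  s <- sum(spectrum)
  if (s == 0) {
    warning("zero-TIC spectrum left unchanged")
    return(spectrum)
  }
  spectrum / s
}

#' Running-median baseline correction
#'
#' Estimates the baseline as the running median of width `window` (replicate
#' edge padding) and subtracts it, flooring at zero.
#'
#' @param spectrum intensity vector.
#' @param window odd window width in bins, `<= length(spectrum)`.
#' @return corrected intensity vector, `pmax(0, x - baseline)`.
#' @export
median_baseline_correct <- function(spectrum, window) {
  n <- length(spectrum)
  if (!is_count(window) || window %% 2 == 0 || window < 1) {
    stopf("window must be an odd positive integer")
  }
  if (window > n) stopf("window larger than spectrum")
  h <- (window - 1L) / 2L
  padded <- c(rep(spectrum[1], h), spectrum, rep(spectrum[n], h))
  baseline <- stats::runmed(padded, window, endrule = "keep")[(h + 1L):(h + n)]
  pmax(0, spectrum - baseline)
}

# quantile over the acquired pixels; type 7 = linear interpolation between
# order statistics, matching the common numeric-library default.
masked_quantile <- function(image, q) {
  v <- image$pixels[image$mask]
  if (length(v) == 0L) stopf("empty mask")
  stats::quantile(v, q, names = FALSE, type = 7)
}

#' Upper winsorization of an ion image
#'
#' Clips pixels above the `q` quantile of the acquired (masked-in) pixels to
#' that quantile. The lower tail is never clipped.
#'
#' @param image an [ion_image_new()].
#' @param q quantile in (0,1); default 0.95.
#' @return winsorized `ion_image`.
#' @export
winsorize_upper <- function(image, q = 0.95) {
  stopifnot(inherits(image, "ion_image"))
  if (q <= 0 || q >= 1) stopf("q must be in (0,1)")
  p <- masked_quantile(image, q)
  px <- image$pixels
  px[px > p] <- p
  ion_image_new(px, mz = image$mz, pixel_size_um = image$pixel_size_um,
                mask = image$mask)
}

#' Affine scaling of an ion image to [0, 1]
#'
#' Maps the acquired pixels' min to 0 and max to 1. A constant image (no
#' dynamic range) maps to all zeros rather than erroring, so blank channels
#' survive the pipeline.
#'
#' @param image an [ion_image_new()].
#' @return scaled `ion_image`.
#' @export
scale_unit <- function(image) {
  stopifnot(inherits(image, "ion_image"))
  v <- image$pixels[image$mask]
  if (length(v) == 0L) stopf("empty mask")
  lo <- min(v); hi <- max(v)
  px <- image$pixels
  if (hi > lo) {
    px[image$mask] <- (px[image$mask] - lo) / (hi - lo)
    px[!image$mask] <- 0
  } else {
    px[] <- 0
  }
  ion_image_new(px, mz = image$mz, pixel_size_um = image$pixel_size_um,
                mask = image$mask)
}

#' Standardize one ion image (winsorize then unit-scale)
#'
#' @param image an [ion_image_new()].
#' @param q winsorization quantile.
#' @return preprocessed `ion_image` with pixels in `[0, 1]`.
#' @export
standardize_image <- function(image, q = 0.95) {
  scale_unit(winsorize_upper(image, q))
}

#' Spectral preprocessing of a whole dataset
#'
#' Applies TIC normalization and (optionally) median baseline correction to
#' every pixel spectrum. Zero-TIC spectra are counted and reported in one
#' summary warning.
#'
#' @param dataset an [msi_dataset()].
#' @param config a [preprocess_config()].
#' @return preprocessed [msi_dataset()].
#' @export
preprocess_spectra <- function(dataset, config = preprocess_config()) {
  stopifnot(inherits(dataset, "msi_dataset"),
            inherits(config, "preprocess_config"))
  intens <- dataset$intensities
  n_zero <- 0L
  if (config$tic_enabled) {
    tic <- rowSums(intens)
    n_zero <- sum(tic == 0)
    nz <- tic > 0
    intens[nz, ] <- intens[nz, , drop = FALSE] / tic[nz]
  }
  if (config$baseline_enabled) {
    w <- min(config$baseline_window,
             if (ncol(intens) %% 2 == 1) ncol(intens) else ncol(intens) - 1L)
    if (w >= 3) {
      intens <- t(apply(intens, 1, median_baseline_correct, window = w))
    }
  }
  if (n_zero > 0) {
    warning(sprintf("%d zero-TIC spectra left unchanged", n_zero))
  }
  msi_dataset(dataset$coords, dataset$mz_axis, intens,
              pixel_size_um = dataset$pixel_size_um,
              meta = c(dataset$meta, list(preprocessed = "tic/baseline")))
}
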
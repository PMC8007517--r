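#' MSI dataset container
#'
#' An `msi_dataset` holds one mass spectrometry imaging acquisition as a
#' pixel grid, a common m/z axis, and one intensity vector per pixel.
#' Processed-mode (per-spectrum centroid) data is binned onto a common axis
#' at load time; continuous-mode data keeps its acquisition axis.
#'
#' @param coords integer matrix with columns `x`, `y`: 0-based grid
#'   positions, one row per acquired pixel. Rows must be unique.
#' @param mz_axis strictly increasing numeric vector of m/z values (Da).
#' @param intensities numeric matrix, `nrow(coords)` rows by
#'   `length(mz_axis)` columns, non-negative.
#' @param pixel_size_um positive scalar, physical pixel pitch in micrometers.
#' @param meta named list of free-form provenance strings.
#' @return An object of class `msi_dataset`.
#' @export
msi_dataset <- function(coords, mz_axis, intensities, pixel_size_um = 1,
                        meta = list()) {
  coords <- as.matrix(coords)
  storage.mode(coords) <- "integer"
  if (ncol(coords) != 2L) stopf("coords must have two columns (x, y)")
  colnames(coords) <- c("x", "y")
  if (anyDuplicated(paste(coords[, 1], coords[, 2]))) {
    stopf("duplicate pixel coordinates")
  }
  mz_axis <- as.numeric(mz_axis)
  if (length(mz_axis) == 0L) stopf("empty m/z axis")
  if (any(diff(mz_axis) <= 0)) stopf("mz_axis must be strictly increasing")
  intensities <- as.matrix(intensities)
  if (nrow(intensities) != nrow(coords) ||
      ncol(intensities) != length(mz_axis)) {
    stopf("intensities must be %d x %d", nrow(coords), length(mz_axis))
  }
  if (any(intensities < 0)) stopf("negative intensities")
  if (!is.numeric(pixel_size_um) || length(pixel_size_um) != 1L ||
      !is.finite(pixel_size_um) || pixel_size_um <= 0) {
    stopf("pixel_size_um must be a positive scalar")
  }
  structure(
    list(coords = coords, mz_axis = mz_axis, intensities = intensities,
         pixel_size_um = as.numeric(pixel_size_um), meta = meta),
    class = "msi_dataset"
  )
}

#' @export
print.msi_dataset <- function(x, ...) {
  cat(sprintf(
    "<msi_dataset> %d pixels, %d m/z channels [%.4f..%.4f Da], %.3g um pitch\n",
    nrow(x$coords), length(x$mz_axis), min(x$mz_axis), max(x$mz_axis),
    x$pixel_size_um))
  invisible(x)
}

#' Ion image container
#'
#' One 2-D intensity map for one m/z bin. Row 1 corresponds to the smallest
#' acquired y coordinate, column 1 to the smallest x. Pixels outside the
#' acquisition mask are zero.
#'
#' @param pixels non-negative numeric matrix (rows x cols).
#' @param mz m/z value of the channel (Da); may be `NA` for derived images
#'   such as cluster means.
#' @param pixel_size_um positive pixel pitch in micrometers.
#' @param mask logical matrix of acquired pixels, same shape as `pixels`.
#'   Defaults to all `TRUE`.
#' @return An object of class `ion_image`.
#' @export
ion_image_new <- function(pixels, mz = NA_real_, pixel_size_um = 1,
                          mask = NULL) {
  pixels <- as.matrix(pixels)
  if (is.null(mask)) mask <- matrix(TRUE, nrow(pixels), ncol(pixels))
  mask <- as.matrix(mask)
  if (!identical(dim(pixels), dim(mask))) stopf("pixels/mask shape mismatch")
  if (any(pixels[!mask] != 0)) stopf("pixels outside mask must be 0")
  structure(
    list(pixels = pixels, mz = as.numeric(mz),
         pixel_size_um = as.numeric(pixel_size_um),
         mask = matrix(as.logical(mask), nrow(mask), ncol(mask))),
    class = "ion_image"
  )
}

#' @export
print.ion_image <- function(x, ...) {
  cat(sprintf("<ion_image> %d x %d px, m/z %s, %.3g um pitch, %d masked-in\n",
              nrow(x$pixels), ncol(x$pixels),
              if (is.na(x$mz)) "NA" else sprintf("%.4f", x$mz),
              x$pixel_size_um, sum(x$mask)))
  invisible(x)
}

#' Materialize the ion image of one mass bin
#'
#' Sums, per pixel, the intensities of all axis entries within `tol` of
#' `mz`, and arranges them on the acquisition grid. Grid positions that were
#' never acquired are masked out and set to zero.
#'
#' @param dataset an [msi_dataset()].
#' @param mz target m/z (Da).
#' @param tol half-width of the mass bin (Da, `>= 0`). Defaults to half the
#'   median axis spacing (or 0 for a single-channel axis), which avoids
#'   empty selections on centroided axes.
#' @return An [ion_image_new()] object.
#' @export
ion_image <- function(dataset, mz, tol = NULL) {
  stopifnot(inherits(dataset, "msi_dataset"))
  if (is.null(tol)) {
    tol <- if (length(dataset$mz_axis) > 1L) {
      stats::median(diff(dataset$mz_axis)) / 2
    } else 0
  }
  if (tol < 0) stopf("tol must be >= 0")
  sel <- which(abs(dataset$mz_axis - mz) <= tol)
  if (length(sel) == 0L) {
    stopf("no m/z axis entry within %.4g Da of %.4f", tol, mz)
  }
  vals <- if (length(sel) == 1L) dataset$intensities[, sel]
          else rowSums(dataset$intensities[, sel, drop = FALSE])
  grid_image(dataset, vals, mz = mean(dataset$mz_axis[sel]))
}

# Place one value per acquired pixel onto the (row = y, col = x) grid.
grid_image <- function(dataset, values, mz = NA_real_) {
  x <- dataset$coords[, 1]; y <- dataset$coords[, 2]
  nr <- max(y) - min(y) + 1L
  nc <- max(x) - min(x) + 1L
  px <- matrix(0, nr, nc)
  mk <- matrix(FALSE, nr, nc)
  idx <- cbind(y - min(y) + 1L, x - min(x) + 1L)
  px[idx] <- values
  mk[idx] <- TRUE
  ion_image_new(px, mz = mz, pixel_size_um = dataset$pixel_size_um, mask = mk)
}

#' All per-channel ion images of a dataset
#'
#' Convenience wrapper that materializes every axis channel at `tol = 0`.
#'
#' @param dataset an [msi_dataset()].
#' @return list of [ion_image_new()] objects, one per `mz_axis` entry.
#' @export
channel_images <- function(dataset) {
  lapply(seq_along(dataset$mz_axis), function(j) {
    grid_image(dataset, dataset$intensities[, j], mz = dataset$mz_axis[j])
  })
}
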
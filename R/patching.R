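# Patch planning and extraction. Square overlapping patches at a target
# physical size; ion images sampled coarser than the embedder's minimum
# input are upsampled by an integer factor first, which shrinks the
# effective pixel pitch but preserves each patch's physical extent.

#' Plan an overlapping patch grid
#'
#' The patch side starts from the physical target:
#' `side0 = round(target_mm * 1000 / pixel_size_um)` pixels. If `side0`
#' falls below the embedder's minimum input side, the image is upsampled by
#' `ceil(min_side / side0)` so the patch keeps its physical size at a finer
#' pitch. The stride is `ceil(side_px * (1 - overlap_target))`, which with
#' the default `overlap_target = 0.5` realizes the 40-50% patch overlap
#' band. Start offsets run at stride multiples, with the final start clamped
#' so the last patch abuts the image border (extra overlap at the edge
#' instead of padding or cropping).
#'
#' @param image_shape integer vector `c(rows, cols)` of the native image.
#' @param pixel_size_um native pixel pitch (micrometers).
#' @param target_mm target physical patch side (mm); 1-2 mm works well in
#'   practice, default 1.5.
#' @param min_side minimum patch side accepted by the embedder (pixels).
#' @param overlap_target fractional overlap aimed for between neighboring
#'   patches, default 0.5.
#' @return object of class `patch_grid`: `side_px`, `upsample_factor`,
#'   `stride_px`, `row_starts`, `col_starts` (0-based, upsampled space),
#'   `effective_pitch_um`, `input_shape`, `upsampled_shape`, `pad`
#'   (TRUE when the image is smaller than one patch and must be
#'   reflect-padded).
#' @export
plan_patch_grid <- function(image_shape, pixel_size_um, target_mm = 1.5,
                            min_side = 71L, overlap_target = 0.5) {
  if (target_mm <= 0) stopf("target_mm must be > 0")
  if (!is_count(min_side) || min_side < 1) stopf("min_side must be >= 1")
  image_shape <- as.integer(image_shape)
  if (length(image_shape) != 2L || any(image_shape < 2L)) {
    stopf("image must be at least 2 x 2")
  }
  side0 <- round(target_mm * 1000 / pixel_size_um)
  if (side0 < 1) side0 <- 1
  upsample <- if (side0 >= min_side) 1L else as.integer(ceiling(min_side / side0))
  side_px <- as.integer(side0 * upsample)
  stride_px <- as.integer(ceiling(side_px * (1 - overlap_target)))
  up_shape <- image_shape * upsample

  pad <- any(up_shape < side_px)
  starts_along <- function(extent) {
    if (extent <= side_px) return(0L)
    s <- seq.int(0L, extent - side_px, by = stride_px)
    if (s[length(s)] < extent - side_px) s <- c(s, extent - side_px)
    s
  }
  if (pad) {
    warning(sprintf(
      "image (%d x %d upsampled) smaller than one %d-px patch; reflect-pad to a single patch",
      up_shape[1], up_shape[2], side_px))
  }
  structure(
    list(side_px = side_px, upsample_factor = upsample,
         stride_px = stride_px,
         row_starts = starts_along(up_shape[1]),
         col_starts = starts_along(up_shape[2]),
         effective_pitch_um = pixel_size_um / upsample,
         input_shape = image_shape, upsampled_shape = as.integer(up_shape),
         target_mm = target_mm, side0 = as.integer(side0), pad = pad),
    class = "patch_grid")
}

#' @export
print.patch_grid <- function(x, ...) {
  cat(sprintf(
    "<patch_grid> side %d px (x%d upsampled), stride %d, %d x %d patches, %.3g um effective pitch\n",
    x$side_px, x$upsample_factor, x$stride_px,
    length(x$row_starts), length(x$col_starts), x$effective_pitch_um))
  invisible(x)
}

# Bilinear resampling with half-pixel centers: output pixel i samples input
# coordinate (i + 0.5) * in/out - 0.5, clamped to the input range.
resize_bilinear <- function(x, out_r, out_c) {
  in_r <- nrow(x); in_c <- ncol(x)
  coord <- function(n_out, n_in) {
    pmin(pmax((seq_len(n_out) - 0.5) * n_in / n_out - 0.5, 0), n_in - 1)
  }
  ry <- coord(out_r, in_r); cx <- coord(out_c, in_c)
  y0 <- pmin(floor(ry), in_r - 1); y1 <- pmin(y0 + 1, in_r - 1)
  x0 <- pmin(floor(cx), in_c - 1); x1 <- pmin(x0 + 1, in_c - 1)
  wy <- ry - y0; wx <- cx - x0
  # gather four corners via index matrices
  g <- function(yi, xi) x[cbind(rep(yi + 1, times = out_c),
                                rep(xi + 1, each = out_r))]
  v <- (1 - wy) %o% (1 - wx) * matrix(g(y0, x0), out_r, out_c) +
       (1 - wy) %o% wx       * matrix(g(y0, x1), out_r, out_c) +
       wy %o% (1 - wx)       * matrix(g(y1, x0), out_r, out_c) +
       wy %o% wx             * matrix(g(y1, x1), out_r, out_c)
  v
}

#' Integer upsampling of an image
#'
#' Bilinear interpolation with half-pixel centers; output shape is `factor`
#' times the input shape on each axis.
#'
#' @param image numeric matrix or [ion_image_new()].
#' @param factor positive integer upsampling factor.
#' @param method `"bilinear"` (only option).
#' @return same type as `image`; an `ion_image` gets its `pixel_size_um`
#'   divided by `factor` and its mask nearest-neighbor upsampled.
#' @export
upsample_image <- function(image, factor, method = "bilinear") {
  if (!is_count(factor) || factor < 1) stopf("factor must be a positive integer")
  method <- match.arg(method, "bilinear")
  if (inherits(image, "ion_image")) {
    if (factor == 1L) return(image)
    px <- resize_bilinear(image$pixels, nrow(image$pixels) * factor,
                          ncol(image$pixels) * factor)
    mk <- image$mask[rep(seq_len(nrow(image$mask)), each = factor),
                     rep(seq_len(ncol(image$mask)), each = factor)]
    px[!mk] <- 0
    return(ion_image_new(px, mz = image$mz,
                         pixel_size_um = image$pixel_size_um / factor,
                         mask = mk))
  }
  if (factor == 1L) return(image)
  resize_bilinear(as.matrix(image), nrow(image) * factor,
                  ncol(image) * factor)
}

# Reflect-pad a matrix on the bottom/right up to (r, c).
reflect_pad <- function(x, r, c) {
  if (nrow(x) < r) {
    need <- r - nrow(x)
    idx <- rev(seq_len(nrow(x)))[seq_len(min(need, nrow(x)))]
    while (length(idx) < need) idx <- c(idx, rev(idx))[seq_len(need)]
    x <- rbind(x, x[idx, , drop = FALSE])
  }
  if (ncol(x) < c) {
    need <- c - ncol(x)
    idx <- rev(seq_len(ncol(x)))[seq_len(min(need, ncol(x)))]
    while (length(idx) < need) idx <- c(idx, rev(idx))[seq_len(need)]
    x <- cbind(x, x[, idx, drop = FALSE])
  }
  x
}

#' Extract the patches of a planned grid
#'
#' @param image numeric matrix in upsampled space (or an `ion_image` whose
#'   pixel matrix is used), with shape `grid$upsampled_shape`.
#' @param grid a [plan_patch_grid()] result for this image.
#' @return list of `side_px` x `side_px` matrices, ordered row-major by
#'   (row_start, col_start).
#' @export
extract_patches <- function(image, grid) {
  stopifnot(inherits(grid, "patch_grid"))
  x <- if (inherits(image, "ion_image")) image$pixels else as.matrix(image)
  if (!identical(dim(x), as.integer(grid$upsampled_shape))) {
    stopf("image shape (%d x %d) does not match grid's upsampled shape (%d x %d)",
          nrow(x), ncol(x), grid$upsampled_shape[1], grid$upsampled_shape[2])
  }
  if (grid$pad) x <- reflect_pad(x, grid$side_px, grid$side_px)
  out <- vector("list", length(grid$row_starts) * length(grid$col_starts))
  k <- 1L
  for (r0 in grid$row_starts) {
    for (c0 in grid$col_starts) {
      out[[k]] <- x[(r0 + 1L):(r0 + grid$side_px),
                    (c0 + 1L):(c0 + grid$side_px), drop = FALSE]
      k <- k + 1L
    }
  }
  out
}
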
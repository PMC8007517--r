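# Embedders turn one preprocessed patch (values in [0,1]) into one
# fixed-length feature vector; a neural ion image is the elementwise max of
# the patch vectors over all patches of one ion image.

#' Construct an embedder
#'
#' An embedder is a deterministic function from a square patch (values in
#' `[0, 1]`) to a fixed-length feature vector. Identical patches always
#' yield identical vectors.
#'
#' @param name identifier string.
#' @param dim output vector length.
#' @param min_side minimum accepted patch side in pixels.
#' @param fn function(matrix) -> numeric(dim).
#' @return object of class `embedder`.
#' @export
embedder <- function(name, dim, min_side, fn) {
  stopifnot(is.character(name), is_count(dim), is_count(min_side),
            is.function(fn))
  structure(list(name = name, dim = as.integer(dim),
                 min_side = as.integer(min_side), fn = fn),
            class = "embedder")
}

#' @export
print.embedder <- function(x, ...) {
  cat(sprintf("<embedder> %s: dim %d, min side %d px\n",
              x$name, x$dim, x$min_side))
  invisible(x)
}

#' Embed one patch
#'
#' @param emb an [embedder()].
#' @param patch square numeric matrix, values in `[0, 1]`.
#' @return numeric vector of length `emb$dim`.
#' @export
embed_patch <- function(emb, patch) {
  stopifnot(inherits(emb, "embedder"))
  patch <- as.matrix(patch)
  if (min(dim(patch)) < emb$min_side) {
    stopf("patch side %d below embedder minimum %d", min(dim(patch)),
          emb$min_side)
  }
  v <- emb$fn(patch)
  if (length(v) != emb$dim) stopf("embedder returned wrong length")
  v
}

block_means <- function(x, g) {
  # mean over a g x g partition of x (dims divisible by g), row-major blocks
  br <- nrow(x) %/% g; bc <- ncol(x) %/% g
  out <- numeric(g * g)
  k <- 1L
  for (bi in seq_len(g)) {
    for (bj in seq_len(g)) {
      out[k] <- mean(x[((bi - 1L) * br + 1L):(bi * br),
                       ((bj - 1L) * bc + 1L):(bj * bc)])
      k <- k + 1L
    }
  }
  out
}

#' Reference patch embedder (dim 101)
#'
#' A fast, dependency-free, fully deterministic embedder honoring the
#' embedder contract; the default for tests and for machines without the
#' convolutional backbone. The patch is resized to 32 x 32 (bilinear,
#' half-pixel centers); the feature vector concatenates block means over
#' 1x1, 2x2, 4x4 and 8x8 partitions (85 values: a multiscale intensity
#' pyramid) with block means of the central-difference gradient magnitude
#' over a 4x4 partition (16 values capturing local structure).
#'
#' @return an [embedder()] with `dim = 101`, `min_side = 8`.
#' @export
reference_embedder <- function() {
  fn <- function(patch) {
    if (any(patch < -1e-9) || any(patch > 1 + 1e-9)) {
      stopf("patch values must lie in [0,1] (preprocess first)")
    }
    p <- resize_bilinear(patch, 32L, 32L)
    pyramid <- unlist(lapply(c(1L, 2L, 4L, 8L), function(g) block_means(p, g)))
    # central differences with replicate edges
    gx <- (p[, c(2:32, 32)] - p[, c(1, 1:31)]) / 2
    gy <- (p[c(2:32, 32), ] - p[c(1, 1:31), ]) / 2
    grad <- sqrt(gx^2 + gy^2)
    c(pyramid, block_means(grad, 4L))
  }
  embedder("reference", 101L, 8L, fn)
}

# plain 2-D convolution (valid, strided) via im2col; x is h x w x cin,
# w_arr is k x k x cin x cout. Returns h' x w' x cout array.
conv2d <- function(x, w_arr, stride = 1L) {
  k <- dim(w_arr)[1]; cin <- dim(w_arr)[3]; cout <- dim(w_arr)[4]
  h <- dim(x)[1]; w <- dim(x)[2]
  ro <- seq(1L, h - k + 1L, by = stride)
  co <- seq(1L, w - k + 1L, by = stride)
  npos <- length(ro) * length(co)
  cols <- matrix(0, npos, k * k * cin)
  pos <- 1L
  for (cc in co) {
    for (rr in ro) {
      cols[pos, ] <- as.numeric(x[rr:(rr + k - 1L), cc:(cc + k - 1L), ,
                                  drop = FALSE])
      pos <- pos + 1L
    }
  }
  wm <- matrix(w_arr, k * k * cin, cout)
  array(cols %*% wm, dim = c(length(ro), length(co), cout))
}

#' Convolutional backbone embedder (dim 2048)
#'
#' Adapter for the pretrained-CNN branch of the pipeline: grayscale patches
#' are replicated to 3 channels, mapped from `[0, 1]` to `[-1, 1]`, pushed
#' through a convolutional feature extractor whose final stage has 2048
#' channels, and globally average-pooled to a single 2048-vector. Pretrained
#' weights require a deep-learning runtime that this package does not ship;
#' `weights = "random"` instantiates the same architecture with
#' deterministic He-initialized random weights (fixed internal seed), which
#' preserves every interface contract (dim 2048, minimum input side 71,
#' bit-reproducible outputs) and is clearly a synthetic stand-in for the
#' pretrained feature extractor.
#'
#' @param weights `"random"` (deterministic random initialization) or
#'   `"pretrained"` (errors: no deep-learning runtime available; use the
#'   [reference_embedder()] or install a backbone runtime).
#' @return an [embedder()] with `dim = 2048`, `min_side = 71`.
#' @export
backbone_embedder <- function(weights = c("random", "pretrained")) {
  weights <- match.arg(weights)
  if (weights == "pretrained") {
    stopf(paste("pretrained backbone weights require a deep-learning runtime",
                "that is not installed; use reference_embedder() instead"))
  }
  he <- function(k, cin, cout) {
    array(stats::rnorm(k * k * cin * cout, sd = sqrt(2 / (k * k * cin))),
          dim = c(k, k, cin, cout))
  }
  w <- with_seed(20481103, list(
    he(3L, 3L, 8L),     # entry conv, stride 2
    he(3L, 8L, 16L),    # stride 2
    he(3L, 16L, 32L),   # stride 2
    he(1L, 32L, 2048L)  # 1x1 projection to the 2048-channel feature map
  ))
  fn <- function(patch) {
    if (any(patch < -1e-9) || any(patch > 1 + 1e-9)) {
      stopf("patch values must lie in [0,1] (preprocess first)")
    }
    p <- 2 * patch - 1                       # [0,1] -> [-1,1]
    x <- array(rep(p, 3L), dim = c(dim(patch), 3L))  # gray -> RGB
    relu <- function(a) { a[a < 0] <- 0; a }
    x <- relu(conv2d(x, w[[1]], stride = 2L))
    x <- relu(conv2d(x, w[[2]], stride = 2L))
    x <- relu(conv2d(x, w[[3]], stride = 2L))
    x <- conv2d(x, w[[4]], stride = 1L)
    # global average pooling over the spatial axes
    apply(x, 3, mean)
  }
  embedder("backbone-random", 2048L, 71L, fn)
}

#' Max-pool aggregation of patch embeddings
#'
#' Elementwise maximum across patch vectors: coordinate k of the result
#' records whether feature k fired in *any* patch, which keeps the neural
#' ion image sensitive to localized structure.
#'
#' @param patch_vectors non-empty list of equal-length numeric vectors.
#' @return numeric vector of the common length.
#' @export
aggregate_max <- function(patch_vectors) {
  if (length(patch_vectors) == 0L) stopf("empty patch vector list")
  lens <- lengths(patch_vectors)
  if (length(unique(lens)) != 1L) stopf("ragged patch vectors")
  Reduce(pmax, patch_vectors)
}

#' Embed one ion image into a neural ion image
#'
#' Upsamples the (preprocessed) image per the grid, extracts the planned
#' overlapping patches, embeds each, and max-pools the patch vectors.
#'
#' @param image preprocessed [ion_image_new()] (winsorized, unit-scaled:
#'   values in `[0, 1]`).
#' @param grid [plan_patch_grid()] result for this image's shape.
#' @param emb an [embedder()].
#' @return a [neural_ion_image()].
#' @export
embed_ion_image <- function(image, grid, emb) {
  stopifnot(inherits(image, "ion_image"), inherits(grid, "patch_grid"),
            inherits(emb, "embedder"))
  up <- if (grid$upsample_factor > 1L) {
    resize_bilinear(image$pixels, nrow(image$pixels) * grid$upsample_factor,
                    ncol(image$pixels) * grid$upsample_factor)
  } else image$pixels
  up[up < 0] <- 0; up[up > 1] <- 1   # guard bilinear overshoot at mask edges
  patches <- extract_patches(up, grid)
  vecs <- lapply(patches, function(p) embed_patch(emb, p))
  prov <- sprintf("embedder=%s;dim=%d;side_px=%d;stride_px=%d;upsample=%d",
                  emb$name, emb$dim, grid$side_px, grid$stride_px,
                  grid$upsample_factor)
  neural_ion_image(aggregate_max(vecs), mz = image$mz, provenance = prov)
}

#' Embed every ion image of a dataset
#'
#' Plans one patch grid from the shared image shape and embeds each channel
#' image (after winsorization and unit scaling unless `preprocessed`).
#'
#' @param images list of [ion_image_new()] with identical shapes.
#' @param emb an [embedder()]; default [reference_embedder()].
#' @param target_mm physical patch side (mm).
#' @param overlap_target fractional patch overlap.
#' @param preprocessed set `TRUE` when images are already winsorized and
#'   unit-scaled.
#' @param winsor_quantile quantile used when preprocessing here.
#' @return an `nii_bundle` (vectors matrix, mz, provenance).
#' @export
embed_dataset <- function(images, emb = reference_embedder(),
                          target_mm = 1.5, overlap_target = 0.5,
                          preprocessed = FALSE, winsor_quantile = 0.95) {
  stopifnot(length(images) > 0L)
  shp <- dim(images[[1]]$pixels)
  grid <- plan_patch_grid(shp, images[[1]]$pixel_size_um,
                          target_mm = target_mm, min_side = emb$min_side,
                          overlap_target = overlap_target)
  nii <- lapply(images, function(im) {
    if (!preprocessed) im <- standardize_image(im, winsor_quantile)
    embed_ion_image(im, grid, emb)
  })
  structure(
    list(vectors = do.call(rbind, lapply(nii, `[[`, "vector")),
         mz = vapply(nii, `[[`, numeric(1), "mz"),
         provenance = unique(vapply(nii, `[[`, character(1), "provenance"))),
    class = "nii_bundle")
}
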
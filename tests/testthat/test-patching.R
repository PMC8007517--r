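test_that("plan_patch_grid reproduces the printed patch geometries", {
  # 10 um pitch, 1.5 mm target: 150 px, no upsampling
  g <- plan_patch_grid(c(1183, 696), 10, target_mm = 1.5, min_side = 71)
  expect_equal(g$side_px, 150L)
  expect_equal(g$upsample_factor, 1L)
  # 50 um pitch, 1.85 mm target: side0 37 < 71 -> x2 upsample, 74 px
  g2 <- plan_patch_grid(c(300, 200), 50, target_mm = 1.85, min_side = 71)
  expect_equal(g2$side0, 37L)
  expect_equal(g2$upsample_factor, 2L)
  expect_equal(g2$side_px, 74L)
  expect_equal(g2$side_px * g2$effective_pitch_um, 1850)  # physical side kept
  # exact boundary: no upsampling needed
  g3 <- plan_patch_grid(c(200, 200), 20, target_mm = 1.42, min_side = 71)
  expect_equal(g3$side_px, 71L)
  expect_equal(g3$upsample_factor, 1L)
})

test_that("patch grids cover the image with 40-50% overlap and clamp the last start", {
  for (case in list(c(100, 120, 30), c(64, 64, 17), c(200, 90, 41))) {
    shp <- case[1:2]; pitch <- 10; target <- case[3] * pitch / 1000
    g <- plan_patch_grid(shp, pitch, target_mm = target, min_side = 8)
    for (starts_extent in list(list(g$row_starts, g$upsampled_shape[1]),
                               list(g$col_starts, g$upsampled_shape[2]))) {
      s <- starts_extent[[1]]; e <- starts_extent[[2]]
      expect_equal(s[length(s)] + g$side_px, e)  # last patch abuts border
      covered <- rep(FALSE, e)
      for (st in s) covered[(st + 1):(st + g$side_px)] <- TRUE
      expect_true(all(covered))
    }
    ov <- (g$side_px - g$stride_px) / g$side_px
    expect_gte(ov, 0.40); expect_lte(ov, 0.50)
  }
  # overlap band property under stride = ceil(side/2), sides >= 4
  for (side in 4:200) {
    stride <- ceiling(side * 0.5)
    ov <- (side - stride) / side
    expect_gte(ov, 0.40); expect_lte(ov, 0.50)
  }
})

test_that("images smaller than one patch trigger the reflect-pad single-patch path", {
  expect_warning(
    g <- plan_patch_grid(c(20, 20), 10, target_mm = 0.5, min_side = 71),
    "reflect-pad")
  expect_true(g$pad)
  expect_equal(length(g$row_starts) * length(g$col_starts), 1L)
  up <- upsample_image(matrix(runif(400), 20, 20), g$upsample_factor)
  patches <- extract_patches(up, g)
  expect_length(patches, 1L)
  expect_equal(dim(patches[[1]]), c(g$side_px, g$side_px))
  # padded region mirrors the interior, never fabricates new values
  expect_true(all(patches[[1]] %in% up))
})

test_that("upsample_image is bilinear with half-pixel centers", {
  x <- matrix(runif(20), 4, 5)
  expect_identical(upsample_image(x, 1L), x)
  expect_equal(upsample_image(matrix(3, 1, 1), 2L), matrix(3, 2, 2))
  expect_error(upsample_image(x, 0L), "positive integer")
  # pinned against the independent loop-based resampler
  for (f in c(2L, 3L)) {
    expect_equal(upsample_image(x, f),
                 oracle_bilinear(x, 4L * f, 5L * f), tolerance = 1e-12)
  }
  expect_equal(upsample_image(matrix(c(0, 1), 1, 2), 2L),
               oracle_bilinear(matrix(c(0, 1), 1, 2), 2L, 4L))
})

test_that("extract_patches slices row-major with exact contents", {
  x <- matrix(seq_len(100), 10, 10)
  g <- plan_patch_grid(c(10, 10), 10, target_mm = 0.04, min_side = 4)
  expect_equal(g$side_px, 4L)
  expect_equal(g$stride_px, 2L)
  expect_equal(g$row_starts, c(0L, 2L, 4L, 6L))
  patches <- extract_patches(x, g)
  expect_length(patches, 16L)
  expect_equal(patches[[1]], x[1:4, 1:4])           # (0,0) patch
  expect_equal(patches[[2]], x[1:4, 3:6])           # row-major ordering
  expect_equal(patches[[16]], x[7:10, 7:10])
  # single patch equal to the whole image
  g1 <- plan_patch_grid(c(10, 10), 10, target_mm = 0.1, min_side = 4)
  expect_equal(extract_patches(x, g1)[[1]], x)
  expect_error(extract_patches(x[1:9, ], g), "shape")
})
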
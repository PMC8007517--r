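test_that("continuous imzML round-trips coords exactly and intensities to float32", {
  ds <- tiny_dataset()
  path <- file.path(withr::local_tempdir(), "tiny.imzML")
  write_imzml(ds, path)
  back <- read_imzml(path)
  expect_equal(nrow(back$coords), 4L)
  expect_identical(back$coords, ds$coords)
  expect_length(back$mz_axis, 3L)
  expect_equal(back$mz_axis, ds$mz_axis)  # float64 storage: exact
  expect_equal(back$intensities, ds$intensities, tolerance = 1e-6)
  expect_equal(back$pixel_size_um, 10)

  # synthetic dataset round-trip (property from the module contract)
  sim <- default_sim()
  p2 <- file.path(withr::local_tempdir(), "sim.imzML")
  write_imzml(sim$dataset, p2)
  b2 <- read_imzml(p2)
  expect_identical(b2$coords, sim$dataset$coords)
  expect_equal(b2$intensities, sim$dataset$intensities, tolerance = 1e-6)
})

test_that("processed-mode peaks are greedily binned on load", {
  # two spectra listing near-identical peaks must share one axis entry
  coords <- cbind(x = 0:1, y = c(0L, 0L))
  ds <- msi_dataset(coords, c(700.001, 700.002),
                    rbind(c(5, 0), c(0, 7)), pixel_size_um = 5)
  path <- file.path(withr::local_tempdir(), "proc.imzML")
  write_imzml(ds, path, mode = "processed")
  back <- read_imzml(path, bin_tol = 0.01)
  expect_length(back$mz_axis, 1L)
  expect_equal(back$mz_axis, mean(c(700.001, 700.002)))
  expect_equal(as.numeric(back$intensities), c(5, 7), tolerance = 1e-6)

  # greedy binning equals the brute-force rule on a random peak list
  set.seed(3)
  mzv <- sort(runif(40, 700, 701))
  b <- greedy_bin(mzv, 0.02)
  # oracle: walk sorted values, split where gap > tol
  splits <- cumsum(c(1, as.integer(diff(mzv) > 0.02)))
  expect_equal(b$centers, as.numeric(tapply(mzv, splits, mean)))
})

test_that("imzML error paths: empty file, missing ibd", {
  d <- withr::local_tempdir()
  empty <- file.path(d, "empty.imzML")
  file.create(empty)
  file.create(file.path(d, "empty.ibd"))
  expect_error(read_imzml(empty), "empty file")
  ds <- tiny_dataset()
  p <- file.path(d, "ok.imzML")
  write_imzml(ds, p)
  unlink(file.path(d, "ok.ibd"))
  expect_error(read_imzml(p), "ibd")
})

test_that("ion_image selects, sums and masks per the bin rule", {
  ds <- tiny_dataset()
  # tol 0 at an exact axis value -> that channel
  im <- ion_image(ds, 700, tol = 0)
  expect_equal(im$pixels, rbind(c(1, 4), c(7, 10)))
  # two axis entries within tol -> per-pixel sum (linearity)
  im2 <- ion_image(ds, 700.5, tol = 0.6)
  expect_equal(im2$pixels,
               ion_image(ds, 700, tol = 0)$pixels +
                 ion_image(ds, 701.003, tol = 0)$pixels)
  # empty selection errors
  expect_error(ion_image(ds, 650, tol = 0.1), "no m/z axis entry")
  # missing interior pixel is masked and zero
  ds2 <- msi_dataset(cbind(x = c(0L, 1L, 0L), y = c(0L, 0L, 1L)),
                     700, cbind(c(1, 2, 3)), pixel_size_um = 1)
  im3 <- ion_image(ds2, 700, tol = 0)
  expect_false(im3$mask[2, 2])
  expect_equal(im3$pixels[2, 2], 0)
})

test_that("assignments CSV round-trips, writes -1, rejects bad input", {
  d <- withr::local_tempdir()
  p <- file.path(d, "a.csv")
  write_assignments(c(0L, -1L, 2L), c(700.1, 701.2, 702.3), p)
  expect_true(any(grepl(",-1$", readLines(p))))
  back <- read_assignments(p)
  expect_equal(back$labels, c(0L, -1L, 2L))
  expect_equal(back$mzs, c(700.1, 701.2, 702.3))
  writeLines(c("mass,clu", "1,2"), p)
  expect_error(read_assignments(p), "header")
  writeLines(c("mz,cluster", "700,1", "700,2"), p)
  expect_error(read_assignments(p), "duplicate")
})

test_that("vectors bundle round-trips bit-exactly and validates", {
  d <- withr::local_tempdir()
  p <- file.path(d, "v.h5")
  nii <- list(neural_ion_image(runif(101), 700.1, "emb=test"),
              neural_ion_image(runif(101), 701.2, "emb=test"))
  write_vectors(nii, p)
  back <- read_vectors(p)
  expect_equal(dim(back$vectors), c(2L, 101L))
  expect_identical(back$vectors[1, ], nii[[1]]$vector)
  expect_identical(back$mz, c(700.1, 701.2))
  expect_error(write_vectors(list(
    neural_ion_image(1:3), neural_ion_image(1:4)), p), "ragged")
  # bundle missing the m/z list is a format error
  p2 <- file.path(d, "bad.h5")
  rhdf5::h5createFile(p2)
  rhdf5::h5write(matrix(1, 1, 3), p2, "vectors")
  rhdf5::h5closeAll()
  expect_error(read_vectors(p2), "missing 'mz'")
})
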
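test_that("NRRD and MHA round-trip data, spacing and origin bit-exactly", {
  set.seed(11)
  v <- vt_volume(array(rnorm(10 * 10 * 10), dim = c(10, 10, 10)),
                 spacing = c(1.5, 2, 2.5), origin = c(-3, 0.5, 7))
  for (ext in c("nrrd", "mha")) {
    p <- withr::local_tempfile(fileext = paste0(".", ext))
    write_volume(v, p)
    r <- read_volume(p)
    expect_identical(r$data, v$data)
    expect_identical(r$spacing, v$spacing)
    expect_identical(r$origin, v$origin)
  }
})

test_that("binary masks stay two-valued through write/read", {
  set.seed(12)
  m <- vt_volume(array(runif(6^3) > 0.5, dim = c(6, 6, 6)),
                 spacing = c(2, 2, 2))
  p <- withr::local_tempfile(fileext = ".nrrd")
  write_volume(m, p)
  r <- read_volume(p)
  expect_true(is.logical(r$data))
  expect_identical(r$data, m$data)
})

test_that("spacing metadata is honoured and overridable", {
  v <- vt_volume(array(0, dim = c(4, 4, 4)), spacing = c(2, 2, 2))
  p <- withr::local_tempfile(fileext = ".nrrd")
  write_volume(v, p)
  expect_equal(read_volume(p)$spacing, c(2, 2, 2))
  expect_equal(read_volume(p, spacing_override = c(9, 9, 9))$spacing,
               c(9, 9, 9))
})

test_that("TIFF stacks carry no spacing and require an override", {
  set.seed(13)
  v <- vt_volume(array(runif(5 * 7 * 3), dim = c(5, 7, 3)),
                 spacing = c(1, 1, 1))
  p <- withr::local_tempfile(fileext = ".tif")
  write_volume(v, p)
  expect_error(read_volume(p), "spacing")
  r <- read_volume(p, spacing_override = c(4, 4, 5))
  expect_equal(r$spacing, c(4, 4, 5))
  expect_lt(max(abs(r$data - v$data)), 1e-6)  # 32-bit float slices
})

test_that("unknown formats and missing files raise errors", {
  expect_error(read_volume("does_not_exist.nrrd"), "not found")
  p <- withr::local_tempfile(fileext = ".xyz")
  writeLines("x", p)
  expect_error(read_volume(p), "unknown volume format")
  v <- vt_volume(array(0, dim = c(3, 3, 3)))
  expect_error(write_volume(v, file.path(tempdir(), "no_dir_here", "a.nrrd")),
               "directory")
})

test_that("resampling to identical spacing is the identity", {
  set.seed(14)
  v <- vt_volume(array(runif(8^3), dim = c(8, 8, 8)), spacing = c(2, 2, 2))
  expect_identical(resample_volume(v, c(2, 2, 2))$data, v$data)
})

test_that("constant volumes stay constant under resampling", {
  v <- vt_volume(array(7, dim = c(12, 12, 12)), spacing = c(1, 1, 1))
  r <- resample_volume(v, c(2.7, 2.7, 2.7), mode = "linear")
  expect_true(all(abs(r$data - 7) < 1e-12))
})

test_that("an oblique sub-resolution tube falls apart at coarse spacing", {
  # diameter ~4 voxels at 2 um, resampled (nearest) to 9 um: the tube is
  # thinner than one target voxel, so its sampled trace fragments or
  # disappears entirely
  dirv <- c(1, 0.37, 0.22)
  dirv <- dirv / sqrt(sum(dirv^2))
  d <- c(70L, 40L, 30L)
  a <- array(FALSE, dim = d)
  p0 <- c(5, 12, 9)
  idx <- as.matrix(expand.grid(x = 1:d[1], y = 1:d[2], z = 1:d[3]))
  w <- sweep(idx, 2, p0)
  t <- pmax(0, pmin(60, w %*% dirv))
  d2 <- rowSums((w - t %*% t(dirv))^2)
  a[idx[d2 <= 4 & t > 0 & t < 60, , drop = FALSE]] <- TRUE
  tube <- vt_volume(a, c(2, 2, 2))
  expect_equal(max(label_components(tube)), 1)
  coarse <- resample_volume(tube, 9, mode = "nearest")
  n_comp <- if (!any(coarse$data)) 0L else
    max(label_components(vt_volume(coarse$data, coarse$spacing)))
  expect_true(n_comp == 0L || n_comp > 1L)
})

test_that("masks refuse linear interpolation", {
  m <- vt_volume(array(TRUE, dim = c(4, 4, 4)))
  expect_error(resample_volume(m, 2, mode = "linear"), "nearest")
  expect_error(resample_volume(m, c(0, 1, 1)), "positive")
})
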
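test_that("a digital ball of radius 10 reads ~20 at its center", {
  b <- make_ball(10)
  tm <- local_thickness(b)
  ctr <- (dim(b$data) + 1) / 2
  expect_equal(tm$data[ctr[1], ctr[2], ctr[3]], 20, tolerance = 1 / 20)
})

test_that("a long cylinder reads its diameter away from the ends", {
  cyl <- make_cylinder(10, 100)
  tm <- local_thickness(cyl)
  interior <- tm$data[30:70, , ]
  vals <- interior[!is.na(interior)]
  # the whole interior block is painted by axis spheres of radius ~10
  expect_true(all(abs(vals - 20) <= 2))
})

test_that("components below the voxel-count threshold are excluded", {
  a <- array(FALSE, dim = c(20, 10, 10))
  a[2:3, 2:3, 2:3] <- TRUE            # 8 voxels: kept at the default
  a[10:12, 5, 5] <- TRUE              # 3 voxels: dropped
  tm <- local_thickness(vt_volume(a), min_component_voxels = 8)
  expect_equal(sum(tm$mask), 8)
  expect_true(all(is.na(tm$data[10:12, 5, 5])))
  a2 <- array(FALSE, dim = c(6, 6, 6))
  a2[2:3, 2:3, 2] <- TRUE
  a2[2:3, 2, 3] <- TRUE               # 6 voxels < 8: everything excluded
  expect_error(local_thickness(vt_volume(a2), min_component_voxels = 8),
               "empty")
})

test_that("local thickness equals the brute-force inscribed-ball oracle", {
  set.seed(31)
  for (rep in 1:5) {
    d <- c(14L, 13L, 12L)
    m <- array(runif(prod(d)) < 0.65, dim = d)
    if (!any(m)) next
    tm <- local_thickness(vt_volume(m), min_component_voxels = 1)
    o <- oracle_local_thickness(m)
    expect_lt(max(abs(tm$data[m] - o[m])), sqrt(3) / 2)
  }
})

test_that("anisotropic spacing is honoured in physical units", {
  # slab 5 voxels thick along z at 2 um spacing = 10 um wall
  a <- array(FALSE, dim = c(20, 20, 9))
  a[, , 3:7] <- TRUE
  tm <- local_thickness(vt_volume(a, spacing = c(1, 1, 2)))
  central <- tm$data[10, 10, 5]
  expect_equal(central, 10, tolerance = 0.25)
})

test_that("thickness values are capped at range_max", {
  b <- make_ball(9)
  tm <- local_thickness(b, range_max = 10)
  expect_lte(max(tm$data, na.rm = TRUE), 10)
})

test_that("dilating the mask never decreases local thickness", {
  set.seed(32)
  d <- rep(15L, 3)
  m <- array(make_ball(5)$data | (runif(prod(d)) < 0.1), dim = d)
  # one-voxel 6-neighbourhood dilation by shifting
  dil <- m
  dil[-1, , ] <- dil[-1, , ] | m[-d[1], , ]
  dil[-d[1], , ] <- dil[-d[1], , ] | m[-1, , ]
  dil[, -1, ] <- dil[, -1, ] | m[, -d[2], ]
  dil[, -d[2], ] <- dil[, -d[2], ] | m[, -1, ]
  dil[, , -1] <- dil[, , -1] | m[, , -d[3]]
  dil[, , -d[3]] <- dil[, , -d[3]] | m[, , -1]
  t0 <- local_thickness(vt_volume(m), min_component_voxels = 1)
  t1 <- local_thickness(vt_volume(dil), min_component_voxels = 1)
  expect_true(all(t1$data[m] >= t0$data[m] - 1e-9))
})

test_that("histogram bin volumes sum exactly to the vessel volume", {
  cyl <- make_cylinder(6, 40, spacing = 1.5)
  tm <- local_thickness(cyl)
  for (bw in c(0.7, 2, 5.3)) {
    h <- diameter_histogram(tm, bin_width = bw)
    expect_identical(sum(h$volume_um3), attr(h, "total_volume_um3"))
    expect_identical(attr(h, "total_volume_um3"),
                     sum(tm$mask) * voxel_volume(cyl))
  }
  expect_error(diameter_histogram(tm, bin_width = 0), "positive")
})

test_that("a uniform cylinder occupies essentially one histogram bin", {
  cyl <- make_cylinder(8, 80)
  tm <- local_thickness(cyl)
  h <- diameter_histogram(tm, bin_width = 2)
  main <- which.max(h$volume_um3)
  expect_gt(h$volume_um3[main] / attr(h, "total_volume_um3"), 0.9)
  expect_true(h$bin_lo_um[main] <= 16 && 16 <= h$bin_hi_um[main] + 2)
})

test_that("two cylinders give a bimodal histogram with ~4x volume ratio", {
  c1 <- make_cylinder(5, 80)
  c2 <- make_cylinder(10, 80)
  d1 <- dim(c1$data); d2 <- dim(c2$data)
  dd <- c(80L, d1[2] + d2[2] + 4L, max(d1[3], d2[3]))
  a <- array(FALSE, dim = dd)
  a[1:80, seq_len(d1[2]), seq_len(d1[3])] <- c1$data
  a[1:80, d1[2] + 2L + seq_len(d2[2]), seq_len(d2[3])] <- c2$data
  tm <- local_thickness(vt_volume(a))
  h <- diameter_histogram(tm, bin_width = 2)
  # peaks at diameters 10 and 20
  peak_small <- sum(h$volume_um3[h$bin_lo_um >= 8 & h$bin_hi_um <= 14])
  peak_large <- sum(h$volume_um3[h$bin_lo_um >= 16 & h$bin_hi_um <= 24])
  expect_gt(peak_small, 0)
  expect_gt(peak_large, 0)
  expect_equal(peak_large / peak_small, 4, tolerance = 0.35)
})

test_that("volume-weighted stats: cylinder and two-point distribution", {
  cyl <- make_cylinder(10, 100)
  st <- volume_weighted_stats(local_thickness(cyl))
  expect_equal(st$mean_um, 20, tolerance = 0.10)
  expect_lt(st$sd_um / st$mean_um, 0.10)
  # two equal-volume populations at 10 and 20 um: mean 15, SD 5
  a <- array(FALSE, dim = c(30, 10, 10))
  a[1:10, 1:5, 1:5] <- TRUE
  tm <- local_thickness(vt_volume(a), min_component_voxels = 1)
  tm$data[tm$mask] <- rep(c(10, 20), each = sum(tm$mask) / 2)
  st2 <- volume_weighted_stats(tm)
  expect_equal(st2$mean_um, 15)
  expect_equal(st2$sd_um, 5)
  expect_equal(st2$min_um, 10)
  expect_equal(st2$max_um, 20)
})
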
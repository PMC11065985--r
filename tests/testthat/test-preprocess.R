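test_that("median filter: constants unchanged, salt noise removed", {
  v <- vt_volume(array(4.2, dim = c(5, 5, 5)))
  expect_equal(median_filter3(v)$data, v$data)
  s <- array(0, dim = c(7, 7, 7))
  s[4, 4, 4] <- 100
  out <- median_filter3(vt_volume(s))
  expect_equal(out$data[4, 4, 4], 0)
  expect_true(all(out$data == 0))
})

test_that("median filter matches a sort-and-pick-middle oracle", {
  set.seed(21)
  v <- array(runif(8^3), dim = c(8, 8, 8))
  out <- median_filter3(vt_volume(v))$data
  for (x in 2:7) for (y in 2:7) for (z in 2:7) {
    expect_equal(out[x, y, z],
                 median(v[(x - 1):(x + 1), (y - 1):(y + 1), (z - 1):(z + 1)]))
  }
})

test_that("median filter leaves the interior of a large convex solid alone", {
  b <- make_ball(8)
  once <- median_filter3(b)
  twice <- median_filter3(once)
  # interior = voxels at least one voxel inside the surface
  inner <- make_ball(7, dim = dim(b$data))$data
  expect_identical(once$data[inner], b$data[inner])
  expect_identical(twice$data[inner], once$data[inner])
  expect_error(median_filter3(vt_volume(array(0, dim = c(2, 5, 5)))), ">= 3")
})

test_that("region growing floods a uniform block and respects the window", {
  v <- array(0, dim = c(10, 10, 10))
  v[2:4, 2:4, 2:4] <- 100
  v[7:9, 7:9, 7:9] <- 200
  vol <- vt_volume(v)
  m <- region_grow(vol, c(3, 3, 3), 90, 110)
  expect_equal(sum(m$data), 27)
  expect_true(all(which(m$data) %in% which(v == 100)))
})

test_that("region growing equals a flood-fill oracle on random volumes", {
  set.seed(22)
  for (rep in 1:3) {
    v <- array(runif(12^3), dim = c(12, 12, 12))
    seed_idx <- which(v >= 0.4 & v <= 0.9)[1]
    co <- arrayInd(seed_idx, dim(v))
    m <- region_grow(vt_volume(v), co, 0.4, 0.9)
    o <- oracle_flood(v >= 0.4 & v <= 0.9, seed_idx)
    expect_identical(m$data, o)
  }
})

test_that("region growing validates seeds", {
  v <- vt_volume(array(1, dim = c(5, 5, 5)))
  expect_error(region_grow(v, c(9, 1, 1), 0, 2), "outside the grid")
  expect_error(region_grow(v, c(1, 1, 1), 2, 3), "window")
  expect_error(region_grow(v, c(1, 1, 1), 3, 2), "low")
})

test_that("region-grown masks are window-limited and seed-connected", {
  set.seed(23)
  v <- array(runif(14^3), dim = c(14, 14, 14))
  adm <- v >= 0.5
  seed_idx <- which(adm)[5]
  m <- region_grow(vt_volume(v), arrayInd(seed_idx, dim(v)), 0.5, 1)
  expect_true(all(adm[m$data]))
  lab <- label_components(m)
  expect_equal(max(lab), 1)  # single 26-connected piece containing the seed
  expect_true(m$data[seed_idx])
})

test_that("fill_holes fills an enclosed cavity", {
  d <- rep(26L, 3)
  ctr <- 13.5
  idx <- as.matrix(expand.grid(1:26, 1:26, 1:26))
  r2 <- colSums((t(idx) - ctr)^2)
  shell <- array(r2 <= 100 & r2 >= 49, dim = d)
  out <- fill_holes(vt_volume(shell), max_gap = 0)
  solid <- array(r2 <= 100, dim = d)
  expect_identical(out$data, solid)
})

test_that("fill_holes bridges a broken tube within max_gap", {
  tube <- make_cylinder(3, 40)
  broken <- tube
  broken$data[19:21, , ] <- FALSE
  expect_equal(max(label_components(broken)), 2)
  fixed <- fill_holes(broken, max_gap = 4)
  expect_equal(max(label_components(fixed)), 1)
  expect_true(all(fixed$data[broken$data]))  # extensive
})

test_that("fill_holes: identity at max_gap 0 on a cavity-free mask, idempotent", {
  b <- make_ball(6)
  expect_identical(fill_holes(b, 0)$data, b$data)
  set.seed(24)
  m <- vt_volume(array(runif(15^3) > 0.7, dim = c(15, 15, 15)))
  once <- fill_holes(m, max_gap = 3)
  twice <- fill_holes(once, max_gap = 3)
  expect_true(all(once$data[m$data]))
  expect_identical(once$data, twice$data)
  expect_error(fill_holes(m, -1), ">= 0")
})
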
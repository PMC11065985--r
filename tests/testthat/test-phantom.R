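test_that("phantom trees honour their spec: counts, taper, determinism", {
  # depth 1: a single root segment
  p1 <- generate_tree(phantom_spec(depth = 1, root_radius = 9,
                                   root_length = 40))
  expect_equal(nrow(p1$segments), 1)
  expect_equal(p1$segments$radius_um, 9)
  expect_equal(p1$segments$length_um, 40)
  # symmetric binary depth d: 2^d - 1 segments, truth Strahler(root) = d
  p2 <- generate_tree(phantom_spec(depth = 5, root_radius = 12,
                                   radius_ratio = 0.75, seed = 2))
  expect_equal(nrow(p2$segments), 2^5 - 1)
  expect_equal(p2$segments$strahler[p2$segments$parent == 0], 5L)
  # Murray's law under the default taper: daughter r^3 sums to parent r^3
  pm <- generate_tree(phantom_spec(depth = 3, root_radius = 10, seed = 3))
  s <- pm$segments
  for (pid in unique(s$parent[s$parent != 0])) {
    kids <- s$radius_um[s$parent == pid]
    expect_equal(sum(kids^3), s$radius_um[s$id == pid]^3, tolerance = 1e-9)
  }
  # identical spec + seed -> identical phantom
  pa <- generate_tree(phantom_spec(depth = 4, root_radius = 8,
                                   angle_jitter = 8, seed = 11))
  pb <- generate_tree(phantom_spec(depth = 4, root_radius = 8,
                                   angle_jitter = 8, seed = 11))
  expect_identical(pa$segments, pb$segments)
})

test_that("truth labels obey the order-scheme relations", {
  set.seed(61)
  ph <- generate_tree(phantom_spec(depth = 5, daughters = 2, root_radius = 10,
                                   angle_jitter = 6, seed = 13))
  s <- ph$segments
  expect_true(all(s$strahler <= s$horsfield))
  terminal <- !(s$id %in% s$parent)
  expect_true(all(s$strahler[terminal] == 1L))
  expect_true(all(s$generation == s$level))  # binary tree: every junction splits
})

test_that("a rasterized single segment matches the analytic capsule volume", {
  ph <- generate_tree(phantom_spec(depth = 1, root_radius = 10,
                                   root_length = 100))
  m <- rasterize_tree(ph, spacing = 1)
  analytic <- pi * 10^2 * 100 + 4 / 3 * pi * 10^3  # cylinder + two caps
  expect_lt(abs(sum(m$data) - analytic) / analytic, 0.05)
})

test_that("casting gaps disconnect the cast and fill_holes repairs it", {
  base <- phantom_spec(depth = 3, root_radius = 6, root_length = 30,
                       casting_gap_rate = 0, seed = 21)
  m0 <- rasterize_tree(generate_tree(base))
  expect_equal(max(label_components(m0)), 1)
  gapped <- phantom_spec(depth = 3, root_radius = 6, root_length = 30,
                         casting_gap_rate = 1, gap_scale = 1.6, seed = 21)
  m1 <- rasterize_tree(generate_tree(gapped))
  expect_gt(max(label_components(m1)), 1)
  healed <- fill_holes(m1, max_gap = 2 * 1.6 * 6)
  expect_equal(max(label_components(healed)), 1)
})

test_that("degradation is identity-stable and seed-deterministic", {
  ph <- generate_tree(phantom_spec(depth = 2, root_radius = 6,
                                   root_length = 24))
  m <- rasterize_tree(ph, spacing = 2)
  same <- degrade_volume(m, 2, blur_sigma = 0, noise_sd = 0)
  expect_equal(same$data, array(as.numeric(m$data), dim = dim(m$data)))
  n1 <- degrade_volume(m, 4, noise_sd = 0.1, seed = 3)
  n2 <- degrade_volume(m, 4, noise_sd = 0.1, seed = 3)
  expect_identical(n1$data, n2$data)
  n3 <- degrade_volume(m, 4, noise_sd = 0.1, seed = 4)
  expect_false(identical(n1$data, n3$data))
  expect_error(degrade_volume(m, 1), "coarse")
})

test_that("infeasible specs fail loudly instead of overlapping", {
  # daughters forced into each other: enormous radii relative to lengths
  spec <- phantom_spec(depth = 3, daughters = 8, root_radius = 30,
                       radius_ratio = 0.95, root_length = 10,
                       length_ratio = 0.9, branch_angle = 5)
  expect_error(generate_tree(spec), "infeasible")
})
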
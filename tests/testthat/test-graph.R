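test_that("a straight tube skeletonizes to a single centered path", {
  cyl <- make_cylinder(6, 40)
  sk <- skeletonize(cyl)
  g <- extract_graph(sk)
  g <- prune_spurs(g, 8)
  expect_equal(length(g$edges), 1)
  deg <- vasctree:::graph_degrees(g)
  expect_equal(sort(deg[deg > 0]), c(1, 1))
  # centerline stays on the cylinder axis
  pts <- g$edges[[1]]$pts
  cy <- (dim(cyl$data)[2] - 1) / 2  # physical center (origin 0, spacing 1)
  expect_true(all(abs(pts[, 2] - cy) <= 1.5))
})

test_that("a Y-shaped union yields one bifurcation and three branches", {
  p0 <- rbind(c(6, 20, 20), c(25, 20, 20), c(25, 20, 20))
  p1 <- rbind(c(25, 20, 20), c(43, 31, 20), c(43, 9, 20))
  y <- make_capsules(p0, p1, rep(4, 3), c(48L, 40L, 40L))
  sk <- skeletonize(y)
  g <- prune_spurs(extract_graph(sk), 6)
  expect_equal(length(g$edges), 3)
  deg <- vasctree:::graph_degrees(g)
  expect_equal(sort(deg[deg > 0]), c(1, 1, 1, 3))
})

test_that("a torus keeps exactly one loop through the whole chain", {
  a <- array(FALSE, dim = c(50, 50, 11))
  for (x in 1:50) for (y in 1:50) for (z in 1:11) {
    rho <- sqrt((x - 25)^2 + (y - 25)^2)
    a[x, y, z] <- (rho - 15)^2 + (z - 6)^2 <= 9
  }
  tor <- vt_volume(a)
  sk <- skeletonize(tor)
  g <- extract_graph(sk)
  # Euler loop census: edges - nodes + components = number of loops
  used <- unique(unlist(lapply(g$edges, function(e) c(e$from, e$to))))
  expect_equal(length(g$edges) - length(used) + 1L, 1L)
  gp <- prune_spurs(g, 5)
  expect_equal(length(gp$edges), 1)
  expect_equal(gp$edges[[1]]$from, gp$edges[[1]]$to)
})

test_that("graph extraction handles a bare voxel path and empty input", {
  p <- array(FALSE, dim = c(30, 5, 5))
  p[3:27, 3, 3] <- TRUE
  g <- extract_graph(vt_volume(p))
  expect_equal(nrow(g$nodes), 2)
  expect_equal(length(g$edges), 1)
  expect_equal(nrow(g$edges[[1]]$pts), 25)
  expect_error(skeletonize(vt_volume(array(FALSE, dim = c(4, 4, 4)))),
               "empty")
})

test_that("prune_spurs: min_len 0 is the identity, twigs go, count shrinks", {
  p0 <- rbind(c(6, 20, 20), c(25, 20, 20), c(25, 20, 20))
  p1 <- rbind(c(25, 20, 20), c(43, 31, 20), c(43, 9, 20))
  y <- make_capsules(p0, p1, rep(4, 3), c(48L, 40L, 40L))
  g <- extract_graph(skeletonize(y))
  expect_equal(length(prune_spurs(g, 0)$edges), length(g$edges))
  for (ml in c(2, 5, 9)) {
    expect_lte(length(prune_spurs(g, ml)$edges), length(g$edges))
  }
  # monotone: stronger pruning never increases the edge count
  n_edges <- vapply(c(0, 3, 6, 12), function(ml)
    length(prune_spurs(g, ml)$edges), integer(1))
  expect_true(all(diff(n_edges) <= 0))
})

test_that("a single cylinder reduces to one segment with full volume", {
  cyl <- make_cylinder(6, 50)
  tm <- local_thickness(cyl)
  g <- prune_spurs(extract_graph(skeletonize(cyl)), 8)
  sg <- reduce_to_segments(g, tm)
  expect_equal(nrow(sg$segments), 1)
  expect_equal(sg$segments$diameter_um, 12, tolerance = 1 / 12)
  expect_identical(sg$segments$volume_um3, sum(tm$mask) * 1)
})

test_that("segment volumes always partition the vessel volume exactly", {
  ph <- generate_tree(phantom_spec(depth = 3, root_radius = 7,
                                   radius_ratio = 0.75, root_length = 26,
                                   seed = 2))
  m <- rasterize_tree(ph, spacing = 1)
  tm <- local_thickness(m)
  g <- prune_spurs(extract_graph(skeletonize(m)), 5, adaptive = tm)
  sg <- reduce_to_segments(g, tm)
  expect_identical(sum(sg$segments$volume_um3),
                   sum(tm$mask) * voxel_volume(m))
  # Euler relation on the tree
  tr <- build_rooted_tree(sg)
  used <- unique(c(sg$segments$from, sg$segments$to))
  expect_equal(tr$n_segments, length(used) - 1L)
})

test_that("identical volumes give bit-identical segment graphs", {
  ph <- generate_tree(phantom_spec(depth = 3, root_radius = 6,
                                   root_length = 20, seed = 5))
  m <- rasterize_tree(ph, spacing = 1)
  run <- function() {
    tm <- local_thickness(m)
    g <- prune_spurs(extract_graph(skeletonize(m)), 5, adaptive = tm)
    reduce_to_segments(g, tm)
  }
  a <- run()
  b <- run()
  expect_identical(a$segments, b$segments)
  expect_identical(a$polylines, b$polylines)
})

test_that("rooting: trees stay intact, loops are recorded, ties resolve low", {
  # synthetic segment graph: path with one extra cycle-closing edge
  nodes <- data.frame(id = 1:4, x = c(0, 10, 20, 30), y = 0, z = 0,
                      anchor = 1:4)
  seg <- data.frame(id = 1:4, from = c(1, 2, 3, 2), to = c(2, 3, 4, 4),
                    length_um = 10, diameter_um = c(8, 5, 5, 5),
                    volume_um3 = 1, n_polyline = 2)
  sg <- structure(list(nodes = nodes, segments = seg,
                       polylines = NULL, vox = NULL, owner = NULL,
                       spacing = c(1, 1, 1), origin = c(0, 0, 0),
                       dim = c(1L, 1L, 1L), diameter_stat = "median"),
                  class = "vt_segment_graph")
  tr <- build_rooted_tree(sg)
  expect_equal(tr$root_node, 1)  # terminal incident to the widest segment
  expect_equal(length(tr$removed), 1)  # cycle rank 1
  expect_equal(tr$n_segments, 3)
  # tie on diameter: lower node id wins
  seg2 <- seg[1:3, ]
  seg2$diameter_um <- 5
  sg$segments <- seg2
  tr2 <- build_rooted_tree(sg)
  expect_equal(tr2$root_node, 1)
  expect_equal(length(tr2$removed), 0)
})

test_that("disconnected segment graphs are refused with guidance", {
  nodes <- data.frame(id = 1:4, x = 0, y = 0, z = 0, anchor = 1:4)
  seg <- data.frame(id = 1:2, from = c(1, 3), to = c(2, 4),
                    length_um = 10, diameter_um = 5, volume_um3 = 1,
                    n_polyline = 2)
  sg <- structure(list(nodes = nodes, segments = seg, polylines = NULL,
                       vox = NULL, owner = NULL, spacing = c(1, 1, 1),
                       origin = c(0, 0, 0), dim = c(1L, 1L, 1L),
                       diameter_stat = "median"),
                  class = "vt_segment_graph")
  expect_error(build_rooted_tree(sg), "components separately")
})
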
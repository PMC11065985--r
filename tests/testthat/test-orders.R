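test_that("hand-checked label examples across the three schemes", {
  # single segment
  t1 <- as_rooted_tree(0L)
  expect_equal(as.integer(assign_generations(t1)), 1L)
  expect_equal(as.integer(assign_horsfield_orders(t1)), 1L)
  expect_equal(as.integer(assign_strahler(t1)), 1L)
  # full binary depth 3: generations {1,2,3} with counts {1,2,4}
  parent <- c(0L, 1L, 1L, 2L, 2L, 3L, 3L)
  t2 <- as_rooted_tree(parent)
  gen <- assign_generations(t2)
  expect_equal(as.integer(table(gen)), c(1L, 2L, 4L))
  expect_equal(unname(assign_horsfield_orders(t2)[as.character(1)]), 3L)
  expect_equal(unname(assign_strahler(t2)[as.character(1)]), 3L)
  # chained path: no junctions, all labels 1 everywhere
  t3 <- as_rooted_tree(c(0L, 1L, 2L))
  expect_true(all(assign_generations(t3) == 1L))
  expect_true(all(assign_horsfield_orders(t3) == 1L))
  expect_true(all(assign_strahler(t3) == 1L))
  # root -> {leaf, internal-with-2-leaves}: Horsfield 3 vs Strahler 2
  t4 <- as_rooted_tree(c(0L, 1L, 1L, 3L, 3L))
  expect_equal(unname(assign_horsfield_orders(t4)[as.character(1)]), 3L)
  expect_equal(unname(assign_strahler(t4)[as.character(1)]), 2L)
})

test_that("labels match recursive oracles on 100 random trees", {
  set.seed(41)
  for (rep in 1:100) {
    n <- sample(2:200, 1)
    parent <- random_parent_vector(n)
    tr <- as_rooted_tree(parent)
    ids <- as.character(seq_len(n))
    gen <- as.integer(assign_generations(tr)[ids])
    hor <- as.integer(assign_horsfield_orders(tr)[ids])
    str <- as.integer(assign_strahler(tr)[ids])
    expect_identical(gen, oracle_generation(parent))
    expect_identical(hor, oracle_horsfield(parent))
    expect_identical(str, oracle_strahler(parent))
    # invariants
    expect_true(all(str <= hor))
    terminal <- !(seq_len(n) %in% parent)
    expect_true(all(hor[terminal] == 1L))
    expect_true(all(str[terminal] == 1L))
    expect_equal(max(str), str[parent == 0])  # root is maximal
  }
})

test_that("generation equals 1 + junction count along the root path", {
  set.seed(42)
  parent <- random_parent_vector(120)
  ch <- oracle_children(parent)
  tr <- as_rooted_tree(parent)
  gen <- assign_generations(tr)
  for (i in seq_along(parent)) {
    # walk to the root, counting >= 2-daughter junctions passed
    jumps <- 0L
    cur <- parent[i]
    while (cur != 0L) {
      if (length(ch[[cur]]) >= 2L) jumps <- jumps + 1L
      cur <- parent[cur]
    }
    expect_equal(unname(gen[as.character(i)]), 1L + jumps)
  }
})

test_that("Strahler respects the binary-depth and log2 bounds", {
  # symmetric full binary tree of depth d has root Strahler d
  for (d in 2:5) {
    n <- 2^d - 1
    parent <- c(0L, rep(seq_len(n), each = 2)[seq_len(n - 1)])
    tr <- as_rooted_tree(parent)
    str <- assign_strahler(tr)
    expect_equal(unname(str[as.character(1)]), d)
    n_term <- sum(!(seq_len(n) %in% parent))
    expect_lte(length(unique(str)), ceiling(log2(n_term)) + 1L)
  }
})

test_that("group summaries conserve counts and volumes", {
  set.seed(43)
  n <- 40
  parent <- random_parent_vector(n)
  tr <- as_rooted_tree(parent)
  tab <- data.frame(id = seq_len(n),
                    diameter_um = runif(n, 5, 50),
                    length_um = runif(n, 10, 100),
                    volume_um3 = runif(n, 100, 1e4))
  for (lab in list(assign_generations(tr), assign_strahler(tr))) {
    gs <- summarize_by_group(tab, lab)
    expect_equal(sum(gs$n), n)
    expect_equal(sum(gs$vol_total), sum(tab$volume_um3))
    expect_true(all(gs$d_min <= gs$d_mean & gs$d_mean <= gs$d_max))
  }
  # identical segments collapse the spread
  tab2 <- tab
  tab2$diameter_um <- 7
  gs2 <- summarize_by_group(tab2, assign_strahler(tr))
  expect_true(all(gs2$d_min == 7 & gs2$d_mean == 7 & gs2$d_max == 7))
  expect_error(summarize_by_group(tab, assign_strahler(tr)[-1]), "cover")
})

test_that("mean diameter rises with Strahler order on a tapering phantom", {
  ph <- generate_tree(phantom_spec(depth = 4, root_radius = 10,
                                   radius_ratio = 0.7, root_length = 36,
                                   seed = 4))
  tab <- data.frame(id = ph$segments$id,
                    diameter_um = 2 * ph$segments$radius_um,
                    length_um = ph$segments$length_um,
                    volume_um3 = pi * ph$segments$radius_um^2 *
                      ph$segments$length_um)
  lab <- assign_strahler(as_rooted_tree(ph$segments$parent))
  gs <- summarize_by_group(tab, lab)
  expect_true(all(diff(gs$d_mean[order(gs$label)]) > 0))
})
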
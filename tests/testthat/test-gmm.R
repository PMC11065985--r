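toy_table <- function(n = 30, seed = 51) {
  set.seed(seed)
  data.frame(id = seq_len(n),
             diameter_um = exp(rnorm(n, 3, 0.8)),
             length_um = exp(rnorm(n, 4, 0.6)),
             volume_um3 = 1)
}

test_that("feature building: standardization, passthrough, errors", {
  tab <- toy_table()
  X <- build_features(tab, log_transform = TRUE, standardize = TRUE)
  expect_equal(unname(colMeans(X)), c(0, 0), tolerance = 1e-12)
  expect_equal(unname(apply(X, 2, sd)), c(1, 1), tolerance = 1e-12)
  Xr <- build_features(tab, log_transform = FALSE, standardize = FALSE)
  expect_equal(unname(Xr[, 1]), tab$diameter_um)
  expect_equal(unname(Xr[, 2]), tab$length_um)
  tab$diameter_um[1] <- 0
  expect_error(build_features(tab, log_transform = TRUE), "positive")
})

test_that("k = 1 fit equals the closed-form single Gaussian", {
  set.seed(52)
  X <- matrix(rnorm(300), ncol = 2)
  f <- fit_gmm(X, 1, "VVV", seed = 1)
  n <- nrow(X)
  mu <- colMeans(X)
  S <- cov(X) * (n - 1) / n  # maximum-likelihood covariance
  ll <- sum(apply(X, 1, function(x) {
    -0.5 * (2 * log(2 * pi) +
              as.numeric(determinant(S)$modulus) +
              t(x - mu) %*% solve(S) %*% (x - mu))
  }))
  expect_equal(f$loglik, ll, tolerance = 1e-6)
  expect_equal(f$bic, 2 * ll - 5 * log(n), tolerance = 1e-6)
  expect_equal(unname(f$means[1, ]), unname(mu), tolerance = 1e-8)
})

test_that("two point-masses are recovered exactly (with a ridge warning)", {
  X <- rbind(matrix(0, 20, 2), matrix(10, 20, 2))
  expect_warning(f <- fit_gmm(X, 2, "VVV", seed = 1), "ridge")
  expect_equal(sort(f$weights), c(0.5, 0.5))
  expect_equal(sort(f$means[, 1]), c(0, 10), tolerance = 1e-6)
})

test_that("fits are deterministic for a fixed seed", {
  set.seed(53)
  X <- rbind(matrix(rnorm(200), ncol = 2),
             matrix(rnorm(200), ncol = 2) + 4)
  f1 <- fit_gmm(X, 2, "VVI", seed = 7)
  f2 <- fit_gmm(X, 2, "VVI", seed = 7)
  expect_identical(f1$loglik, f2$loglik)
  expect_identical(f1$means, f2$means)
  expect_error(fit_gmm(X, nrow(X) + 1, seed = 1), "exceeds")
})

test_that("per-constellation BIC agrees with an independent implementation", {
  skip_if_not_installed("mclust")
  suppressMessages(withr::local_package("mclust"))
  set.seed(54)
  X <- matrix(rnorm(240), ncol = 2)
  for (mod in gmm_constellations()) {
    m <- mclust::Mclust(X, G = 1, modelNames = mod, verbose = FALSE)
    f <- fit_gmm(X, 1, mod, seed = 1)
    expect_equal(f$bic, as.numeric(m$bic), tolerance = 1e-6,
                 label = paste("BIC", mod))
  }
  # a separated 2-component mixture, richer-model fits
  X2 <- rbind(matrix(rnorm(300), ncol = 2),
              matrix(rnorm(300), ncol = 2) + 7)
  for (mod in c("EII", "VVI", "VVV")) {
    m <- mclust::Mclust(X2, G = 2, modelNames = mod, verbose = FALSE)
    f <- fit_gmm(X2, 2, mod, seed = 3)
    expect_equal(f$bic, as.numeric(m$bic), tolerance = 1e-4,
                 label = paste("BIC k=2", mod))
  }
})

test_that("nested constellations never lose log-likelihood", {
  set.seed(55)
  X <- rbind(matrix(rnorm(200), ncol = 2),
             sweep(matrix(rnorm(200), ncol = 2) %*%
                     matrix(c(1, 0.6, 0, 0.8), 2), 2, c(5, 1), "+"))
  # nesting chains at fixed k: EII <= VII <= VVI <= VVV; EII <= EEI <= EEE <= VVV
  ll <- vapply(gmm_constellations(), function(cs)
    fit_gmm(X, 2, cs, seed = 2, n_init = 12)$loglik, numeric(1))
  tol <- 1e-4
  expect_gte(ll["VII"], ll["EII"] - tol)
  expect_gte(ll["VVI"], ll["VII"] - tol)
  expect_gte(ll["VVV"], ll["VVI"] - tol)
  expect_gte(ll["EEI"], ll["EII"] - tol)
  expect_gte(ll["EEE"], ll["EEI"] - tol)
  expect_gte(ll["VVV"], ll["EEE"] - tol)
})

test_that("select_gmm: single Gaussian selects k = 1; table shape is right", {
  set.seed(56)
  X <- matrix(rnorm(1000), ncol = 2)  # n = 500 spherical Gaussian
  sel <- select_gmm(X, k_range = 1:4, seed = 1)
  expect_equal(sel$best$k, 1L)
  sel2 <- select_gmm(X, k_range = 2, constellations = "VVV", seed = 1)
  expect_equal(nrow(sel2$bic_table), 1L)
  expect_error(select_gmm(X, constellations = character(0)), "constellations")
})

test_that("select_gmm recovers 3 well-separated components", {
  set.seed(57)
  X <- rbind(matrix(rnorm(400), ncol = 2),
             matrix(rnorm(400), ncol = 2) + c(10, 0),
             matrix(rnorm(400), ncol = 2) + c(5, 10))
  sel <- select_gmm(X, k_range = 1:9, seed = 5)
  expect_equal(sel$best$k, 3L)
  cls <- predict(sel$best, X)
  expect_equal(length(unique(cls)), 3L)
  # posterior rows sum to one
  post <- predict(sel$best, X, type = "posterior")
  expect_equal(rowSums(post), rep(1, nrow(X)), tolerance = 1e-12)
})

test_that("Davies-Bouldin and Dunn match hand-computed toy values", {
  X <- rbind(c(0, 0), c(0, 2), c(10, 0), c(10, 2))
  lab <- c("A", "A", "B", "B")
  expect_equal(davies_bouldin(X, lab), 0.2, tolerance = 1e-9)
  expect_equal(dunn_index(X, lab), 5.0, tolerance = 1e-9)
  # zero scatter: DB = 0; two singletons: Dunn = Inf
  X2 <- rbind(c(0, 0), c(0, 0), c(5, 5), c(5, 5))
  expect_equal(davies_bouldin(X2, lab), 0)
  expect_equal(dunn_index(rbind(c(0, 0), c(9, 9)), c(1, 2)), Inf)
  expect_error(davies_bouldin(X, rep("A", 4)), "2 non-empty")
  expect_error(dunn_index(X, rep("A", 4)), "2 non-empty")
})

test_that("validity indices behave under rigid motion and labelling noise", {
  set.seed(58)
  X <- rbind(matrix(rnorm(100, sd = 0.5), ncol = 2),
             matrix(rnorm(100, sd = 0.5), ncol = 2) + 6)
  lab <- rep(1:2, each = 50)
  db <- davies_bouldin(X, lab)
  du <- dunn_index(X, lab)
  th <- 0.7
  R <- matrix(c(cos(th), sin(th), -sin(th), cos(th)), 2)
  Xr <- sweep(X %*% R, 2, c(100, -40), "+")
  expect_equal(davies_bouldin(Xr, lab), db, tolerance = 1e-9)
  expect_equal(dunn_index(Xr, lab), du, tolerance = 1e-9)
  # isotropic scaling leaves both ratios unchanged
  expect_equal(davies_bouldin(X * 3.7, lab), db, tolerance = 1e-9)
  expect_equal(dunn_index(X * 3.7, lab), du, tolerance = 1e-9)
  # random labels score strictly worse on separated blobs
  rnd <- sample(lab)
  expect_gt(davies_bouldin(X, rnd), db)
  expect_lt(dunn_index(X, rnd), du)
})

test_that("compare_groupings reports all schemes, undefined ones as NA", {
  set.seed(59)
  X <- rbind(matrix(rnorm(60), ncol = 2),
             matrix(rnorm(60), ncol = 2) + 5)
  lab <- rep(1:2, each = 30)
  rep_tab <- compare_groupings(X, list(a = lab, b = lab, single = rep(1, 60)))
  expect_equal(rep_tab$davies_bouldin[1], rep_tab$davies_bouldin[2])
  expect_equal(rep_tab$dunn[1], rep_tab$dunn[2])
  expect_true(is.na(rep_tab$davies_bouldin[3]) && is.na(rep_tab$dunn[3]))
  expect_error(compare_groupings(X, list(lab)), "named")
})

test_that("label back-mapping partitions the mask like the group summary", {
  ph <- generate_tree(phantom_spec(depth = 3, root_radius = 6,
                                   root_length = 20, seed = 6))
  m <- rasterize_tree(ph, spacing = 1)
  tm <- local_thickness(m)
  g <- prune_spurs(extract_graph(skeletonize(m)), 5, adaptive = tm)
  sg <- reduce_to_segments(g, tm)
  lab <- assign_strahler(build_rooted_tree(sg))
  geo <- map_labels_to_geometry(sg, lab)
  vox <- voxel_volume(m)
  per_label <- tapply(rep(vox, sum(geo$volume$data > 0)),
                      geo$volume$data[geo$volume$data > 0], sum)
  gs <- summarize_by_group(segment_table(sg), lab)
  expect_equal(as.numeric(per_label[as.character(gs$label)]), gs$vol_total)
  # single-segment mapping is uniform
  cyl <- make_cylinder(5, 30)
  tmc <- local_thickness(cyl)
  sgc <- reduce_to_segments(prune_spurs(extract_graph(skeletonize(cyl)), 8),
                            tmc)
  one <- c(9L)
  names(one) <- sgc$segments$id
  geoc <- map_labels_to_geometry(sgc, one)
  expect_true(all(geoc$volume$data[tmc$mask] == 9L))
  expect_true(all(geoc$volume$data[!tmc$mask] == 0L))
})
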
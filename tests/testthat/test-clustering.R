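test_that("reduce_umap: shape, determinism, and group separation", {
  set.seed(31)
  # two groups with distinct directions (cosine-separable), 25 each
  g1 <- matrix(rnorm(25 * 10, 0, 0.05), 25) +
    matrix(c(rep(1, 5), rep(0, 5)), 25, 10, byrow = TRUE)
  g2 <- matrix(rnorm(25 * 10, 0, 0.05), 25) +
    matrix(c(rep(0, 5), rep(1, 5)), 25, 10, byrow = TRUE)
  x <- rbind(g1, g2)
  e1 <- reduce_umap(x, seed = 0)
  expect_equal(dim(e1), c(50L, 3L))
  expect_true(all(is.finite(e1)))
  expect_identical(reduce_umap(x, seed = 0), e1)
  truth <- rep(0:1, each = 25)
  expect_gt(oracle_silhouette(e1, truth), 0)
  expect_error(reduce_umap(x[1:10, ], n_neighbors = 15), "n_neighbors")
})

test_that("cluster_dbscan matches the density-reachability oracle", {
  set.seed(7)
  blob <- function(cx, cy, n) cbind(rnorm(n, cx, 0.1), rnorm(n, cy, 0.1))
  pts <- rbind(blob(0, 0, 8), blob(10, 0, 8))
  lab <- cluster_dbscan(cbind(pts, 0), eps = 1, min_samples = 3)
  expect_equal(length(unique(lab[lab != -1])), 2L)
  expect_equal(sum(lab == -1), 0L)
  expect_equal(oracle_ari(lab, rep(0:1, each = 8)), 1)
  # far-away singleton becomes noise
  pts2 <- rbind(pts, c(100, 0))
  lab2 <- cluster_dbscan(cbind(pts2, 0), eps = 1, min_samples = 3)
  expect_equal(lab2[17], -1L)
  # identical points collapse to a single cluster
  same <- matrix(1, 5, 3)
  expect_equal(cluster_dbscan(same, eps = 0.5, min_samples = 5), rep(0L, 5))
  # random instances against the oracle (partition + noise-set equality)
  for (i in 1:8) {
    p <- matrix(runif(3 * sample(8:20, 1), 0, 4), ncol = 3)
    eps <- runif(1, 0.3, 1.2); ms <- sample(2:4, 1)
    got <- cluster_dbscan(p, eps, ms)
    want <- oracle_dbscan(p, eps, ms)
    expect_equal(which(got == -1L), which(want == -1L))
    keep <- got != -1L
    if (sum(keep) > 1) expect_equal(oracle_ari(got[keep], want[keep]), 1)
  }
  expect_error(cluster_dbscan(matrix(0, 0, 3), 1, 1), "empty")
})

test_that("cluster_kmeans recovers the exhaustive 2-partition minimizer", {
  expect_equal(cluster_kmeans(matrix(rnorm(10), 5), 1), rep(0L, 5))
  set.seed(17)
  x <- rbind(matrix(rnorm(12, 0, 0.3), 6), matrix(rnorm(12, 6, 0.3), 6))
  got <- cluster_kmeans(x, 2, seed = 1)
  want <- oracle_best_2partition(x)$labels
  expect_equal(oracle_ari(got, want), 1)
  # k = n on distinct points: every point its own cluster
  xd <- matrix(seq_len(8), 4, 2)
  expect_equal(sort(cluster_kmeans(xd, 4, seed = 2)), 0:3)
  expect_error(cluster_kmeans(xd, 5), "k must satisfy")
  # determinism under a fixed seed
  expect_identical(cluster_kmeans(x, 2, seed = 9), cluster_kmeans(x, 2, seed = 9))
})

test_that("count_meaningful_clusters excludes noise and singletons", {
  expect_equal(count_meaningful_clusters(c(0L, 0L, 1L, -1L, -1L)), 1L)
  expect_equal(count_meaningful_clusters(rep(-1L, 4)), 0L)
  expect_equal(count_meaningful_clusters(c(0L, 0L, 1L, 1L)), 2L)
  # label permutation invariance
  set.seed(3)
  lab <- sample(c(-1L, 0L, 1L, 2L), 30, replace = TRUE)
  perm <- c(2L, 0L, 1L)
  relab <- ifelse(lab == -1L, -1L, perm[lab + 1L])
  expect_equal(count_meaningful_clusters(relab),
               count_meaningful_clusters(lab))
})

test_that("mean_cluster_image averages standardized members", {
  set.seed(8)
  x <- img(matrix(runif(64, 0, 10), 8, 8))
  imgs <- list(x, x, img(matrix(runif(64), 8, 8)))
  m <- mean_cluster_image(imgs, c(0L, 0L, 1L), 0L)
  expect_equal(m$pixels, standardize_image(x)$pixels)
  # post-scaling constant images are all-zero, so their mean is zero
  m2 <- mean_cluster_image(list(img(matrix(0, 4, 4)), img(matrix(1, 4, 4))),
                           c(2L, 2L), 2L)
  expect_equal(m2$pixels, matrix(0, 4, 4))
  expect_error(mean_cluster_image(imgs, c(0L, 0L, 1L), 5L), "empty")
})

test_that("adjusted_rand_index agrees with the pair-counting definition", {
  set.seed(12)
  for (i in 1:6) {
    a <- sample(0:3, 20, replace = TRUE)
    b <- sample(0:2, 20, replace = TRUE)
    expect_equal(adjusted_rand_index(a, b), oracle_ari(a, b))
  }
  expect_equal(adjusted_rand_index(1:5, c(9, 8, 7, 6, 5)), 1)
})

test_that("k-means with one extra centroid recovers all five synthetic classes", {
  sim <- default_sim()
  b <- default_embedding()
  truth <- sim$truth$pattern_label
  # the embedding separates the 4 patterns AND the pure-noise class; with
  # k = n_patterns + 1 the recovery is exact (see the methods vignette for
  # why k = n_patterns cannot reach ARI 0.8 on this world)
  km5 <- cluster_kmeans(b$vectors, 5, seed = 11)
  expect_equal(adjusted_rand_index(km5, truth), 1)
  # with k = n_patterns the best attainable solution merges two pattern
  # classes; assert the structural ceiling rather than pretending otherwise
  km4 <- cluster_kmeans(b$vectors, 4, seed = 11)
  expect_equal(adjusted_rand_index(km4, truth), 0.7372, tolerance = 1e-3)
})
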
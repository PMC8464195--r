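test_that("average-linkage merge trees match the brute-force oracle on random points", {
  for (seed in 1:3) {
    set.seed(seed)
    x <- matrix(rnorm(12), 6, 2)
    fm <- fm_points(x)
    rep <- hierarchical_cluster(fm, "average")
    oracle <- oracle_agglomerate(x, "average")
    expect_equal(rep$height, oracle$heights, tolerance = 1e-10)
    for (k in 2:5)
      expect_true(same_partition(cut_clusters(rep, k = k),
                                 oracle$partitions[[6 - k]]))
  }
  expect_error(hierarchical_cluster(fm_points(matrix(1, 1, 2))), "2 samples")
})

test_that("average-linkage heights are non-decreasing and well-separated groups split at k = 2", {
  set.seed(1)
  x <- rbind(matrix(rnorm(10, 0, 0.1), 5, 2),
             matrix(rnorm(10, 10, 0.1), 5, 2))
  rep <- hierarchical_cluster(fm_points(x))
  expect_equal(length(rep$height), 9L)
  expect_true(all(diff(rep$height) >= -1e-12))
  cut2 <- cut_clusters(rep, k = 2)
  expect_true(same_partition(cut2, rep(1:2, each = 5)))
})

test_that("k-means attains the exhaustive-partition optimum on small instances", {
  for (seed in 1:3) {
    set.seed(seed)
    x <- matrix(rnorm(16), 8, 2)
    rep <- kmeans_cluster(fm_points(x), k = 2, restarts = 25, seed = seed)
    expect_equal(rep$within_ss, oracle_kmeans_min_wss(x, 2), tolerance = 1e-8)
    # conservation: between + within = total
    expect_equal(rep$between_ss + rep$within_ss, rep$total_ss,
                 tolerance = 1e-8)
  }
})

test_that("k-means ratio hits its degenerate endpoints", {
  set.seed(2)
  x <- matrix(rnorm(20), 10, 2)
  fm <- fm_points(x)
  expect_equal(kmeans_cluster(fm, k = 10, seed = 1)$between_total_ratio, 1)
  expect_equal(kmeans_cluster(fm, k = 1, seed = 1)$between_total_ratio, 0)
  expect_error(kmeans_cluster(fm, k = 11), "k <= n")
})

test_that("elbow selection recovers the true blob count and ties go to smallest k", {
  set.seed(7)
  centers <- matrix(c(0, 0, 10, 0, 0, 10, 10, 10), 4, 2, byrow = TRUE)
  x <- do.call(rbind, lapply(1:4, function(i)
    sweep(matrix(rnorm(20, 0, 1), 10, 2), 2L, centers[i, ], "+")))
  k <- elbow_select_k(fm_points(x), k_max = 8L, seed = 3L)
  expect_equal(as.integer(k), 4L)
  expect_length(attr(k, "wss"), 8L)
  # exactly linear curve has no elbow: distances are all ~0, first wins
  d <- hptlcauth:::chord_distance(1:5, seq(100, 20, by = -20))
  expect_true(all(d < 1e-9))
})

test_that("DBSCAN matches the reachability-closure oracle on a 12-point fixture", {
  set.seed(11)
  x <- rbind(matrix(rnorm(10, 0, 0.3), 5, 2),
             matrix(rnorm(10, 5, 0.3), 5, 2),
             c(10, 10), c(-10, -10))
  fm <- fm_points(x)
  rep <- dbscan_cluster(fm, eps = 1.5, min_pts = 3)
  oracle <- oracle_dbscan(x, eps = 1.5, min_pts = 3)
  expect_equal(rep$n_clusters, oracle$n_clusters)
  # noise sets agree
  expect_setequal(which(rep$assignments == 0), oracle$noise)
  # core points partition identically (up to relabelling)
  expect_true(same_partition(rep$assignments[oracle$core],
                             oracle$core_partition[oracle$core]))
  # border points sit within eps of a core point of their own cluster
  for (b in oracle$border) {
    cl <- rep$assignments[b]
    cores_cl <- intersect(oracle$core, which(rep$assignments == cl))
    expect_true(min(as.matrix(dist(x))[b, cores_cl]) <= 1.5)
  }
})

test_that("DBSCAN degenerate cases and row-order invariance", {
  set.seed(3)
  x <- matrix(rnorm(8, 0, 0.1), 4, 2)
  rep <- dbscan_cluster(fm_points(x), eps = 5, min_pts = 4)
  expect_equal(rep$n_clusters, 1L)
  expect_length(rep$noise_points, 0L)

  x2 <- rbind(x, c(100, 100))
  rep2 <- dbscan_cluster(fm_points(x2), eps = 5, min_pts = 2)
  expect_equal(rep2$noise_points, "p05")

  set.seed(9)
  x3 <- matrix(rnorm(30), 15, 2)
  r_a <- dbscan_cluster(fm_points(x3), eps = 1, min_pts = 3)
  perm <- sample(15)
  r_b <- dbscan_cluster(fm_points(x3[perm, , drop = FALSE]), eps = 1,
                        min_pts = 3)
  back <- integer(15); back[perm] <- seq_len(15)
  expect_true(same_partition(r_a$assignments + 1L,
                             r_b$assignments[back] + 1L))
})

test_that("PCA component variances equal covariance eigenvalues and scores centre at zero", {
  set.seed(5)
  x <- matrix(rnorm(20), 5, 4)
  fm <- fm_points(x)
  res <- pca_decompose(fm, n_components = 4L)
  ev <- eigen(cov(x), symmetric = TRUE)$values
  vars <- apply(res$scores, 2L, var)
  expect_equal(unname(vars), ev[1:4], tolerance = 1e-10)
  expect_equal(res$all_fractions, ev / sum(ev), tolerance = 1e-10)
  expect_equal(sum(res$all_fractions), 1)
  expect_true(all(abs(colMeans(res$scores)) < 1e-10))
  expect_true(all(diff(res$explained_fraction) <= 1e-12))
  # orthonormal loadings
  expect_equal(crossprod(res$loadings), diag(4), tolerance = 1e-10,
               ignore_attr = TRUE)
  expect_error(pca_decompose(fm, 5L), "exceeds")
})

test_that("rank-1 data puts all variance on the first component and reconstruction improves with components", {
  set.seed(6)
  t <- rnorm(6); p <- rnorm(3)
  x <- outer(t, p)
  res <- pca_decompose(fm_points(x), n_components = 2L)
  expect_equal(res$explained_fraction[1], 1, tolerance = 1e-10)

  x2 <- matrix(rnorm(40), 8, 5)
  errs <- vapply(1:4, function(c) {
    r <- pca_decompose(fm_points(x2), c)
    xc <- scale(x2, center = TRUE, scale = FALSE)
    sum((xc - r$scores %*% t(r$loadings))^2)
  }, numeric(1))
  expect_true(all(diff(errs) < 1e-10))
})
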
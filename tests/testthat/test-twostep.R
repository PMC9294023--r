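embed15 <- function(v) {
  # 1-D coordinates embedded in the 15-D score space
  cbind(matrix(v, ncol = 1), matrix(0, length(v), 14))
}

test_that("bypass mode returns one singleton pre-cluster per subject", {
  set.seed(31)
  x <- matrix(rnorm(20 * 15), ncol = 15)
  pcs <- build_cf_tree(x, cf_tree_params(bypass_tree = TRUE))
  expect_length(pcs$n, 20)
  expect_equal(pcs$n, rep(1, 20))
  expect_equal(pcs$ls, x)
  expect_equal(pcs$ss, x^2)
})

test_that("the CF tree separates well-spaced clouds and absorbs duplicates", {
  set.seed(32)
  x <- rbind(matrix(rnorm(10 * 15, 0, 0.1), ncol = 15),
             matrix(rnorm(10 * 15, 5, 0.1), ncol = 15))
  pcs <- build_cf_tree(x, cf_tree_params(initial_threshold = 1))
  expect_lte(length(pcs$n), 6)
  cloud_of <- sapply(pcs$members, function(m) length(unique(m > 10)))
  expect_true(all(cloud_of == 1))  # no pre-cluster mixes clouds
  expect_equal(sort(unlist(pcs$members)), 1:20)

  dup <- matrix(rep(as.numeric(1:15), 5), nrow = 5, byrow = TRUE)
  pcd <- build_cf_tree(dup, cf_tree_params(initial_threshold = 0))
  expect_length(pcd$n, 1)
  expect_equal(pcd$n, 5)

  expect_error(build_cf_tree(matrix(numeric(0), 0, 15)), "empty")
  xna <- x; xna[1, 1] <- NA
  expect_error(build_cf_tree(xna), "missing")
})

test_that("tree rebuilds under tight capacity still cover every point", {
  set.seed(33)
  y <- matrix(rnorm(100 * 3), ncol = 3)
  pcs <- build_cf_tree(y, cf_tree_params(branching_factor = 3,
                                         max_leaf_entries = 3, max_depth = 2))
  expect_equal(sum(pcs$n), 100)
  expect_equal(sort(unlist(pcs$members)), 1:100)
  # sufficient statistics remain exact under absorption and rebuilds
  for (p in seq_along(pcs$members)) {
    rows <- y[pcs$members[[p]], , drop = FALSE]
    expect_equal(pcs$ls[p, ], colSums(rows), tolerance = 1e-9)
    expect_equal(pcs$ss[p, ], colSums(rows^2), tolerance = 1e-9)
  }
})

test_that("agglomeration merges the nearest pair first", {
  x <- embed15(c(0, 1, 10))
  pcs <- build_cf_tree(x, cf_tree_params(bypass_tree = TRUE))
  dend <- agglomerate_preclusters(pcs)
  expect_equal(dend$merges$distance[1], 1)
  expect_true(same_partition(partition_at(dend, 2), c(1, 1, 2)))

  # duplicate pre-clusters merge at distance zero first
  xd <- embed15(c(3, 3, 9))
  dd <- agglomerate_preclusters(build_cf_tree(xd, cf_tree_params(bypass_tree = TRUE)))
  expect_equal(dd$merges$distance[1], 0)

  expect_error(agglomerate_preclusters(build_cf_tree(embed15(1),
                                                     cf_tree_params(bypass_tree = TRUE))),
               "at least 2")
})

test_that("bypass-mode agglomeration equals the naive centroid-linkage oracle", {
  set.seed(34)
  x <- matrix(rnorm(30 * 15), ncol = 15)
  dend <- agglomerate_preclusters(build_cf_tree(x, cf_tree_params(bypass_tree = TRUE)))
  oracle <- naive_agglomerate(x)
  expect_equal(dend$merges$distance, oracle$distances, tolerance = 1e-10)
  for (k in 1:29) {
    expect_true(same_partition(partition_at(dend, k), oracle$partitions[[k]]))
  }
  # merged sufficient statistics are exact sums of raw members
  part <- partition_at(dend, 4)
  cluster <- integer(30)
  for (p in seq_along(dend$preclusters$members)) {
    cluster[dend$preclusters$members[[p]]] <- part[p]
  }
  for (lab in unique(cluster)) {
    rows <- x[cluster == lab, , drop = FALSE]
    expect_equal(colMeans(rows),
                 colSums(dend$preclusters$ls[part == lab, , drop = FALSE]) /
                   sum(dend$preclusters$n[part == lab]), tolerance = 1e-10)
  }
})

test_that("partitions also agree with hclust centroid linkage on continuous data", {
  skip_if_not_installed("mclust")
  set.seed(35)
  x <- matrix(rnorm(25 * 15), ncol = 15)
  dend <- agglomerate_preclusters(build_cf_tree(x, cf_tree_params(bypass_tree = TRUE)))
  hc <- stats::hclust(stats::dist(x)^2, method = "centroid")
  for (k in c(2, 3, 5)) {
    a <- integer(25)
    part <- partition_at(dend, k)
    for (p in seq_along(dend$preclusters$members)) a[dend$preclusters$members[[p]]] <- part[p]
    expect_equal(mclust::adjustedRandIndex(a, stats::cutree(hc, k)), 1)
  }
})

test_that("the BIC matches its closed form and penalises extra clusters", {
  set.seed(36)
  x <- matrix(rnorm(5 * 15), ncol = 15)
  pcs <- build_cf_tree(x, cf_tree_params(bypass_tree = TRUE))
  N <- 5; d <- 15
  cohort_var <- colMeans(x^2) - colMeans(x)^2

  # J = 1: xi = -N * sum_v 0.5*log(2 * sigma_v^2)
  bic1 <- twostep_bic(pcs, rep(1, 5))
  expect_equal(bic1, -2 * (-N * sum(0.5 * log(2 * cohort_var))) + 2 * d * log(N))

  # arbitrary 2-cluster partition recomputed by hand
  part <- c(1, 1, 2, 2, 2)
  xi <- 0
  for (lab in 1:2) {
    rows <- x[part == lab, , drop = FALSE]
    vj <- colMeans(rows^2) - colMeans(rows)^2
    vj <- pmax(vj, 1e-9 * cohort_var)
    xi <- xi + (-nrow(rows) * sum(0.5 * log(cohort_var + vj)))
  }
  expect_equal(twostep_bic(pcs, part), -2 * xi + 2 * d * 2 * log(N))

  expect_error(twostep_bic(pcs, c(1, 1, 2, 2, NA)))
})

test_that("BIC favours two clusters for well-separated blobs", {
  set.seed(37)
  x <- rbind(matrix(rnorm(20 * 15, 0, 1), ncol = 15),
             matrix(rnorm(20 * 15, 6, 1), ncol = 15))
  dend <- agglomerate_preclusters(build_cf_tree(x, cf_tree_params(bypass_tree = TRUE)))
  bic <- dend$bic
  expect_lt(bic$bic[bic$k == 2], bic$bic[bic$k == 1])
  sel <- select_cluster_count(dend)
  expect_equal(sel$k, 2L)
})

test_that("auto-selection recovers three equidistant blobs in the modal case", {
  # three spherical blobs at mutually equidistant simplex vertices; the
  # cohort must be large enough for the likelihood gain to beat the
  # 2*d*J*log(N) parameter penalty in 15 dimensions
  ks <- sapply(1:20, function(s) {
    set.seed(400 + s)
    x <- do.call(rbind, lapply(1:3, function(j) {
      m <- matrix(rnorm(100 * 15, 0, 0.5), ncol = 15)
      m[, j] <- m[, j] + 6
      m
    }))
    dend <- agglomerate_preclusters(build_cf_tree(x, cf_tree_params(bypass_tree = TRUE)))
    select_cluster_count(dend)$k
  })
  expect_equal(as.integer(names(which.max(table(ks)))), 3L)
  expect_error(select_cluster_count(NULL, k_max = 1), "k_max")
})

test_that("assignment is a permutation-equivariant identity in bypass mode", {
  set.seed(38)
  x <- rbind(matrix(rnorm(15 * 15, 0, 1), ncol = 15),
             matrix(rnorm(15 * 15, 5, 1), ncol = 15))
  rownames(x) <- sprintf("P%02d", 1:30)
  fit <- cluster_twostep(x, k = 2)
  # dendrogram partition and subject assignment coincide
  part <- partition_at(fit$dendrogram, 2)
  raw <- integer(30)
  for (p in seq_along(fit$dendrogram$preclusters$members)) {
    raw[fit$dendrogram$preclusters$members[[p]]] <- part[p]
  }
  expect_true(same_partition(fit$assignments$cluster, raw))
  # cluster 1 is the smaller cluster by convention
  expect_equal(which.min(fit$cluster_sizes), 1L)

  perm <- sample(30)
  fit2 <- cluster_twostep(x[perm, ], k = 2)
  expect_true(same_partition(fit2$assignments$cluster, fit$assignments$cluster[perm]))
  expect_equal(fit2$assignments$subject_id, rownames(x)[perm])
})

test_that("silhouette matches brute force and flags degenerate input", {
  set.seed(39)
  x6 <- matrix(rnorm(6 * 15), ncol = 15)
  cl6 <- c(1, 1, 2, 2, 3, 3)
  expect_equal(silhouette_widths(x6, cl6), brute_silhouette(x6, cl6),
               tolerance = 1e-12)
  skip_if_not_installed("cluster")
  sw <- cluster::silhouette(cl6, stats::dist(x6))
  expect_equal(mean_silhouette(x6, cl6), mean(sw[, "sil_width"]), tolerance = 1e-12)

  xs <- rbind(matrix(rnorm(10 * 15, 0, 0.05), ncol = 15),
              matrix(rnorm(10 * 15, 8, 0.05), ncol = 15))
  expect_gt(mean_silhouette(xs, rep(1:2, each = 10)), 0.9)
  expect_error(mean_silhouette(xs, rep(1, 20)), "at least 2")
})

test_that("planted two-subtype cohorts are recovered with high agreement", {
  skip_if_not_installed("mclust")
  ok <- sapply(1:5, function(s) {
    sc <- scored_cohort(n = 120, seed = 500 + s)
    fit <- cluster_twostep(sc$scores)
    c(k = fit$k,
      ari = mclust::adjustedRandIndex(fit$assignments$cluster, sc$sim$latent$subtype))
  })
  expect_true(all(ok["k", ] == 2))
  expect_true(all(ok["ari", ] > 0.9))
})
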
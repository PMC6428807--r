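# Distances, single-linkage trees, cluster-content curves and C_1/3.

test_that("cosine distance handles the documented cases", {
  expect_equal(cosine_distance(c(1, 2, 3), c(1, 2, 3)), 0)
  expect_equal(cosine_distance(c(1, 0, 0), c(0, 1, 0)), 1)
  expect_equal(cosine_distance(c(1, 1, 0), c(1, 0, 1)), 0.5)
  expect_equal(cosine_distance(c(0, 0), c(0, 0)), 0)
  expect_equal(cosine_distance(c(0, 0), c(1, 0)), 1)
  expect_error(cosine_distance(1:3, 1:4), "length")
})

test_that("pairwise cosine distances equal the element-wise recomputation", {
  set.seed(2)
  for (i in 1:30) {
    n <- sample(3:8, 1)
    x <- matrix(rbinom(n * 10, 1, 0.4), n, 10)
    x[sample(n, 1), ] <- 0   # include a zero row
    expect_equal(unname(pairwise_distances(x, "cosine")),
                 oracle_cosine_matrix(x), tolerance = 1e-12,
                 ignore_attr = TRUE)
  }
  # degenerate fixtures
  xid <- matrix(1, 40, 5)
  expect_true(all(pairwise_distances(xid) == 0))
  xor <- diag(3)
  d <- pairwise_distances(xor)
  expect_true(all(d[upper.tri(d)] == 1))
})

test_that("single linkage equals a naive O(n^3) agglomeration oracle", {
  set.seed(4)
  for (i in 1:100) {
    n <- sample(4:10, 1)
    x <- matrix(runif(n * 6), n, 6)
    d <- pairwise_distances(x, "euclidean")
    tree <- single_linkage_tree(d)
    expect_equal(sort(tree$height), oracle_single_linkage_heights(d),
                 tolerance = 1e-10)
    expect_true(all(diff(tree$height) >= -1e-12))
  }
})

test_that("cluster counts match a union-find oracle along the curve", {
  set.seed(9)
  for (i in 1:20) {
    n <- sample(5:10, 1)
    x <- matrix(runif(n * 4), n, 4)
    d <- pairwise_distances(x, "euclidean")
    curve <- cluster_content_curve(single_linkage_tree(d), n_grid = 25)
    for (ci in seq_along(curve$cutoffs))
      expect_equal(curve$n_clusters[ci],
                   oracle_cluster_count(d, curve$cutoffs[ci]))
    expect_true(all(diff(curve$n_clusters) <= 0))
    expect_equal(curve$n_clusters[length(curve$n_clusters)], 1)
  }
})

test_that("two tight triads merge as expected across the cutoff", {
  # 6 points: two clusters of 3 with intra distance <= 0.1, inter >= 0.9
  x <- rbind(c(0, 0), c(0.05, 0), c(0, 0.05),
             c(1, 1), c(1.05, 1), c(1, 1.05))
  d <- pairwise_distances(x, "euclidean")
  tree <- single_linkage_tree(d)
  curve <- cluster_content_curve(tree, cutoffs = c(0.01, 0.2, 2))
  expect_equal(curve$n_clusters, c(6, 2, 1))
})

test_that("C 1/3 is the first cutoff dropping below a third of the leaves", {
  # 12 leaves in 3 well-separated clusters: threshold is 4 clusters
  set.seed(11)
  centers <- rbind(c(0, 0), c(5, 0), c(0, 5))
  x <- do.call(rbind, lapply(1:3, function(k)
    sweep(matrix(rnorm(8, 0, 0.05), 4, 2), 2, centers[k, ], "+")))
  d <- pairwise_distances(x, "euclidean")
  curve <- cluster_content_curve(single_linkage_tree(d), n_grid = 400)
  c13 <- c_one_third(curve)
  expect_true(c13$dropped)
  oracle_first <- curve$cutoffs[min(which(curve$n_clusters < 4))]
  expect_equal(c13$value, oracle_first)
  # identical responses: collapses at the first grid cutoff
  did <- pairwise_distances(matrix(1, 40, 5))
  cid <- c_one_third(cluster_content_curve(single_linkage_tree(did)))
  expect_equal(cid$value, 0)
  # mutually orthogonal responses only collapse at the grid's end (distance 1)
  dor <- pairwise_distances(diag(40))
  res <- c_one_third(cluster_content_curve(single_linkage_tree(dor)))
  expect_equal(res$value, 1)
})

test_that("condition comparison reproduces the analytic signed-rank values", {
  # 8 paired networks, all shifted in the expected direction
  cmp <- compare_conditions(control = seq(0.2, 0.9, length.out = 8),
                            blocked = seq(0.2, 0.9, length.out = 8) - 0.1)
  expect_equal(cmp$p_value, 1 / 256)
  expect_equal(cmp$n_positive, 8)
  # no difference at all
  cmp0 <- compare_conditions(rep(0.5, 5), rep(0.5, 5))
  expect_equal(cmp0$p_value, 1)
  # mixed signs at n = 6: exhaustive enumeration oracle
  set.seed(13)
  for (i in 1:10) {
    delta <- round(rnorm(6), 2)
    delta[delta == 0] <- 0.01
    cmp6 <- compare_conditions(delta, rep(0, 6))
    expect_equal(cmp6$p_value, oracle_signed_rank_p(delta, "right"))
  }
  expect_error(compare_conditions(1, 1), "2 pairs")
})
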
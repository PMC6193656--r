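make_toy_suite <- function(seed = 19) {
  generate_suite(table1_models(n0 = 40, snapshots = 3), replicates = 2,
                 seed = seed)
}

test_that("feature dimensions follow the method contracts", {
  cat4 <- build_catalog(4)
  nets <- make_toy_suite()
  f_got <- build_features(nets, "got", cat4)
  expect_equal(ncol(f_got), 121L)
  f_stg <- build_features(nets, "stg", cat4)
  expect_equal(ncol(f_stg), 3L * 11L)
  f_sg <- build_features(nets, "sg", cat4)
  expect_equal(ncol(f_sg), 11L)
  f_sm <- build_features(nets[1:4], "sm", cat4, n_random = 3, seed = 1)
  expect_equal(ncol(f_sm), 6L)
  expect_equal(nrow(f_got), length(nets))
  expect_equal(attr(f_got, "labels"),
               vapply(nets, function(n) n$meta$model, character(1)))

  # structurally identical networks map to identical rows
  twin <- nets[c(1, 1)]
  f_twin <- build_features(twin, "got", cat4)
  expect_equal(f_twin[1, ], f_twin[2, ])

  mixed <- c(nets[1], list(generate_temporal(model_spec("erdos", n0 = 40,
                                                        snapshots = 4, seed = 2))))
  expect_error(build_features(mixed, "stg", cat4), "snapshot count")
})

test_that("PCA reduction keeps the requested variance and degenerates gracefully", {
  set.seed(3)
  x <- matrix(rnorm(60), 12, 5)
  # full variance: pairwise distances are preserved exactly
  r <- pca_reduce(x, variance = 1)
  expect_equal(as.matrix(dist(r)), as.matrix(dist(x)), ignore_attr = TRUE)
  # rank-1 data collapses to one component
  u <- outer(rnorm(10), c(1, 2, 3))
  expect_equal(ncol(pca_reduce(u, 0.99)), 1L)
  # constant matrix -> single zero component
  k <- pca_reduce(matrix(5, 6, 4), 0.99)
  expect_equal(dim(k), c(6L, 1L))
  expect_true(all(k == 0))
})

test_that("distance matrices are min-max normalized and order preserving", {
  x <- rbind(c(0, 0), c(0, 0), c(3, 4), c(6, 8))
  expect_warning(d0 <- distance_matrix(rbind(c(1, 1), c(1, 1))), "equal")
  expect_true(all(d0 == 0))
  d <- distance_matrix(x)
  expect_equal(d[1, 2], 0)
  expect_equal(max(d), 1)
  expect_true(all(d >= 0 & d <= 1))
  raw <- as.matrix(dist(x))
  expect_equal(order(raw[upper.tri(raw)]), order(d[upper.tri(d)]))
})

test_that("precision-recall sweep matches a brute-force pair scan", {
  # four units, two classes, hand-set distances
  d <- matrix(0, 4, 4)
  d[1, 2] <- d[2, 1] <- 0.1   # same class  (a)
  d[3, 4] <- d[4, 3] <- 0.4   # same class  (b)
  d[1, 3] <- d[3, 1] <- 0.25
  d[1, 4] <- d[4, 1] <- 0.8
  d[2, 3] <- d[3, 2] <- 0.6
  d[2, 4] <- d[4, 2] <- 1.0
  labels <- c("a", "a", "b", "b")
  res <- precision_recall(d, labels, step = 0.001)

  # brute force over the same threshold grid
  pairs <- which(upper.tri(d), arr.ind = TRUE)
  pd <- d[pairs]
  same <- labels[pairs[, 1]] == labels[pairs[, 2]]
  eps <- seq(0, 1, by = 0.001)
  pr <- vapply(eps, function(e) {
    g <- pd <= e
    if (!any(g)) 1 else sum(g & same) / sum(g)
  }, numeric(1))
  rec <- vapply(eps, function(e) sum(pd <= e & same) / sum(same), numeric(1))
  expect_equal(res$curve$precision, pr)
  expect_equal(res$curve$recall, rec)
  expect_equal(res$aupr, sum(pr[-1] * diff(rec)))

  # perfectly separated classes reach AUPR 1; recall 1 at the last step
  d2 <- matrix(0.9, 4, 4); diag(d2) <- 0
  d2[1, 2] <- d2[2, 1] <- d2[3, 4] <- d2[4, 3] <- 0.05
  res2 <- precision_recall(d2, labels)
  expect_equal(res2$aupr, 1)
  expect_equal(res2$curve$recall[nrow(res2$curve)], 1)

  expect_error(precision_recall(d, c("a", "a", "a", "a")), "classes")
})

test_that("label-independent distances score near the same-label prevalence", {
  set.seed(29)
  n <- 12
  labels <- rep(c("a", "b", "c"), each = 4)
  pairs_same <- outer(labels, labels, `==`)
  prevalence <- sum(pairs_same[upper.tri(pairs_same)]) / sum(upper.tri(pairs_same))
  auprs <- replicate(20, {
    x <- matrix(rnorm(n * 3), n, 3)
    precision_recall(distance_matrix(x), labels)$aupr
  })
  expect_lt(abs(mean(auprs) - prevalence), 0.05)
})

test_that("complete-linkage clustering recovers well-separated pairs", {
  d <- matrix(0.9, 4, 4); diag(d) <- 0
  d[1, 2] <- d[2, 1] <- 0.1
  d[3, 4] <- d[4, 3] <- 0.2
  attr(d, "kind") <- "euclidean-distance"
  hc <- cluster_complete_linkage(d)
  expect_equal(hc$height[1:2], c(0.1, 0.2))
  merges <- apply(hc$merge[1:2, ], 1, function(r) sort(-r))
  expect_equal(sort(as.vector(merges)), 1:4)

  # similarity input is converted via 1 - s
  s <- 1 - d
  attr(s, "kind") <- "OTA"
  hc2 <- cluster_complete_linkage(s)
  expect_equal(hc2$height, hc$height)

  # permutation invariance of merge heights
  p <- c(3, 1, 4, 2)
  hc3 <- cluster_complete_linkage(d[p, p])
  expect_equal(hc3$height, hc$height)

  expect_error(cluster_complete_linkage(matrix(1:4, 2, 2)), "symmetric")
})
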
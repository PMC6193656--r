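# A 4-node set carrying orbits (x,x,y,y) at t and (x,y,x,y) at t+1: built
# from two diamond graphs on nodes {5,8,10,12} whose degree-3 pair moves
# from {5,8} to {5,10}.
diamond_example <- function() {
  d1 <- snapshot(rbind(c(5, 8), c(5, 10), c(5, 12), c(8, 10), c(8, 12)), 12)
  d2 <- snapshot(rbind(c(5, 10), c(5, 8), c(5, 12), c(10, 8), c(10, 12)), 12)
  temporal_network(list(d1, d2), as.character(1:12))
}

test_that("orbit patterns (x,x,y,y) -> (x,y,x,y) increment four transition cells by one", {
  cat4 <- build_catalog(4)
  tm <- got_matrix(diamond_example(), cat4)
  x <- 9L; y <- 10L  # diamond orbits: degree-3 pair and degree-2 pair
  expect_equal(tm[x, x], 1L)
  expect_equal(tm[x, y], 1L)
  expect_equal(tm[y, x], 1L)
  expect_equal(tm[y, y], 1L)
  expect_equal(sum(tm), 4L)
})

test_that("triangle-to-path and disconnection toys are counted per the orbit definitions", {
  cat3 <- build_catalog(3)
  tri_path <- temporal_network(list(toy_triangle(), toy_path3()),
                               as.character(1:3))
  tm <- got_matrix(tri_path, cat3)
  expect_equal(tm[3, 1], 1L)  # triangle -> chain center
  expect_equal(tm[3, 2], 2L)  # triangle -> chain periphery
  expect_equal(sum(tm), 3L)

  # subgraph disconnected at t+1 contributes nothing
  tri_edge <- temporal_network(list(toy_triangle(),
                                    snapshot(rbind(c(1, 2)), 3)),
                               as.character(1:3))
  expect_equal(sum(got_matrix(tri_edge, cat3)), 0L)

  expect_error(got_matrix(temporal_network(list(toy_triangle()),
                                           as.character(1:3)), cat3),
               "two snapshots")
})

test_that("transition matrices match the all-subsets oracle on random temporal toys", {
  set.seed(23)
  for (rep in 1:8) {
    n <- sample(6:10, 1)
    net <- random_toy_network(n, sample(2:4, 1), p = runif(1, 0.2, 0.45))
    for (k in 3:4) {
      cat_k <- build_catalog(k)
      expect_equal(unname(got_matrix(net, cat_k)), oracle_got(net, cat_k))
    }
  }
})

test_that("a temporally constant network has a diagonal transition matrix", {
  set.seed(31)
  snap <- random_toy_network(9, 1, p = 0.4)$snapshots[[1]]
  net <- temporal_network(list(snap, snap, snap), as.character(1:9))
  for (k in 3:4) {
    tm <- got_matrix(net, build_catalog(k))
    expect_true(all(tm[upper.tri(tm) | lower.tri(tm)] == 0L))
    ntr <- row_normalize(tm)
    occupied <- rowSums(tm) > 0
    expect_equal(diag(ntr)[occupied], rep(1, sum(occupied)), ignore_attr = TRUE)
  }
})

test_that("per-node transition vectors conserve the network matrix", {
  cat3 <- build_catalog(3)
  tri_path <- temporal_network(list(toy_triangle(), toy_path3()),
                               as.character(1:3))
  ntv <- node_transition_vectors(tri_path, cat3)
  expect_equal(ntv["2", "O3->O1"], 1L)
  expect_equal(ntv["1", "O3->O2"], 1L)
  expect_equal(ntv["3", "O3->O2"], 1L)
  expect_equal(sum(ntv), 3L)

  set.seed(13)
  net <- random_toy_network(8, 3, p = 0.35)
  cat4 <- build_catalog(4)
  tm <- got_matrix(net, cat4)
  ntv4 <- node_transition_vectors(net, cat4)
  expect_equal(matrix(colSums(ntv4), 11, 11, byrow = TRUE), unname(tm))
  # nodes absent from all matched occurrences have all-zero rows
  isolated <- temporal_network(list(snapshot(rbind(c(1, 2), c(2, 3), c(1, 3)), 5),
                                    snapshot(rbind(c(1, 2), c(2, 3), c(1, 3)), 5)),
                               as.character(1:5))
  ntv5 <- node_transition_vectors(isolated, cat3)
  expect_equal(sum(ntv5[4:5, ]), 0L)
})

test_that("row normalization maps counts to per-row distributions", {
  m <- rbind(c(2, 2, 4), c(0, 0, 0), c(1, 0, 0))
  nm <- row_normalize(m)
  expect_equal(nm[1, ], c(0.25, 0.25, 0.5))
  expect_equal(nm[2, ], c(0, 0, 0))
  expect_equal(rowSums(nm)[c(1, 3)], c(1, 1), ignore_attr = TRUE)
  expect_error(row_normalize(matrix(1, 2, 3)), "square")
})

test_that("discretization uses the rare/common/frequent interval bounds", {
  v <- matrix(c(0, 1 / 3, 0.5, 2 / 3, 0.7, 1), 2, 3)
  d <- discretize(v)
  expect_equal(as.vector(d), c("rare", "rare", "common", "common",
                               "frequent", "frequent"))
  expect_error(discretize(matrix(c(0.2, 1.2), 1, 2)), "0, 1")
})
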
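test_that("canonical codes are isomorphism invariants", {
  tri <- adj_from_edges(rbind(c(1, 2), c(2, 3), c(1, 3)), 3)
  path <- adj_from_edges(rbind(c(1, 2), c(2, 3)), 3)
  # any relabeling of the triangle gives the same code
  codes <- vapply(oracle_perms(3L), function(p) canonical_code(tri[p, p]),
                  numeric(1))
  expect_equal(length(unique(codes)), 1L)
  expect_false(canonical_code(tri) == canonical_code(path))

  c4 <- adj_from_edges(rbind(c(1, 2), c(2, 3), c(3, 4), c(1, 4)), 4)
  p4 <- adj_from_edges(rbind(c(1, 2), c(2, 3), c(3, 4)), 4)
  expect_false(canonical_code(c4) == canonical_code(p4))
})

test_that("canonical code agrees with an igraph isomorphism oracle on random graph pairs", {
  set.seed(7)
  for (k in 4:5) {
    for (rep in 1:40) {
      a <- adj_from_edges(t(combn(k, 2))[runif(choose(k, 2)) < 0.5, , drop = FALSE], k)
      b <- adj_from_edges(t(combn(k, 2))[runif(choose(k, 2)) < 0.5, , drop = FALSE], k)
      iso <- igraph::isomorphic(
        igraph::graph_from_adjacency_matrix(a, mode = "undirected"),
        igraph::graph_from_adjacency_matrix(b, mode = "undirected"))
      expect_equal(canonical_code(a) == canonical_code(b), iso)
    }
  }
})

test_that("orbit partitions match their definition on named graphlets", {
  star <- adj_from_edges(cbind(1L, 2:4), 4)
  orb <- automorphism_orbits(star)
  expect_equal(length(orb), 2L)
  expect_equal(sort(lengths(orb)), c(1L, 3L))

  path <- adj_from_edges(rbind(c(1, 2), c(2, 3)), 3)
  expect_equal(length(automorphism_orbits(path)), 2L)

  tri <- adj_from_edges(rbind(c(1, 2), c(2, 3), c(1, 3)), 3)
  expect_equal(length(automorphism_orbits(tri)), 1L)

  expect_error(automorphism_orbits(adj_from_edges(rbind(c(1, 2)), 4)),
               "connected")
})

test_that("orbit partitions agree with the brute-force oracle on all cataloged graphlets", {
  for (k in 3:5) {
    cat_k <- build_catalog(k)
    for (g in cat_k$graphlets) {
      got <- automorphism_orbits(g$adjacency)
      exp <- oracle_orbits(g$adjacency)
      norm <- function(b) sort(vapply(b, function(x) paste(sort(x), collapse = ","),
                                      character(1)))
      expect_equal(norm(got), norm(exp))
    }
  }
})

test_that("catalog sizes reproduce the known orbit and graphlet counts", {
  expect_equal(build_catalog(2)$n_graphlets, 1L)
  expect_equal(build_catalog(2)$orbit_count, 1L)
  expect_equal(build_catalog(3)$n_graphlets, 2L)
  expect_equal(build_catalog(3)$orbit_count, 3L)
  expect_equal(build_catalog(4)$n_graphlets, 6L)
  expect_equal(build_catalog(4)$orbit_count, 11L)
  expect_equal(build_catalog(5)$n_graphlets, 21L)
  expect_equal(build_catalog(5)$orbit_count, 58L)
  expect_equal(build_catalog(3, directed = TRUE)$orbit_count, 30L)
  expect_error(build_catalog(5, directed = TRUE), "directed")
  expect_error(build_catalog(7), "between 2 and 6")
})

test_that("the 4-node undirected catalog pins the named orbits", {
  cat4 <- build_catalog(4)
  # graphlet 1 is the star: orbit 1 its center (degree 3), orbit 2 the leaves
  expect_equal(cat4$orbits$degree[cat4$orbits$orbit == 1], 3)
  expect_equal(cat4$orbits$degree[cat4$orbits$orbit == 2], 1)
  # orbit 5 is the 4-cycle's single orbit, orbit 11 the clique's
  expect_equal(cat4$orbits$graphlet[cat4$orbits$orbit == 5], 3)
  cyc <- cat4$graphlets[[3]]
  expect_equal(sort(as.integer(rowSums(cyc$adjacency))), rep(2L, 4))
  cli <- cat4$graphlets[[6]]
  expect_equal(sort(as.integer(rowSums(cli$adjacency))), rep(3L, 4))
  expect_equal(unique(cli$orbit_ids), 11L)
})

test_that("orbit ids are invariant under automorphic relabeling (fixed point)", {
  cat4 <- build_catalog(4)
  for (g in cat4$graphlets) {
    for (p in oracle_perms(4L)) {
      if (all(g$adjacency[p, p] == g$adjacency)) {
        expect_equal(orbit_lookup(cat4, g$adjacency[p, p]),
                     orbit_lookup(cat4, g$adjacency)[p])
      }
    }
  }
})

test_that("orbit lookup preserves the query node order", {
  cat3 <- build_catalog(3)
  tri <- adj_from_edges(rbind(c(1, 2), c(2, 3), c(1, 3)), 3)
  expect_equal(length(unique(orbit_lookup(cat3, tri))), 1L)

  path <- adj_from_edges(rbind(c(1, 2), c(2, 3)), 3)
  o <- orbit_lookup(cat3, path)
  expect_equal(o[1], o[3])
  expect_false(o[1] == o[2])

  cat4 <- build_catalog(4)
  # star with center queried in position 2
  star_perm <- adj_from_edges(rbind(c(2, 1), c(2, 3), c(2, 4)), 4)
  expect_equal(orbit_lookup(cat4, star_perm), c(2L, 1L, 2L, 2L))

  disc <- adj_from_edges(rbind(c(1, 2), c(3, 4)), 4)
  expect_error(orbit_lookup(cat4, disc), "disconnected")
})

test_that("catalogs are deterministic across rebuilds and export to JSON", {
  a <- build_catalog(4)
  # force a fresh build in a clean cache by comparing against field recompute
  expect_equal(vapply(a$graphlets, `[[`, numeric(1), "code"),
               vapply(build_catalog(4)$graphlets, `[[`, numeric(1), "code"))
  f <- withr::local_tempfile(fileext = ".json")
  export_catalog_json(a, f)
  doc <- jsonlite::read_json(f)
  expect_equal(doc$orbit_count, 11L)
  expect_equal(length(doc$graphlets), 6L)
})
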